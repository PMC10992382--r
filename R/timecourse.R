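#' Concentration series with a declared unit
#'
#' @param values non-negative concentrations, one per sample time.
#' @param unit `"mM"` or `"gL"` (grams per litre).
#' @return An object of class `conc_series`.
#' @export
conc_series <- function(values, unit = c("mM", "gL")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(values))
  if (any(!is.finite(values)) || any(values < 0))
    stop("concentrations must be finite and >= 0")
  structure(list(values = as.numeric(values), unit = unit),
            class = "conc_series")
}

#' Fermentation time course
#'
#' Holds sampled times (hours), OD600 readings and per-species concentration
#' series for a resting-cell batch. The capture phase runs at roughly
#' constant biomass, so concentrations change (near-)linearly at constant
#' specific rates.
#'
#' @param times sample times in hours, strictly increasing.
#' @param od600 OD600 per sample, > 0.
#' @param concentrations named list of [conc_series()] (one per species), all
#'   the same length as `times`.
#' @param labeled_lactate optional [conc_series()] of 13C-labeled lactate,
#'   same unit convention as lactate.
#' @return An object of class `time_course`.
#' @export
time_course <- function(times, od600, concentrations,
                        labeled_lactate = NULL) {
  stopifnot(is.numeric(times), length(times) >= 2)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  stopifnot(is.numeric(od600), length(od600) == length(times))
  if (any(od600 <= 0)) stop("od600 must be positive")
  if (is.null(names(concentrations)) || any(!nzchar(names(concentrations))))
    stop("concentrations must be a named list")
  for (sp in names(concentrations)) {
    cs <- concentrations[[sp]]
    if (!inherits(cs, "conc_series"))
      stop("concentration for '", sp, "' must be a conc_series")
    if (length(cs$values) != length(times))
      stop("series for '", sp, "' has wrong length")
  }
  if (!is.null(labeled_lactate)) {
    stopifnot(inherits(labeled_lactate, "conc_series"))
    if (length(labeled_lactate$values) != length(times))
      stop("labeled_lactate series has wrong length")
  }
  structure(list(times = as.numeric(times), od600 = as.numeric(od600),
                 concentrations = concentrations,
                 labeled_lactate = labeled_lactate),
            class = "time_course")
}

#' Convert a concentration to mM
#'
#' g/L values are converted through the species molar mass
#' (`value / molar_mass * 1000`); mM values pass through unchanged.
#'
#' @param value numeric concentration(s).
#' @param unit `"mM"` or `"gL"`.
#' @param species species name (needed for g/L input).
#' @param constants a [network_constants()] supplying molar masses.
#' @return Concentration(s) in mM.
#' @examples
#' convert_concentration(0.49, "gL", "lactate") # 5.44 mM
#' @export
convert_concentration <- function(value, unit, species,
                                  constants = network_constants()) {
  if (unit == "mM") return(value)
  if (unit == "gL") {
    mm <- unname(constants$molar_mass[species])
    if (length(mm) != 1 || is.na(mm))
      stop("no molar mass for species '", species, "'; cannot convert g/L")
    return(value / mm * 1000)
  }
  stop("unknown concentration unit '", unit, "'")
}

series_mM <- function(tc, species, constants) {
  cs <- tc$concentrations[[species]]
  if (is.null(cs)) stop("time course has no series for '", species, "'")
  convert_concentration(cs$values, cs$unit, species, constants)
}

# resolve a [t_start, t_end] window to sample indices; window endpoints must
# be sample times (snap = TRUE snaps to the nearest samples, used for the
# default last-12-h window when sampling is irregular)
resolve_window <- function(tc, window = NULL, snap = is.null(window)) {
  tmax <- max(tc$times)
  if (is.null(window)) window <- c(tmax - 12, tmax)
  stopifnot(is.numeric(window), length(window) == 2, window[1] < window[2])
  if (window[1] < min(tc$times) - 1e-8 || window[2] > tmax + 1e-8)
    stop("window outside sampled range")
  idx <- function(t) {
    d <- abs(tc$times - t)
    i <- which.min(d)
    if (!snap && d[i] > 1e-8) stop("window endpoint ", t, " is not a sample time")
    i
  }
  i1 <- idx(window[1]); i2 <- idx(window[2])
  if (i2 - i1 < 1) stop("window must contain at least 2 samples")
  c(i1, i2)
}

#' Specific rate over a time window
#'
#' Computes the specific consumption or production rate of one species in
#' mmol gDCW^-1 h^-1: the concentration change across the window (mM/h)
#' divided by the biomass density (mean OD600 in the window times the
#' OD-to-DCW factor). The direction is set by the sign of the concentration
#' change (decreasing = consumption).
#'
#' @param tc a [time_course()].
#' @param species species name.
#' @param window `c(t_start, t_end)` in hours; endpoints must be sample
#'   times. `NULL` (default) uses the last 12 h of the series.
#' @param constants a [network_constants()].
#' @param biomass_mode `"constant"` divides the window-average rate by the
#'   window-mean biomass (resting-cell assumption); `"per_sample"` computes
#'   interval-wise rates against interval-midpoint biomass and returns their
#'   time-weighted mean.
#' @param method `"endpoint"` (difference quotient between the window
#'   endpoints, the default) or `"lm"` (least-squares slope over all samples
#'   in the window; its standard error populates the `sd` field).
#' @return A [rate_measurement()].
#' @examples
#' tc <- time_course(c(60, 72), c(2, 2),
#'                   list(lactate = conc_series(c(10, 16), "mM")))
#' specific_rate(tc, "lactate")$value # 0.833
#' @export
specific_rate <- function(tc, species, window = NULL,
                          constants = network_constants(),
                          biomass_mode = c("constant", "per_sample"),
                          method = c("endpoint", "lm")) {
  biomass_mode <- match.arg(biomass_mode)
  method <- match.arg(method)
  ii <- resolve_window(tc, window)
  sel <- seq(ii[1], ii[2])
  conc <- series_mM(tc, species, constants)[sel]
  times <- tc$times[sel]
  od <- tc$od600[sel]
  if (all(od * constants$dcw_per_od <= 0)) stop("zero biomass in window")

  if (biomass_mode == "per_sample" && method == "endpoint") {
    # interval-wise quotient against interval-midpoint biomass
    dc <- diff(conc)
    biom <- (utils::head(od, -1) + utils::tail(od, -1)) / 2 *
      constants$dcw_per_od
    net <- sum(dc / biom)                    # mmol/gDCW accumulated
    rate <- net / (times[length(times)] - times[1])
    sdv <- 0
  } else {
    biomass <- mean(od) * constants$dcw_per_od
    if (method == "endpoint") {
      rate <- (conc[length(conc)] - conc[1]) /
        (times[length(times)] - times[1]) / biomass
      sdv <- 0
    } else {
      fit <- stats::lm(conc ~ times)
      slope <- stats::coef(fit)[["times"]]
      se <- tryCatch(
        suppressWarnings(summary(fit)$coefficients["times", "Std. Error"]),
        error = function(e) 0)
      rate <- slope / biomass
      sdv <- if (is.finite(se)) se / biomass else 0
    }
  }
  direction <- if (rate < 0) "consumption" else "production"
  rate_measurement(abs(rate), sdv, direction)
}

#' Labeled-lactate fraction over a window
#'
#' The fraction of lactate accumulated over the window that is 13C-labeled,
#' after subtracting the control strain's labeled-lactate accumulation over
#' the same window as background:
#' `R = (delta labeled - delta background) / delta total`.
#'
#' If no control time course is supplied the fraction is uncorrected and the
#' result carries attribute `corrected = FALSE`. A negative corrected
#' numerator is clipped to zero with a warning (attribute `clipped = TRUE`).
#'
#' @param tc a [time_course()] containing `lactate` and a labeled-lactate
#'   series.
#' @param window window in hours (default: last 12 h).
#' @param control_tc optional control-strain [time_course()] supplying the
#'   background labeled-lactate accumulation.
#' @param constants a [network_constants()].
#' @return Dimensionless fraction in `[0, 1)` with attributes `corrected` and
#'   `clipped`.
#' @export
label_fraction_from_timecourse <- function(tc, window = NULL,
                                           control_tc = NULL,
                                           constants = network_constants()) {
  if (is.null(tc$labeled_lactate)) stop("time course has no labeled_lactate")
  ii <- resolve_window(tc, window)
  total <- series_mM(tc, "lactate", constants)
  lab <- convert_concentration(tc$labeled_lactate$values,
                               tc$labeled_lactate$unit, "lactate", constants)
  d_total <- total[ii[2]] - total[ii[1]]
  if (d_total <= 0) stop("total lactate accumulation over window is <= 0")
  d_lab <- lab[ii[2]] - lab[ii[1]]

  background <- 0
  corrected <- FALSE
  if (!is.null(control_tc)) {
    if (is.null(control_tc$labeled_lactate))
      stop("control time course has no labeled_lactate")
    jj <- resolve_window(control_tc, tc$times[ii])
    clab <- convert_concentration(control_tc$labeled_lactate$values,
                                  control_tc$labeled_lactate$unit, "lactate",
                                  constants)
    background <- clab[jj[2]] - clab[jj[1]]
    corrected <- TRUE
  }
  num <- d_lab - background
  clipped <- FALSE
  if (num < 0) {
    warning("background exceeds labeled-lactate accumulation; clipping to 0")
    num <- 0
    clipped <- TRUE
  }
  structure(num / d_total, corrected = corrected, clipped = clipped)
}

#' Assemble a strain rate table from a time course
#'
#' Runs [specific_rate()] for the five core species and, when a labeled
#' series is present, [label_fraction_from_timecourse()], returning a
#' [strain_rate_table()] ready for flux inference. CO2 uptake is left absent
#' (to be inferred), except for control strains where it is set to 0.
#'
#' @inheritParams specific_rate
#' @inheritParams label_fraction_from_timecourse
#' @param strain a [strain_config()].
#' @return A validated [strain_rate_table()].
#' @export
rates_from_timecourse <- function(tc, strain, window = NULL,
                                  control_tc = NULL,
                                  constants = network_constants(),
                                  biomass_mode = "constant",
                                  method = "endpoint") {
  get <- function(sp) specific_rate(tc, sp, window, constants,
                                    biomass_mode, method)
  lf <- NULL
  if (!is.null(tc$labeled_lactate) && !is_control_strain(strain))
    lf <- as.numeric(label_fraction_from_timecourse(tc, window, control_tc,
                                                    constants))
  tab <- strain_rate_table(strain,
                           xylose = get("xylose"), glycerol = get("glycerol"),
                           lactate = get("lactate"), acetate = get("acetate"),
                           ethanol = get("ethanol"),
                           co2_uptake = if (is_control_strain(strain)) 0 else NULL,
                           label_fraction = lf)
  validate_rate_table(tab, constants)
}
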