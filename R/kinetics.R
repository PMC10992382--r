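#' Carboxylation assay dataset
#'
#' CO2 concentrations (uM) versus per-active-site carboxylation rates (s^-1),
#' optionally tagged by replicate.
#'
#' @param conc CO2 concentrations in uM, > 0.
#' @param rate carboxylation rates in s^-1, >= 0, same length.
#' @param replicate optional replicate identifiers.
#' @return An object of class `kinetic_dataset`.
#' @export
kinetic_dataset <- function(conc, rate, replicate = NULL) {
  stopifnot(is.numeric(conc), is.numeric(rate),
            length(conc) == length(rate), length(conc) >= 2)
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (any(rate < 0)) stop("rates must be non-negative")
  if (!is.null(replicate) && length(replicate) != length(conc))
    stop("replicate has wrong length")
  structure(list(conc = as.numeric(conc), rate = as.numeric(rate),
                 replicate = replicate),
            class = "kinetic_dataset")
}

new_kinetic_params <- function(kcat, kcat_sd, km, km_sd, eff, eff_sd,
                               fit = NULL) {
  stopifnot(kcat > 0, km > 0)
  if (abs(eff - kcat / km * 1000) > 1e-9 * eff)
    stop("efficiency inconsistent with kcat/km")
  structure(list(kcat_c = kcat, kcat_sd = kcat_sd, km_c = km, km_sd = km_sd,
                 efficiency = eff, efficiency_sd = eff_sd, fit = fit),
            class = "kinetic_params")
}

#' Fit the Michaelis-Menten carboxylation curve
#'
#' Nonlinear least-squares fit of `v = kcat [CO2] / (K_M + [CO2])` via
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]) with positivity bounds.
#' Starting values default to `kcat0 = max(rate)` and `K_M0 =` the
#' concentration whose rate is nearest half-maximal. Parameter standard
#' deviations come from the fit covariance; the catalytic efficiency
#' `kcat/K_M` (s^-1 mM^-1) and its SD follow by first-order propagation
#' using the full parameter covariance.
#'
#' @param data a [kinetic_dataset()]; at least two distinct concentrations
#'   are required (three, spanning the eventual `K_M` estimate, to avoid a
#'   warning).
#' @param init optional named list/vector with starting values `kcat`, `km`.
#' @return An object of class `kinetic_params` with fields `kcat_c`,
#'   `kcat_sd`, `km_c`, `km_sd`, `efficiency`, `efficiency_sd` and the
#'   underlying `fit`.
#' @examples
#' grid <- exp(seq(log(30), log(1800), length.out = 13))
#' d <- kinetic_dataset(grid, 16.4 * grid / (172.4 + grid))
#' fit_michaelis_menten(d)$kcat_c
#' @export
fit_michaelis_menten <- function(data, init = NULL) {
  stopifnot(inherits(data, "kinetic_dataset"))
  n_distinct <- length(unique(data$conc))
  if (n_distinct < 2)
    stop("data at a single concentration: parameters are unidentifiable")
  if (n_distinct < 3)
    warning("fewer than 3 distinct concentrations; fit may be poorly determined")
  kcat0 <- if (!is.null(init$kcat)) init$kcat else max(data$rate)
  km0 <- if (!is.null(init$km)) init$km else
    data$conc[which.min(abs(data$rate - max(data$rate) / 2))]
  if (kcat0 <= 0) kcat0 <- 1
  if (km0 <= 0) km0 <- stats::median(data$conc)
  conc <- data$conc
  rate <- data$rate
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(kcat = kcat0, km = km0),
                       lower = c(kcat = 1e-12, km = 1e-12),
                       fn = function(p) rate - p[1] * conc / (p[2] + conc),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Michaelis-Menten fit failed to converge: ",
                             conditionMessage(e)))
  if (fit$info == 0 || fit$info == 5)
    stop("Michaelis-Menten fit failed to converge: ", fit$message)
  kcat <- fit$par[["kcat"]]; km <- fit$par[["km"]]
  # covariance = sigma^2 (J'J)^-1; nls.lm's hessian is the J'J approximation
  dof <- max(length(rate) - 2L, 1L)
  sigma2 <- fit$deviance / dof
  vc <- tryCatch(sigma2 * solve(fit$hessian),
                 error = function(e) matrix(0, 2, 2))
  vc[!is.finite(vc)] <- 0
  if (km < min(data$conc) || km > max(data$conc))
    warning("K_M estimate (", signif(km, 4),
            " uM) lies outside the assayed concentration range")
  eff <- catalytic_efficiency(kcat, km)
  grad <- c(1000 / km, -1000 * kcat / km^2)
  eff_var <- drop(t(grad) %*% vc %*% grad)
  new_kinetic_params(kcat, sqrt(max(vc[1, 1], 0)), km,
                     sqrt(max(vc[2, 2], 0)), eff,
                     sqrt(max(eff_var, 0)), fit)
}

#' Carboxylation catalytic efficiency
#'
#' `kcat / K_M` with the uM to mM conversion, i.e. s^-1 mM^-1.
#'
#' @param kcat_c turnover number, s^-1.
#' @param km_c Michaelis constant for CO2, uM, > 0.
#' @return Efficiency in s^-1 mM^-1.
#' @examples
#' catalytic_efficiency(16.4, 172.4) # 95.1
#' @export
catalytic_efficiency <- function(kcat_c, km_c) {
  if (any(km_c <= 0)) stop("km_c must be positive")
  kcat_c / km_c * 1000
}

#' Relative change in percent
#'
#' @param a new value.
#' @param b reference value, nonzero.
#' @return `(a - b) / b * 100`.
#' @examples
#' relative_change(95.1, 63.2) # +50.5
#' @export
relative_change <- function(a, b) {
  if (b == 0) stop("reference value is zero")
  (a - b) / b * 100
}

#' Turnover number from a fixed-CO2 measurement
#'
#' Molar amount of CO2 fixed divided by the molar amount of active sites
#' (titrated with the transition-state analogue CABP) per second.
#'
#' @param fixed_co2 nmol CO2 fixed over the assay.
#' @param active_sites nmol active sites, > 0.
#' @param duration assay duration in seconds, > 0.
#' @return Turnover number in s^-1.
#' @examples
#' turnover_number(19.68, 0.01, 120) # 16.4
#' @export
turnover_number <- function(fixed_co2, active_sites, duration) {
  if (active_sites <= 0) stop("active_sites must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (fixed_co2 < 0) stop("fixed_co2 must be >= 0")
  fixed_co2 / active_sites / duration
}

#' Rubisco fraction of cellular soluble protein (%CSP)
#'
#' Converts CABP-titrated active sites to a protein mass (nmol sites times
#' the molar mass attributed to one site, in ug) and expresses it as a
#' percentage of the total cellular soluble protein. Because CABP counts
#' sites rather than holoenzymes, the default convention attributes one
#' large subunit per site (hexamer mass / 6); pass the holoenzyme mass with
#' sites divided accordingly to use the other convention.
#'
#' @param active_sites nmol active sites.
#' @param site_molar_mass g/mol of protein attributed per site (default
#'   322000/6, one large subunit of a 322 kDa hexamer).
#' @param total_csp total cellular soluble protein, mg, > 0.
#' @return Percentage of cellular soluble protein.
#' @examples
#' csp_fraction(2.38, 50500, 1.0) # 12.0
#' @export
csp_fraction <- function(active_sites, site_molar_mass = 322000 / 6,
                         total_csp) {
  if (total_csp <= 0) stop("total_csp must be positive")
  if (active_sites < 0 || site_molar_mass <= 0)
    stop("active_sites must be >= 0 and site_molar_mass > 0")
  # nmol * (g/mol) / 1000 = ug of protein; total_csp mg -> ug
  active_sites * site_molar_mass / 1000 / (total_csp * 1000) * 100
}

#' Specific carboxylation activity of a crude extract
#'
#' nmol CO2 fixed per minute per mg of total cellular soluble protein.
#'
#' @param fixed_co2 nmol CO2 fixed.
#' @param duration assay duration in minutes, > 0.
#' @param total_csp total cellular soluble protein, mg, > 0.
#' @return Specific activity, nmol min^-1 mg^-1.
#' @examples
#' specific_activity(164, 2, 0.1) # 820
#' @export
specific_activity <- function(fixed_co2, duration, total_csp) {
  if (duration <= 0) stop("duration must be positive")
  if (total_csp <= 0) stop("total_csp must be positive")
  if (fixed_co2 < 0) stop("fixed_co2 must be >= 0")
  fixed_co2 / duration / total_csp
}

#' Expression quantitation from a CABP titration
#'
#' Bundles the active-site count with the derived %CSP and, when a fixed-CO2
#' measurement is supplied, the specific activity of the extract.
#'
#' @inheritParams csp_fraction
#' @param fixed_co2 optional nmol CO2 fixed (for specific activity).
#' @param duration_min assay duration in minutes (with `fixed_co2`).
#' @return An object of class `expression_quant` with fields `active_sites`,
#'   `site_molar_mass`, `total_csp`, `csp_percent` and (optionally)
#'   `specific_activity`.
#' @export
expression_quant <- function(active_sites, site_molar_mass = 322000 / 6,
                             total_csp, fixed_co2 = NULL,
                             duration_min = NULL) {
  csp <- csp_fraction(active_sites, site_molar_mass, total_csp)
  sa <- NULL
  if (!is.null(fixed_co2)) {
    if (is.null(duration_min))
      stop("duration_min is required with fixed_co2")
    sa <- specific_activity(fixed_co2, duration_min, total_csp)
  }
  structure(list(active_sites = active_sites,
                 site_molar_mass = site_molar_mass,
                 total_csp = total_csp, csp_percent = csp,
                 specific_activity = sa),
            class = "expression_quant")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("kcat_c      %7.2f +/- %.2f s^-1\n", x$kcat_c, x$kcat_sd))
  cat(sprintf("K_M_c       %7.1f +/- %.1f uM\n", x$km_c, x$km_sd))
  cat(sprintf("kcat/K_M    %7.1f +/- %.1f s^-1 mM^-1\n",
              x$efficiency, x$efficiency_sd))
  invisible(x)
}
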