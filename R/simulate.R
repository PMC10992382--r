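#' Configuration for a synthetic capture fermentation
#'
#' Describes a resting-cell batch with known ground truth: constant biomass,
#' constant specific rates, labeled lactate accumulating at the fraction the
#' labeling model predicts plus an unlabeled-background term, and optional
#' Gaussian measurement noise on concentrations.
#'
#' By default the lactate rate is set to the carbon-conserving value
#' `((5 xyl + 3 gly + x2)/3 - acetate - ethanol)` so that every noiseless
#' simulation satisfies carbon recovery = 1 under the ledger model; pass
#' `lactate_rate` explicitly to simulate a model-inconsistent (leaky)
#' fermentation.
#'
#' @param xyl_total,gly_total,x2 true substrate and bypass fluxes,
#'   mmol gDCW^-1 h^-1 (`0 <= x2 <= xyl_total`).
#' @param acetate_rate,ethanol_rate by-product formation rates.
#' @param lactate_rate lactate formation rate, or `NULL` for the
#'   carbon-conserving default.
#' @param background_label_rate labeled-lactate accumulation rate of the
#'   unlabeled background, mM h^-1 (what a control strain shows).
#' @param od600 constant biomass level (default 2.0).
#' @param sample_times sampling grid in hours (default 0 to 72 h every 6 h).
#' @param initial_mM named vector of initial concentrations in mM; defaults
#'   to the capture medium (5 g/L xylose, 6.13 g/L glycerol, products at 0).
#' @param noise_cv coefficient of variation of the Gaussian measurement
#'   noise, a single number or a named per-species vector (default 0).
#' @param seed integer seed; draws are deterministic given the seed.
#' @param constants a [network_constants()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(xyl_total, gly_total, x2,
                              acetate_rate = 0, ethanol_rate = 0,
                              lactate_rate = NULL,
                              background_label_rate = 0,
                              od600 = 2.0,
                              sample_times = seq(0, 72, by = 6),
                              initial_mM = NULL,
                              noise_cv = 0, seed = 1L,
                              constants = network_constants()) {
  stopifnot(xyl_total >= 0, gly_total >= 0, x2 >= 0,
            acetate_rate >= 0, ethanol_rate >= 0,
            background_label_rate >= 0, od600 > 0)
  if (x2 > xyl_total) stop("x2 exceeds xyl_total")
  if (length(sample_times) < 2 || any(diff(sample_times) <= 0))
    stop("sample_times must be strictly increasing, length >= 2")
  if (any(noise_cv < 0)) stop("noise_cv must be >= 0")
  if (is.null(lactate_rate))
    lactate_rate <- (5 * xyl_total + 3 * gly_total + x2) / 3 -
      acetate_rate - ethanol_rate
  if (lactate_rate < 0)
    stop("infeasible configuration: implied lactate rate is negative")
  if (is.null(initial_mM))
    initial_mM <- c(xylose = 5 / constants$molar_mass[["xylose"]] * 1000,
                    glycerol = 6.13 / constants$molar_mass[["glycerol"]] * 1000,
                    lactate = 0, acetate = 0, ethanol = 0)
  structure(list(xyl_total = xyl_total, gly_total = gly_total, x2 = x2,
                 lactate_rate = lactate_rate, acetate_rate = acetate_rate,
                 ethanol_rate = ethanol_rate,
                 background_label_rate = background_label_rate,
                 od600 = od600, sample_times = sample_times,
                 initial_mM = initial_mM, noise_cv = noise_cv,
                 seed = as.integer(seed), constants = constants),
            class = "simulation_config")
}

cv_for <- function(noise_cv, species) {
  if (!is.null(names(noise_cv)) && species %in% names(noise_cv))
    return(noise_cv[[species]])
  if (is.null(names(noise_cv))) return(noise_cv[[1]])
  0
}

#' Simulate a capture fermentation with known ground truth
#'
#' Concentrations evolve linearly at the configured specific rates times the
#' (constant) biomass density; substrates are clipped at zero on exhaustion.
#' Labeled lactate accumulates at `r_3pga` times the lactate formation rate
#' plus the background rate. Gaussian noise with the per-species CV is
#' applied to each observed concentration and truncated at zero.
#'
#' @param cfg a [simulation_config()].
#' @return A list with elements `timecourse` (a [time_course()]), `truth`
#'   (the generating [strain_rate_table()], labeled fraction included) and
#'   `partition` (the generating [flux_partition]).
#' @export
simulate_fermentation <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  nc <- cfg$constants
  t <- cfg$sample_times
  biomass <- cfg$od600 * nc$dcw_per_od  # gDCW/L

  partition <- if (cfg$xyl_total + cfg$gly_total > 0 &&
                   (5 / 3) * (cfg$xyl_total - cfg$x2) + cfg$gly_total +
                   2 * cfg$x2 > 0)
    forward_label_fraction(cfg$x2, cfg$xyl_total, cfg$gly_total)
  else new_flux_partition(0, 0, 0, 0, cfg$xyl_total, cfg$gly_total)

  traj <- function(sp, rate, sign) {
    pmax(0, cfg$initial_mM[[sp]] + sign * rate * biomass * t)
  }
  clean <- list(xylose = traj("xylose", cfg$xyl_total, -1),
                glycerol = traj("glycerol", cfg$gly_total, -1),
                lactate = traj("lactate", cfg$lactate_rate, +1),
                acetate = traj("acetate", cfg$acetate_rate, +1),
                ethanol = traj("ethanol", cfg$ethanol_rate, +1))
  labeled <- partition$r_3pga * cfg$lactate_rate * biomass * t +
    cfg$background_label_rate * t

  noisy <- function(v, sp) {
    cv <- cv_for(cfg$noise_cv, sp)
    if (cv <= 0) return(v)
    pmax(0, v + stats::rnorm(length(v), 0, cv * v))
  }
  conc <- lapply(names(clean), function(sp)
    conc_series(noisy(clean[[sp]], sp), "mM"))
  names(conc) <- names(clean)
  labeled_obs <- conc_series(noisy(labeled, "lactate"), "mM")

  tc <- time_course(t, rep(cfg$od600, length(t)), conc, labeled_obs)
  truth <- strain_rate_table(
    strain_config("synthetic", rubisco_active = cfg$x2 > 0),
    xylose = cfg$xyl_total, glycerol = cfg$gly_total,
    lactate = cfg$lactate_rate, acetate = cfg$acetate_rate,
    ethanol = cfg$ethanol_rate, co2_uptake = cfg$x2,
    label_fraction = partition$r_3pga)
  list(timecourse = tc, truth = truth, partition = partition)
}

#' Simulate a Michaelis-Menten carboxylation assay
#'
#' Rates follow `kcat c / (km + c)` times unit-mean lognormal noise with the
#' requested coefficient of variation, independently per replicate and
#' concentration. Deterministic given the seed.
#'
#' @param kcat,km true parameters (s^-1, uM).
#' @param conc_grid CO2 concentrations in uM; defaults to 13 log-spaced
#'   points over the 30-1800 uM assay range.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param replicates replicates per concentration, >= 1.
#' @param seed integer seed.
#' @return A [kinetic_dataset()].
#' @export
simulate_kinetic_assay <- function(kcat, km,
                                   conc_grid = exp(seq(log(30), log(1800),
                                                       length.out = 13)),
                                   noise_cv = 0, replicates = 1, seed = 1L) {
  stopifnot(kcat >= 0, km > 0, replicates >= 1, noise_cv >= 0)
  if (length(conc_grid) == 0) stop("conc_grid is empty")
  if (any(conc_grid <= 0)) stop("conc_grid must be positive")
  set.seed(as.integer(seed))
  conc <- rep(conc_grid, times = replicates)
  rep_id <- rep(seq_len(replicates), each = length(conc_grid))
  v <- kcat * conc / (km + conc)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    v <- v * stats::rlnorm(length(v), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  kinetic_dataset(conc, v, rep_id)
}

#' Ideal stoichiometric rate table
#'
#' The table implied by the overall conversion
#' xylose + 2 glycerol + CO2 -> 4 lactate: rates in molar ratio 1:2:1:4 with
#' no acetate or ethanol. Its carbon books close exactly (12 C in, 12 C out)
#' and all xylose runs through the bypass, giving a labeled fraction of 1/4
#' and an NADH ratio of exactly 1 (the feasibility boundary).
#'
#' @param scale multiplies all rates (mmol gDCW^-1 h^-1 per unit).
#' @return A [strain_rate_table()].
#' @export
ideal_stoichiometry_table <- function(scale = 1) {
  stopifnot(scale > 0)
  strain_rate_table(strain_config("ideal"),
                    xylose = 1 * scale, glycerol = 2 * scale,
                    lactate = 4 * scale, acetate = 0, ethanol = 0,
                    co2_uptake = 1 * scale,
                    label_fraction = 0.25)
}
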