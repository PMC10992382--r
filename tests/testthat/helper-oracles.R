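# independent oracles and shared fixtures, built in code

# bisection root-finding on r(x2) = target, independent of the closed-form
# inversion it cross-checks
bisect_x2 <- function(xyl, gly, r_target, tol = 1e-13) {
  f <- function(x2) {
    x1 <- xyl - x2
    x3 <- (5 / 3) * x1 + gly
    x2 / (x3 + 2 * x2) - r_target
  }
  lo <- 0
  hi <- xyl
  if (f(hi) < 0) return(NA_real_) # target unreachable within substrate supply
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# the published per-strain rates, rebuilt in code (unit tests use these;
# IO tests read the same numbers from the packaged CSV)
ref_tables <- function() {
  list(
    "197-2021" = strain_rate_table(
      strain_config("197-2021", rubisco_active = FALSE, prk_active = FALSE),
      xylose = rate_measurement(0.41, 0.01),
      glycerol = rate_measurement(0.18, 0.03),
      lactate = rate_measurement(0.57, 0.02, "production"),
      acetate = rate_measurement(0.11, 0.01, "production"),
      ethanol = rate_measurement(0.01, 0.002, "production"),
      co2_uptake = 0),
    "7002" = strain_rate_table(
      strain_config("7002"),
      xylose = rate_measurement(0.67, 0.03),
      glycerol = rate_measurement(0.28, 0.06),
      lactate = rate_measurement(0.89, 0.03, "production"),
      acetate = rate_measurement(0.11, 0.02, "production"),
      ethanol = rate_measurement(0.06, 0.01, "production"),
      co2_uptake = rate_measurement(0.05, 0.002)),
    "RPE" = strain_rate_table(
      strain_config("RPE"),
      xylose = rate_measurement(0.50, 0.11),
      glycerol = rate_measurement(0.46, 0.07),
      lactate = rate_measurement(1.01, 0.11, "production"),
      acetate = rate_measurement(0.18, 0.02, "production"),
      ethanol = rate_measurement(0.06, 0.01, "production"),
      co2_uptake = rate_measurement(0.18, 0.04)))
}

mm_grid <- function() exp(seq(log(30), log(1800), length.out = 13))
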