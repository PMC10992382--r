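nc <- network_constants()

test_that("concentration conversion follows molar mass and passes mM through", {
  expect_equal(convert_concentration(0.49, "gL", "lactate", nc),
               0.49 / 90.08 * 1000, tolerance = 1e-12)
  expect_equal(round(convert_concentration(0.49, "gL", "lactate", nc), 2),
               5.44)
  expect_equal(round(convert_concentration(2.8, "gL", "xylose", nc), 2),
               18.65)
  expect_equal(convert_concentration(0, "gL", "ethanol", nc), 0)
  expect_identical(convert_concentration(7.3, "mM", "anything", nc), 7.3)
  expect_error(convert_concentration(1, "gL", "rubp", nc), "molar mass")
  expect_error(convert_concentration(1, "mol", "lactate", nc), "unknown")
})

test_that("specific rate is the biomass-normalised difference quotient", {
  tc <- time_course(c(60, 66, 72), c(2, 2, 2),
                    list(lactate = conc_series(c(10, 13, 16), "mM"),
                         xylose = conc_series(c(12, 10.5, 9), "mM"),
                         flat = conc_series(c(5, 5, 5), "mM")))
  r <- specific_rate(tc, "lactate", c(60, 72), nc)
  expect_equal(r$value, 6 / 12 / 0.6, tolerance = 1e-12)
  expect_equal(r$direction, "production")
  rx <- specific_rate(tc, "xylose", c(60, 72), nc)
  expect_equal(rx$value, 3 / 12 / 0.6, tolerance = 1e-12)
  expect_equal(rx$direction, "consumption")
  expect_equal(specific_rate(tc, "flat", c(60, 72), nc)$value, 0)
  # least-squares slope agrees on exactly linear data
  expect_equal(specific_rate(tc, "lactate", c(60, 72), nc, method = "lm")$value,
               r$value, tolerance = 1e-9)
  expect_error(specific_rate(tc, "lactate", c(0, 72), nc), "window")
  expect_error(specific_rate(tc, "lactate", c(60, 70), nc), "sample time")
})

test_that("specific rate is invariant to the declared concentration unit", {
  t <- seq(0, 72, by = 12)
  lac_mM <- 0.9 * t
  tc_mM <- time_course(t, rep(2, length(t)),
                       list(lactate = conc_series(lac_mM, "mM")))
  tc_gL <- time_course(t, rep(2, length(t)),
                       list(lactate = conc_series(lac_mM * 90.08 / 1000,
                                                  "gL")))
  r1 <- specific_rate(tc_mM, "lactate", constants = nc)
  r2 <- specific_rate(tc_gL, "lactate", constants = nc)
  expect_equal(r1$value, r2$value, tolerance = 1e-9)
})

test_that("doubling the DCW factor exactly halves every rate", {
  sim <- simulate_fermentation(simulation_config(0.5, 0.46, 0.18,
                                                 acetate_rate = 0.1))
  nc2 <- network_constants(dcw_per_od = 0.6)
  for (sp in c("xylose", "glycerol", "lactate")) {
    r1 <- specific_rate(sim$timecourse, sp, constants = nc)
    r2 <- specific_rate(sim$timecourse, sp, constants = nc2)
    expect_equal(r2$value, r1$value / 2, tolerance = 1e-12)
  }
})

test_that("noiseless constant-rate simulations are recovered on any window", {
  cfg <- simulation_config(0.5, 0.46, 0.18, acetate_rate = 0.18,
                           ethanol_rate = 0.06)
  sim <- simulate_fermentation(cfg)
  for (win in list(NULL, c(0, 72), c(12, 36), c(6, 18))) {
    expect_equal(specific_rate(sim$timecourse, "xylose", win, nc)$value,
                 0.5, tolerance = 1e-9)
    expect_equal(specific_rate(sim$timecourse, "lactate", win, nc)$value,
                 cfg$lactate_rate, tolerance = 1e-9)
  }
  # per-sample biomass mode agrees at constant biomass
  expect_equal(specific_rate(sim$timecourse, "glycerol", NULL, nc,
                             biomass_mode = "per_sample")$value,
               0.46, tolerance = 1e-9)
})

test_that("labeled fraction is the background-corrected accumulation ratio", {
  t <- c(60, 72)
  tc <- time_course(t, c(2, 2),
                    list(lactate = conc_series(c(0, 3.007), "mM")),
                    labeled_lactate = conc_series(c(0, 0.40), "mM"))
  r <- label_fraction_from_timecourse(tc, c(60, 72), constants = nc)
  expect_equal(as.numeric(r), 0.40 / 3.007, tolerance = 1e-12)
  expect_equal(round(as.numeric(r), 4), 0.133)
  expect_false(attr(r, "corrected"))

  ctrl <- time_course(t, c(2, 2),
                      list(lactate = conc_series(c(0, 1.0), "mM")),
                      labeled_lactate = conc_series(c(0, 0.40), "mM"))
  r0 <- label_fraction_from_timecourse(tc, c(60, 72), ctrl, nc)
  expect_equal(as.numeric(r0), 0)
  expect_true(attr(r0, "corrected"))

  flat <- time_course(t, c(2, 2),
                      list(lactate = conc_series(c(3, 3), "mM")),
                      labeled_lactate = conc_series(c(0, 0.1), "mM"))
  expect_error(label_fraction_from_timecourse(flat, c(60, 72), constants = nc),
               "accumulation")
})

test_that("a full strain table assembles from a time course", {
  sim <- simulate_fermentation(simulation_config(0.5, 0.46, 0.18,
                                                 acetate_rate = 0.18,
                                                 ethanol_rate = 0.06))
  tab <- rates_from_timecourse(sim$timecourse, strain_config("RPE"),
                               window = c(0, 72))
  expect_s3_class(tab, "strain_rate_table")
  expect_equal(rate_value(tab, "xylose"), 0.5, tolerance = 1e-9)
  expect_equal(tab$label_fraction, sim$partition$r_3pga, tolerance = 1e-9)
  expect_false(has_co2_uptake(tab))
})
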