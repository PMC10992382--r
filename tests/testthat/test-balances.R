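tabs <- ref_tables()

test_that("carbon ledger reproduces the published totals and recoveries", {
  printed <- list("197-2021" = c(cons = 2.59, prod = 2.07, rel = 0.12,
                                 rec = 0.80),
                  "7002" = c(cons = 4.24, prod = 3.18, rel = 0.17,
                             rec = 0.75),
                  "RPE" = c(cons = 4.06, prod = 3.75, rel = 0.24,
                            rec = 0.92))
  for (st in names(tabs)) {
    led <- carbon_ledger(tabs[[st]])
    expect_equal(round_half_out(led$total_consumption, 2),
                 printed[[st]][["cons"]], info = st)
    expect_equal(round_half_out(led$total_production, 2),
                 printed[[st]][["prod"]], info = st)
    expect_equal(round_half_out(led$released_co2, 2),
                 printed[[st]][["rel"]], info = st)
    expect_equal(round_half_out(led$recovery, 2),
                 printed[[st]][["rec"]], info = st)
  }
})

test_that("the ideal stoichiometric conversion conserves carbon exactly", {
  led <- carbon_ledger(ideal_stoichiometry_table())
  expect_equal(led$total_consumption, 12)
  expect_equal(led$total_production, 12)
  expect_equal(led$recovery, 1.0, tolerance = 1e-12)
})

test_that("carbon ledger guards its preconditions", {
  tab <- strain_rate_table(strain_config("x"), 0.5, 0.4, 1, 0.1, 0.1)
  expect_error(carbon_ledger(tab), "co2_uptake is absent")
  zero <- strain_rate_table(strain_config("z", FALSE, FALSE),
                            0, 0, 0, 0, 0, co2_uptake = 0)
  expect_error(carbon_ledger(zero), "consumption is zero")
})

test_that("NADH ledger reproduces the published ratios", {
  printed <- c("197-2021" = 0.56, "7002" = 0.60, "RPE" = 0.74)
  for (st in names(tabs)) {
    tab <- tabs[[st]]
    p <- forward_label_fraction(rate_value(tab, "co2"),
                                rate_value(tab, "xylose"),
                                rate_value(tab, "glycerol"))
    led <- redox_ledger(tab, p)
    expect_equal(round_half_out(led$ratio, 2), printed[[st]], info = st)
    expect_true(led$feasible)
  }
})

test_that("NADH ledger terms follow the one-per-reaction convention", {
  tab <- tabs[["RPE"]]
  p <- forward_label_fraction(0.18, 0.50, 0.46)
  led <- redox_ledger(tab, p)
  expect_equal(led$nadh_consumption, 1.01 + 0.06, tolerance = 1e-12)
  expect_equal(led$nadh_production, 0.46 + p$x3, tolerance = 1e-12)
  # the ideal conversion sits exactly on the feasibility boundary
  ideal <- ideal_stoichiometry_table()
  pi <- forward_label_fraction(1, 1, 2)
  li <- redox_ledger(ideal, pi)
  expect_equal(li$ratio, 1.0, tolerance = 1e-12)
  expect_true(li$feasible)
  # all products zero: ratio 0, feasible
  quiet <- strain_rate_table(strain_config("q"), 0.1, 0.1, 0, 0, 0,
                             co2_uptake = 0)
  lq <- redox_ledger(quiet, forward_label_fraction(0, 0.1, 0.1))
  expect_equal(lq$ratio, (0) / lq$nadh_production)
  expect_true(lq$feasible)
  # mismatched partition is refused
  expect_error(redox_ledger(tab, forward_label_fraction(0.05, 0.67, 0.28)),
               "do not match")
})

test_that("recovery and NADH ratio are scale-invariant (degree-0 homogeneous)", {
  for (c_scale in c(0.1, 3, 42)) {
    tab <- tabs[["RPE"]]
    for (sp in names(tab$rates)) tab$rates[[sp]]$value <-
        tab$rates[[sp]]$value * c_scale
    led <- carbon_ledger(tab)
    base <- carbon_ledger(tabs[["RPE"]])
    expect_equal(led$recovery, base$recovery, tolerance = 1e-12)
    p <- forward_label_fraction(rate_value(tab, "co2"),
                                rate_value(tab, "xylose"),
                                rate_value(tab, "glycerol"))
    p0 <- forward_label_fraction(0.18, 0.50, 0.46)
    expect_equal(redox_ledger(tab, p)$ratio,
                 redox_ledger(tabs[["RPE"]], p0)$ratio, tolerance = 1e-12)
  }
})

test_that("Monte-Carlo propagation degenerates exactly with zero SDs", {
  tab <- tabs[["RPE"]]
  for (sp in names(tab$rates)) tab$rates[[sp]]$sd <- 0
  out <- monte_carlo_propagate(carbon_ledger, tab, n_draws = 1000, seed = 3)
  expect_true(all(out$sd == 0))
  led <- carbon_ledger(tab)
  expect_equal(out$mean[out$quantity == "recovery"], led$recovery)
  expect_error(monte_carlo_propagate(carbon_ledger, tab, n_draws = 10),
               "1000")
})

test_that("Monte-Carlo SDs match closed forms for sums and ratios", {
  # sum of two independent N(1, 0.1^2): SD = sqrt(0.02) = 0.1414
  tab <- strain_rate_table(strain_config("mc"),
                           xylose = rate_measurement(1, 0.1),
                           glycerol = rate_measurement(1, 0.1),
                           lactate = 0, acetate = 0, ethanol = 0,
                           co2_uptake = 0)
  fn_sum <- function(t) c(total = rate_value(t, "xylose") +
                            rate_value(t, "glycerol"))
  out <- monte_carlo_propagate(fn_sum, tab, n_draws = 1e5, seed = 10)
  # 3 sigma of the SD estimator: sd/sqrt(2n) ~ 3.2e-4
  expect_equal(out$sd, sqrt(0.02), tolerance = 3 * sqrt(0.02) /
                 sqrt(2 * 1e5) / sqrt(0.02))

  # ratio N(2, 0.1^2) / N(4, 0.2^2): first-order delta method gives
  # 0.5 * sqrt((0.1/2)^2 + (0.2/4)^2) = 0.03536
  tab2 <- strain_rate_table(strain_config("mc2"),
                            xylose = rate_measurement(4, 0.2),
                            glycerol = 0,
                            lactate = rate_measurement(2, 0.1, "production"),
                            acetate = 0, ethanol = 0, co2_uptake = 0)
  fn_ratio <- function(t) c(ratio = rate_value(t, "lactate") /
                              rate_value(t, "xylose"))
  out2 <- monte_carlo_propagate(fn_ratio, tab2, n_draws = 1e5, seed = 11)
  delta_sd <- 0.5 * sqrt((0.1 / 2)^2 + (0.2 / 4)^2)
  expect_equal(out2$sd, delta_sd, tolerance = 0.05)
})

test_that("Monte-Carlo propagation is deterministic given the seed", {
  tab <- tabs[["7002"]]
  a <- monte_carlo_propagate(carbon_ledger, tab, n_draws = 2000, seed = 99)
  b <- monte_carlo_propagate(carbon_ledger, tab, n_draws = 2000, seed = 99)
  expect_identical(a, b)
  # propagated SDs land on the printed scale for the published inputs
  expect_lt(abs(a$sd[a$quantity == "total_consumption"] - 0.33), 0.15)
})
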