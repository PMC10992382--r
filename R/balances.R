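#' Carbon-atom ledger
#'
#' Multiplies each specific rate by its carbon-atom count and balances the
#' books. The consumption side is xylose + glycerol + CO2 uptake; the
#' production side is the detected products plus the released CO2, which is
#' estimated as one CO2 per acetate and one per ethanol (the decarboxylation
#' accompanying the dissimilation of pyruvate to a C2 product). Carbon
#' recovery is total production over total consumption.
#'
#' @param table a validated [strain_rate_table()] with a CO2-uptake entry
#'   (set it to 0 for control strains).
#' @param constants a [network_constants()].
#' @return An object of class `carbon_ledger` with fields `carbon_rates`
#'   (named, C-mmol gDCW^-1 h^-1), `released_co2`, `total_consumption`,
#'   `total_production` and `recovery`.
#' @examples
#' tab <- strain_rate_table(strain_config("RPE"), 0.50, 0.46, 1.01, 0.18,
#'                          0.06, co2_uptake = 0.18)
#' carbon_ledger(tab)$recovery # 0.9236
#' @export
carbon_ledger <- function(table, constants = network_constants()) {
  table <- validate_rate_table(table, constants)
  if (!has_co2_uptake(table))
    stop("co2_uptake is absent; infer it first (or set 0 for controls)")
  crates <- vapply(names(table$rates), function(sp) {
    table$rates[[sp]]$value * constants$carbon_atoms[[sp]]
  }, numeric(1))
  dirs <- vapply(table$rates, function(r) r$direction, character(1))
  released <- rate_value(table, "acetate") + rate_value(table, "ethanol")
  total_cons <- sum(crates[dirs == "consumption"])
  total_prod <- sum(crates[dirs == "production"]) + released
  if (total_cons <= 0) stop("total carbon consumption is zero")
  structure(list(carbon_rates = crates, released_co2 = released,
                 total_consumption = total_cons,
                 total_production = total_prod,
                 recovery = total_prod / total_cons),
            class = "carbon_ledger")
}

#' NADH ledger
#'
#' Accounts one NADH consumed per lactate and per ethanol formed, and one
#' NADH produced per glycerol oxidised and per G3P flux unit through GAPDH.
#' Only `x3` feeds GAPDH: the 3PGA generated by Rubisco enters glycolysis
#' below GAPDH and generates no NADH. The reported quantity is the ratio of
#' NADH consumption to production; the labeling model assumes production >=
#' consumption, so `feasible` flags whether the ratio is <= 1.
#'
#' @param table a validated [strain_rate_table()].
#' @param partition the strain's [flux_partition] (supplies `x3`); its
#'   substrate fluxes must match the table.
#' @param constants a [network_constants()].
#' @return An object of class `redox_ledger` with fields `nadh_consumption`,
#'   `nadh_production`, `ratio` and `feasible`.
#' @export
redox_ledger <- function(table, partition, constants = network_constants()) {
  table <- validate_rate_table(table, constants)
  stopifnot(inherits(partition, "flux_partition"))
  rel_ok <- function(a, b) abs(a - b) <= 1e-6 * max(1, abs(a), abs(b))
  if (!rel_ok(partition$xyl_total, rate_value(table, "xylose")) ||
      !rel_ok(partition$gly_total, rate_value(table, "glycerol")))
    stop("partition substrate fluxes do not match the rate table")
  cons <- sum(vapply(names(constants$nadh_consumed_per), function(sp) {
    rate_value(table, sp) * constants$nadh_consumed_per[[sp]]
  }, numeric(1)))
  prod <- rate_value(table, "glycerol") *
    constants$nadh_produced_per[["glycerol_oxidation"]] +
    partition$x3 * constants$nadh_produced_per[["gapdh"]]
  if (prod <= 0) {
    if (cons > 0) stop("NADH production is zero but consumption is positive")
    ratio <- 0
  } else {
    ratio <- cons / prod
  }
  structure(list(nadh_consumption = cons, nadh_production = prod,
                 ratio = ratio, feasible = ratio <= 1 + 1e-9),
            class = "redox_ledger")
}

#' @export
print.carbon_ledger <- function(x, ...) {
  cat("Carbon ledger (C-mmol gDCW^-1 h^-1):\n")
  for (sp in names(x$carbon_rates))
    cat(sprintf("  %-10s %8.4f\n", sp, x$carbon_rates[[sp]]))
  cat(sprintf("  released CO2       %8.4f\n", x$released_co2))
  cat(sprintf("  total consumption  %8.4f\n", x$total_consumption))
  cat(sprintf("  total production   %8.4f\n", x$total_production))
  cat(sprintf("  carbon recovery    %8.4f\n", x$recovery))
  invisible(x)
}

#' @export
print.redox_ledger <- function(x, ...) {
  cat("NADH ledger (mmol gDCW^-1 h^-1):\n")
  cat(sprintf("  consumption %8.4f\n  production  %8.4f\n  ratio       %8.4f%s\n",
              x$nadh_consumption, x$nadh_production, x$ratio,
              if (x$feasible) "" else "  (infeasible: consumption > production)"))
  invisible(x)
}

# replace measurement values without re-validating (hot path of the MC loop)
set_rate_values <- function(table, values) {
  for (sp in names(values)) table$rates[[sp]]$value <- values[[sp]]
  table
}

ledger_scalars <- function(x) {
  if (inherits(x, "carbon_ledger"))
    return(c(x$carbon_rates,
             released_co2 = x$released_co2,
             total_consumption = x$total_consumption,
             total_production = x$total_production,
             recovery = x$recovery))
  if (inherits(x, "redox_ledger"))
    return(c(nadh_consumption = x$nadh_consumption,
             nadh_production = x$nadh_production, ratio = x$ratio))
  u <- unlist(x)
  u[vapply(u, is.numeric, logical(1))]
}

#' Monte-Carlo uncertainty propagation through a ledger computation
#'
#' Draws each rate in the table independently from a normal distribution with
#' its measured mean and standard deviation, truncated at zero by clamping
#' (a small positive bias for rates within a few SDs of zero), recomputes
#' `fn` for each draw, and summarises every scalar the ledger reports by its
#' sample mean and SD. Deterministic given `seed`.
#'
#' @param fn a function mapping a [strain_rate_table()] to a ledger (e.g.
#'   [carbon_ledger()], [redox_ledger()]) or to a named numeric vector.
#' @param table a [strain_rate_table()] whose `rate_measurement`s carry SDs.
#' @param n_draws number of draws, >= 1000.
#' @param seed integer seed.
#' @return A data.frame with columns `quantity`, `mean`, `sd`.
#' @examples
#' tab <- strain_rate_table(strain_config("RPE"), rate_measurement(0.5, 0.11),
#'                          0.46, 1.01, 0.18, 0.06, co2_uptake = 0.18)
#' head(monte_carlo_propagate(carbon_ledger, tab, n_draws = 1000, seed = 1))
#' @export
monte_carlo_propagate <- function(fn, table, n_draws = 1e5, seed = 1L) {
  stopifnot(is.function(fn), inherits(table, "strain_rate_table"))
  if (n_draws < 1000) stop("n_draws must be at least 1000")
  set.seed(as.integer(seed))
  species <- names(table$rates)
  means <- vapply(species, function(sp) table$rates[[sp]]$value, numeric(1))
  sds <- vapply(species, function(sp) table$rates[[sp]]$sd, numeric(1))
  draws <- matrix(stats::rnorm(n_draws * length(species),
                               mean = rep(means, each = n_draws),
                               sd = rep(sds, each = n_draws)),
                  nrow = n_draws, dimnames = list(NULL, species))
  draws[draws < 0] <- 0
  if (any(!is.finite(draws))) stop("non-finite draws")
  first <- ledger_scalars(fn(set_rate_values(table, draws[1, ])))
  out <- matrix(NA_real_, nrow = n_draws, ncol = length(first),
                dimnames = list(NULL, names(first)))
  out[1, ] <- first
  for (i in 2:n_draws)
    out[i, ] <- ledger_scalars(fn(set_rate_values(table, draws[i, ])))
  data.frame(quantity = colnames(out),
             mean = colMeans(out),
             sd = apply(out, 2, stats::sd),
             row.names = NULL)
}
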