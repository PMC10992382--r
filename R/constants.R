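#' Stoichiometric and physical constants of the capture network
#'
#' Bundles the fixed numbers needed to turn measured rates into carbon-atom
#' and NADH ledgers: carbon-atom counts per molecule, NADH stoichiometry of
#' the lactate/ethanol-forming and glycerol/GAPDH reactions (one NADH per
#' reaction event), the OD600-to-dry-cell-weight conversion, and molar masses
#' for g/L to mM conversion.
#'
#' The defaults describe the engineered d-lactate capture network: xylose and
#' glycerol are consumed, CO2 is taken up by Rubisco, and lactate, acetate and
#' ethanol are the detected products. NADH is consumed once per lactate and
#' once per ethanol formed, and produced once per glycerol oxidised (glycerol
#' to glycerone) and once per G3P passing GAPDH.
#'
#' @param carbon_atoms named integer vector, carbon atoms per molecule of each
#'   species. Every species appearing in a rate table must have an entry.
#' @param nadh_consumed_per named vector, NADH consumed per molecule of each
#'   reduced product.
#' @param nadh_produced_per named vector with entries `glycerol_oxidation`
#'   (NADH per glycerol consumed) and `gapdh` (NADH per G3P flux unit).
#' @param dcw_per_od biomass conversion factor, gDCW per litre per OD600 unit.
#' @param molar_mass named vector, g/mol, used to convert g/L inputs to mM.
#' @return An object of class `network_constants`.
#' @examples
#' nc <- network_constants()
#' nc$carbon_atoms[["xylose"]]
#' @export
network_constants <- function(carbon_atoms = c(xylose = 5L, glycerol = 3L,
                                               lactate = 3L, acetate = 2L,
                                               ethanol = 2L, co2 = 1L),
                              nadh_consumed_per = c(lactate = 1L, ethanol = 1L),
                              nadh_produced_per = c(glycerol_oxidation = 1L,
                                                    gapdh = 1L),
                              dcw_per_od = 0.3,
                              molar_mass = c(lactate = 90.08, xylose = 150.13,
                                             glycerol = 92.09, acetate = 60.05,
                                             ethanol = 46.07)) {
  stopifnot(is.numeric(carbon_atoms), length(carbon_atoms) > 0,
            !is.null(names(carbon_atoms)))
  if (any(carbon_atoms <= 0) || any(carbon_atoms != round(carbon_atoms)))
    stop("carbon_atoms must be positive integers")
  if (any(nadh_consumed_per < 0) || any(nadh_produced_per < 0))
    stop("NADH stoichiometric coefficients must be >= 0")
  if (!all(c("glycerol_oxidation", "gapdh") %in% names(nadh_produced_per)))
    stop("nadh_produced_per needs entries 'glycerol_oxidation' and 'gapdh'")
  if (!is.numeric(dcw_per_od) || length(dcw_per_od) != 1 || dcw_per_od <= 0)
    stop("dcw_per_od must be a single positive number")
  if (any(molar_mass <= 0)) stop("molar masses must be positive")
  structure(list(carbon_atoms = carbon_atoms,
                 nadh_consumed_per = nadh_consumed_per,
                 nadh_produced_per = nadh_produced_per,
                 dcw_per_od = dcw_per_od,
                 molar_mass = molar_mass),
            class = "network_constants")
}

#' Strain description
#'
#' Identifies a strain and records whether its Rubisco and PRK are active.
#' A strain with both inactive is the background control: it cannot run the
#' bypass, so its CO2 uptake is zero and its labeled-lactate signal defines
#' the background subtracted from test strains.
#'
#' @param strain_id unique strain label.
#' @param rubisco_active,prk_active logical flags.
#' @param notes free text.
#' @return An object of class `strain_config`.
#' @export
strain_config <- function(strain_id, rubisco_active = TRUE, prk_active = TRUE,
                          notes = "") {
  stopifnot(is.character(strain_id), length(strain_id) == 1, nzchar(strain_id),
            is.logical(rubisco_active), is.logical(prk_active))
  structure(list(strain_id = strain_id,
                 rubisco_active = isTRUE(rubisco_active),
                 prk_active = isTRUE(prk_active),
                 notes = notes),
            class = "strain_config")
}

#' @rdname strain_config
#' @param x a `strain_config`.
#' @export
is_control_strain <- function(x) {
  stopifnot(inherits(x, "strain_config"))
  !x$rubisco_active && !x$prk_active
}

#' Single specific-rate measurement
#'
#' A rate magnitude in mmol gDCW^-1 h^-1 with its standard deviation and an
#' explicit direction. Magnitudes are stored unsigned; the sign convention
#' lives in `direction` so downstream ledgers never guess.
#'
#' @param value rate magnitude, mmol gDCW^-1 h^-1, >= 0.
#' @param sd standard deviation, same units, >= 0.
#' @param direction `"consumption"` or `"production"`.
#' @return An object of class `rate_measurement`.
#' @export
rate_measurement <- function(value, sd = 0,
                             direction = c("consumption", "production")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(value), length(value) == 1,
            is.numeric(sd), length(sd) == 1)
  if (!is.finite(value) || value < 0) stop("negative rate")
  if (!is.finite(sd) || sd < 0) stop("negative sd")
  structure(list(value = value, sd = sd, direction = direction),
            class = "rate_measurement")
}

as_rate <- function(x, direction) {
  if (inherits(x, "rate_measurement")) return(x)
  rate_measurement(x, 0, direction)
}

# direction each core species must carry (CO2 uptake sits on the
# consumption side of the carbon ledger)
.species_direction <- c(xylose = "consumption", glycerol = "consumption",
                        co2 = "consumption", lactate = "production",
                        acetate = "production", ethanol = "production")

#' Per-strain table of specific rates
#'
#' Collects the measured substrate-consumption and product-formation rates of
#' one strain, plus optionally the CO2-uptake rate (absent means "to be
#' inferred from labeling") and the background-corrected labeled-lactate
#' fraction.
#'
#' @param strain a [strain_config()].
#' @param xylose,glycerol consumption rates (numeric or [rate_measurement()]).
#' @param lactate,acetate,ethanol production rates.
#' @param co2_uptake CO2 uptake rate, or `NULL` if it is to be inferred (set
#'   it to 0 for control strains).
#' @param label_fraction fraction of 13C-labeled lactate in `[0, 1)`, or
#'   `NULL` if unknown.
#' @param extra named list of additional `rate_measurement`s for species
#'   beyond the core network (must have `carbon_atoms` entries to validate).
#' @return An object of class `strain_rate_table`.
#' @examples
#' tab <- strain_rate_table(strain_config("RPE"),
#'                          xylose = 0.50, glycerol = 0.46, lactate = 1.01,
#'                          acetate = 0.18, ethanol = 0.06, co2_uptake = 0.18)
#' rate_value(tab, "xylose")
#' @export
strain_rate_table <- function(strain, xylose, glycerol, lactate, acetate,
                              ethanol, co2_uptake = NULL,
                              label_fraction = NULL, extra = list()) {
  stopifnot(inherits(strain, "strain_config"))
  rates <- list(xylose = as_rate(xylose, "consumption"),
                glycerol = as_rate(glycerol, "consumption"),
                lactate = as_rate(lactate, "production"),
                acetate = as_rate(acetate, "production"),
                ethanol = as_rate(ethanol, "production"))
  if (!is.null(co2_uptake)) rates$co2 <- as_rate(co2_uptake, "consumption")
  if (length(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra))))
      stop("extra rates must be named by species")
    for (sp in names(extra)) rates[[sp]] <- extra[[sp]]
  }
  if (!is.null(label_fraction)) {
    stopifnot(is.numeric(label_fraction), length(label_fraction) == 1)
    if (label_fraction < 0 || label_fraction >= 1)
      stop("label_fraction must lie in [0, 1)")
  }
  structure(list(strain = strain, rates = rates,
                 label_fraction = label_fraction),
            class = "strain_rate_table")
}

#' @rdname strain_rate_table
#' @param table a `strain_rate_table`.
#' @param species species name.
#' @export
rate_value <- function(table, species) {
  r <- table$rates[[species]]
  if (is.null(r)) stop("no rate for species '", species, "'")
  r$value
}

#' @rdname strain_rate_table
#' @export
has_co2_uptake <- function(table) !is.null(table$rates$co2)

#' Validate a strain rate table against the network constants
#'
#' Checks that every species in the table has a carbon-atom entry, that all
#' rate magnitudes and standard deviations are non-negative, that each core
#' species carries its expected direction (substrates and CO2 uptake are
#' consumption, fermentation products production), and that any labeled
#' fraction lies in `[0, 1)`. Rates are already in the canonical
#' mmol gDCW^-1 h^-1 unit, so validation passes values through untouched and
#' is idempotent.
#'
#' @param table a [strain_rate_table()].
#' @param constants a [network_constants()].
#' @return The table, unchanged, if valid; otherwise an error.
#' @export
validate_rate_table <- function(table, constants = network_constants()) {
  stopifnot(inherits(table, "strain_rate_table"),
            inherits(constants, "network_constants"))
  for (sp in names(table$rates)) {
    r <- table$rates[[sp]]
    if (!inherits(r, "rate_measurement"))
      stop("rate for '", sp, "' is not a rate_measurement")
    if (!is.finite(r$value) || r$value < 0)
      stop("negative rate for species '", sp, "'")
    if (!is.finite(r$sd) || r$sd < 0)
      stop("negative sd for species '", sp, "'")
    if (!sp %in% names(constants$carbon_atoms))
      stop("unknown species '", sp, "': no carbon_atoms entry")
    expected <- .species_direction[sp]
    if (!is.na(expected) && r$direction != expected)
      stop("direction mismatch for '", sp, "': expected ", expected)
  }
  if (!is.null(table$label_fraction) &&
      (table$label_fraction < 0 || table$label_fraction >= 1))
    stop("label_fraction must lie in [0, 1)")
  table
}

#' @export
print.strain_rate_table <- function(x, ...) {
  cat("Strain rate table:", x$strain$strain_id,
      if (is_control_strain(x$strain)) "(control)" else "", "\n")
  for (sp in names(x$rates)) {
    r <- x$rates[[sp]]
    cat(sprintf("  %-10s %8.4f +/- %-8.4f %s\n", sp, r$value, r$sd,
                r$direction))
  }
  if (!is.null(x$label_fraction))
    cat(sprintf("  labeled-lactate fraction: %.4f\n", x$label_fraction))
  invisible(x)
}

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (the convention
#' used when comparing derived quantities with values printed at fixed
#' decimal precision), unlike [round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_out(0.125, 2) # 0.13
#' @export
round_half_out <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
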