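#' Read a fermentation time course from CSV
#'
#' The file must have a `time` column (hours), an `od600` column, and one
#' column per species named `<species>_<unit>` with unit suffix `gL` or `mM`
#' (e.g. `lactate_gL`, `xylose_mM`). A `lactate13C_<unit>` column is read as
#' the 13C-labeled lactate series. Rows are sorted by time.
#'
#' @param path CSV file path.
#' @return A [time_course()].
#' @export
read_timecourse_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!"time" %in% names(df)) stop("missing time column")
  if (!"od600" %in% names(df)) stop("missing od600 column")
  if (anyDuplicated(df$time)) stop("duplicate timestamps")
  df <- df[order(df$time), , drop = FALSE]
  conc <- list()
  labeled <- NULL
  for (col in setdiff(names(df), c("time", "od600"))) {
    parts <- regmatches(col, regexec("^(.*)_(gL|mM)$", col))[[1]]
    if (length(parts) != 3)
      stop("unparseable unit suffix in column '", col,
           "' (expected <species>_gL or <species>_mM)")
    sp <- parts[2]; unit <- parts[3]
    if (sp == "lactate13C") {
      labeled <- conc_series(df[[col]], unit)
    } else {
      conc[[sp]] <- conc_series(df[[col]], unit)
    }
  }
  time_course(df$time, df$od600, conc, labeled)
}

#' Write a fermentation time course to CSV
#'
#' Inverse of [read_timecourse_csv()]: one `<species>_<unit>` column per
#' series, labeled lactate as `lactate13C_<unit>`.
#'
#' @param tc a [time_course()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tc, path) {
  stopifnot(inherits(tc, "time_course"))
  df <- data.frame(time = tc$times, od600 = tc$od600)
  for (sp in names(tc$concentrations)) {
    cs <- tc$concentrations[[sp]]
    df[[paste0(sp, "_", cs$unit)]] <- cs$values
  }
  if (!is.null(tc$labeled_lactate))
    df[[paste0("lactate13C_", tc$labeled_lactate$unit)]] <-
      tc$labeled_lactate$values
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

parse_pm_cell <- function(cell) {
  cell <- trimws(cell)
  if (cell %in% c("", "-", "NA", "\u2013")) return(NULL)
  parts <- strsplit(cell, "\u00b1|\\+/-")[[1]]
  vals <- suppressWarnings(as.numeric(trimws(parts)))
  if (length(vals) < 1 || length(vals) > 2 || any(is.na(vals)))
    stop("malformed value cell '", cell, "' (expected 'value \u00b1 sd')")
  c(value = vals[1], sd = if (length(vals) == 2) vals[2] else 0)
}

#' Read a per-strain rate table from CSV
#'
#' Expects species rows by strain columns, the first column named `species`
#' and cells formatted `value +/- sd` (or with a literal plus-minus sign, or a bare value).
#' Recognised species rows: `xylose`, `glycerol`, `co2_uptake`, `lactate`,
#' `acetate`, `ethanol`, and optionally `label_fraction`. An empty or `-`
#' `co2_uptake` cell means the uptake flux is absent; such a strain is
#' flagged as the background control (inactive PRK and Rubisco) and its
#' uptake is taken as zero.
#'
#' @param path CSV file path.
#' @param constants a [network_constants()] used to validate the tables.
#' @return A named list of validated [strain_rate_table()]s, one per strain
#'   column.
#' @export
read_rate_table_csv <- function(path, constants = network_constants()) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        colClasses = "character")
  if (nrow(df) == 0 || ncol(df) < 2) stop("empty rate table")
  if (names(df)[1] != "species") stop("first column must be 'species'")
  known <- c("xylose", "glycerol", "co2_uptake", "lactate", "acetate",
             "ethanol", "label_fraction")
  bad <- setdiff(df$species, known)
  if (length(bad)) stop("unknown species row(s): ", paste(bad, collapse = ", "))
  need <- c("xylose", "glycerol", "lactate", "acetate", "ethanol")
  if (!all(need %in% df$species))
    stop("rate table must contain rows: ", paste(need, collapse = ", "))
  strains <- setdiff(names(df), "species")
  out <- list()
  for (st in strains) {
    cells <- stats::setNames(df[[st]], df$species)
    getm <- function(sp, direction) {
      v <- parse_pm_cell(cells[[sp]])
      if (is.null(v)) return(NULL)
      rate_measurement(v[["value"]], v[["sd"]], direction)
    }
    co2 <- if ("co2_uptake" %in% df$species) getm("co2_uptake", "consumption")
    lf <- if ("label_fraction" %in% df$species) {
      v <- parse_pm_cell(cells[["label_fraction"]])
      if (!is.null(v)) v[["value"]]
    }
    is_ctrl <- is.null(co2) && is.null(lf)
    cfg <- strain_config(st, rubisco_active = !is_ctrl,
                         prk_active = !is_ctrl)
    tab <- strain_rate_table(cfg,
                             xylose = getm("xylose", "consumption"),
                             glycerol = getm("glycerol", "consumption"),
                             lactate = getm("lactate", "production"),
                             acetate = getm("acetate", "production"),
                             ethanol = getm("ethanol", "production"),
                             co2_uptake = if (is_ctrl) 0 else co2,
                             label_fraction = lf)
    out[[st]] <- validate_rate_table(tab, constants)
  }
  out
}

#' Path to the packaged reference rate table
#'
#' A CSV holding the published specific rates of the background control
#' strain (197-2021) and the two capture strains (7002, RPE) of the
#' engineered d-lactate CO2-capture model, in the strain-column layout
#' [read_rate_table_csv()] consumes.
#'
#' @return File path of the packaged CSV.
#' @export
reference_rates_path <- function() {
  system.file("extdata", "capture_strain_rates.csv", package = "rubicap",
              mustWork = TRUE)
}

#' Path to the packaged reference kinetic parameters
#'
#' Published carboxylation kinetic parameters (kcat in s^-1, K_M in uM, with
#' SDs) of the 7002 and RPE Rubiscos.
#'
#' @return File path of the packaged CSV.
#' @export
reference_kinetics_path <- function() {
  system.file("extdata", "capture_kinetics.csv", package = "rubicap",
              mustWork = TRUE)
}

strain_result <- function(table, constants) {
  # establish the bypass flux: printed pass-through, inferred from labeling,
  # or zero for a control strain
  source <- if (is_control_strain(table$strain)) "control (zero)" else
    "measured"
  if (!has_co2_uptake(table)) {
    if (!is.null(table$label_fraction)) {
      p <- infer_flux_partition(rate_value(table, "xylose"),
                                rate_value(table, "glycerol"),
                                table$label_fraction)
      table$rates$co2 <- rate_measurement(p$x2, 0, "consumption")
      source <- "inferred"
    } else if (is_control_strain(table$strain)) {
      table$rates$co2 <- rate_measurement(0, 0, "consumption")
      source <- "control (zero)"
    } else {
      stop("strain '", table$strain$strain_id,
           "': no CO2 uptake and no label fraction to infer it from")
    }
  }
  partition <- forward_label_fraction(rate_value(table, "co2"),
                                      rate_value(table, "xylose"),
                                      rate_value(table, "glycerol"))
  carbon <- carbon_ledger(table, constants)
  redox <- redox_ledger(table, partition, constants)
  list(strain_id = table$strain$strain_id, table = table,
       partition = partition, carbon = carbon, redox = redox,
       bypass_percent = bypass_fraction(partition),
       co2_uptake_source = source)
}

#' Run the full capture-accounting analysis
#'
#' For every strain: establishes the CO2-uptake flux (pass-through if
#' measured, inferred from the labeled-lactate fraction otherwise, zero for
#' the control), computes the flux partition, carbon and NADH ledgers and
#' the bypass fraction, and assembles a summary table in the conventional
#' row order (rates, released CO2, totals, carbon balance, NADH ratio) plus
#' pairwise CO2-uptake fold comparisons between capture strains. The output
#' is deterministic for identical inputs and configuration.
#'
#' @param tables a named list of [strain_rate_table()]s (e.g. from
#'   [read_rate_table_csv()]), or a single table.
#' @param constants a [network_constants()].
#' @return An object of class `capture_analysis` with elements `strains`
#'   (per-strain results), `summary` (data.frame, quantities by strain),
#'   `comparisons` (CO2-uptake fold ratios) and `provenance`.
#' @examples
#' tabs <- read_rate_table_csv(reference_rates_path())
#' rep <- run_capture_analysis(tabs)
#' rep$summary
#' @export
run_capture_analysis <- function(tables, constants = network_constants()) {
  if (inherits(tables, "strain_rate_table")) {
    tables <- stats::setNames(list(tables), tables$strain$strain_id)
  }
  stopifnot(length(tables) >= 1)
  results <- lapply(tables, strain_result, constants = constants)
  names(results) <- vapply(results, `[[`, character(1), "strain_id")

  rows <- c("xylose", "glycerol", "co2_uptake", "lactate", "acetate",
            "ethanol", "released_co2", "total_carbon_consumption",
            "total_carbon_production", "carbon_balance", "nadh_ratio",
            "bypass_percent")
  summary <- data.frame(quantity = rows)
  for (res in results) {
    tab <- res$table
    summary[[res$strain_id]] <- c(
      rate_value(tab, "xylose"), rate_value(tab, "glycerol"),
      rate_value(tab, "co2"), rate_value(tab, "lactate"),
      rate_value(tab, "acetate"), rate_value(tab, "ethanol"),
      res$carbon$released_co2, res$carbon$total_consumption,
      res$carbon$total_production, res$carbon$recovery,
      res$redox$ratio, res$bypass_percent)
  }

  uptakes <- vapply(results, function(r) rate_value(r$table, "co2"),
                    numeric(1))
  comparisons <- NULL
  pos <- names(sort(uptakes[uptakes > 0], decreasing = TRUE))
  if (length(pos) >= 2) {
    pairs <- utils::combn(pos, 2)
    comparisons <- data.frame(
      strain_a = pairs[1, ], strain_b = pairs[2, ],
      co2_uptake_fold = uptakes[pairs[1, ]] / uptakes[pairs[2, ]],
      row.names = NULL)
  }
  structure(list(strains = results, summary = summary,
                 comparisons = comparisons,
                 provenance = list(
                   package_version = as.character(utils::packageVersion("rubicap")),
                   dcw_per_od = constants$dcw_per_od,
                   carbon_atoms = constants$carbon_atoms,
                   nadh_consumed_per = constants$nadh_consumed_per,
                   nadh_produced_per = constants$nadh_produced_per,
                   co2_uptake_source = vapply(results, `[[`, character(1),
                                              "co2_uptake_source"))),
            class = "capture_analysis")
}

#' @export
print.capture_analysis <- function(x, digits = 2, ...) {
  cat("Rubisco CO2-capture accounting",
      sprintf("(rubicap %s, DCW/OD = %g)\n",
              x$provenance$package_version, x$provenance$dcw_per_od))
  s <- x$summary
  num <- s[-1]
  num[] <- lapply(num, round_half_out, digits = digits)
  print(cbind(s[1], num), row.names = FALSE)
  if (!is.null(x$comparisons)) {
    cat("\nCO2-uptake fold comparisons:\n")
    comp <- x$comparisons
    comp$co2_uptake_fold <- round_half_out(comp$co2_uptake_fold, 1)
    print(comp, row.names = FALSE)
  }
  invisible(x)
}

#' Write a capture analysis to machine-readable files
#'
#' Writes the summary table as CSV and (optionally) all scalar results plus
#' provenance as JSON. Outputs are byte-identical for identical inputs.
#'
#' @param report a `capture_analysis` from [run_capture_analysis()].
#' @param csv_path summary CSV output path, or `NULL` to skip.
#' @param json_path JSON output path, or `NULL` to skip.
#' @return Invisibly, the list written to JSON.
#' @export
write_capture_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "capture_analysis"))
  if (!is.null(csv_path))
    utils::write.csv(report$summary, csv_path, row.names = FALSE)
  payload <- list(provenance = report$provenance,
                  summary = report$summary,
                  comparisons = report$comparisons)
  if (!is.null(json_path))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  invisible(payload)
}
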