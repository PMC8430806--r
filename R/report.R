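#' Full mass-balance pipeline for one ash sample
#'
#' Runs the whole analysis: crystalline element totals from the phase
#' assemblage, amorphous composition by difference from the bulk analysis
#' with Gaussian error propagation, water-solubility classification of the
#' phases, the per-element soluble fraction of the crystalline budget, and
#' closure diagnostics.
#'
#' @param assemblage a [phase_assemblage()].
#' @param bulk a [bulk_composition()] of the same sample.
#' @param solubility solubility lookup, default [solubility_table()].
#' @param k sigma multiplier for over-allocation diagnostics.
#' @param closure_tol closure tolerance (wt%).
#' @return A list of class `"mass_balance_report"`: `report` (tidy tibble:
#'   `element`, `bulk`, `bulk_sd`, `crystalline`, `crystalline_sd`,
#'   `amorphous`, `amorphous_sd`, `clamped`, `soluble_fraction`),
#'   `budget`, `amorphous`, `solubility` (per-phase records),
#'   `diagnostics` (a [closure_report()]), and `label`.
#' @examples
#' asm <- sorghum_ash_phases("razinieh_normal")
#' blk <- sorghum_ash_bulk("razinieh_normal")
#' rep <- ash_mass_balance(asm, blk)
#' rep$report
#' @export
ash_mass_balance <- function(assemblage, bulk,
                             solubility = solubility_table(),
                             k = 1, closure_tol = 0.5) {
  budget <- crystalline_element_totals(assemblage)
  amor <- amorphous_by_difference(bulk, budget)
  records <- classify_solubility(assemblage, solubility)
  solfrac <- vapply(amor$element, function(el) {
    soluble_element_fraction(assemblage, budget, records, el)$fraction
  }, numeric(1))
  report <- dplyr::mutate(tibble::as_tibble(amor),
                          soluble_fraction = unname(solfrac))
  diag <- closure_report(assemblage, bulk, budget, k = k,
                         closure_tol = closure_tol)
  structure(list(report = report, budget = budget, amorphous = amor,
                 solubility = records, diagnostics = diag,
                 label = attr(assemblage, "label")),
            class = "mass_balance_report")
}

#' @export
print.mass_balance_report <- function(x, ...) {
  cat("<mass_balance_report>",
      if (!is.na(x$label)) paste0(" ", x$label), "\n", sep = "")
  print(x$report, ...)
  print(x$diagnostics)
  invisible(x)
}

#' Write a mass-balance report to disk
#'
#' Writes the tidy per-element table as TSV (fixed printed precision,
#' default two decimals) and the diagnostics as versioned JSON with full
#' precision, the package version and a configuration echo.
#'
#' @param x a `"mass_balance_report"`.
#' @param dir output directory (created if needed).
#' @param stem file stem; files become `<stem>.tsv` and
#'   `<stem>_diagnostics.json`.
#' @param digits printed decimals in the TSV (default 2).
#' @return Character vector of the two paths, invisibly.
#' @export
write_report <- function(x, dir, stem = "mass_balance", digits = 2) {
  stopifnot(inherits(x, "mass_balance_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, paste0(stem, ".tsv"))
  out <- x$report
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) formatC(v, digits = digits,
                                                   format = "f"))
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- file.path(dir, paste0(stem, "_diagnostics.json"))
  d <- x$diagnostics
  payload <- list(
    schema = "ashbalance-diagnostics-1",
    package_version = as.character(utils::packageVersion("ashbalance")),
    label = x$label,
    closure = list(total = d$total, deviation = d$closure_deviation,
                   ok = d$closure_ok, tolerance = d$closure_tol),
    over_allocated = d$over_allocated,
    unanalysed_elements = as.list(d$unanalysed_elements),
    below_detection = d$below_detection,
    config = list(k = d$k, closure_tol = d$closure_tol),
    report = x$report
  )
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(tsv, js))
}
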