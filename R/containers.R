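#' Construct a quantified phase assemblage
#'
#' A phase assemblage is the output of quantitative phase analysis
#' (Rietveld refinement with an internal standard): crystalline phases with
#' weight fractions in wt% of the bulk ash and their estimated standard
#' deviations (esds), plus the amorphous weight fraction.
#'
#' @param phases a data frame with columns `phase` (name), `formula`
#'   (formula string), `wtpct` (weight percent of bulk ash) and `esd`
#'   (estimated standard deviation, wt%).
#' @param amorphous_wtpct amorphous weight fraction (wt% of bulk ash).
#' @param amorphous_esd its esd (wt%).
#' @param label sample label.
#' @param closure_tol allowed deviation of the total (crystalline +
#'   amorphous) from 100 wt% before a warning is issued, in wt%.
#' @return A tibble of class `"phase_assemblage"` with the parsed formulas
#'   in a list column `parsed`, and attributes `amorphous_wtpct`,
#'   `amorphous_esd`, `label`.
#' @examples
#' phase_assemblage(data.frame(phase = "Sylvite", formula = "KCl",
#'                             wtpct = 60, esd = 0.2),
#'                  amorphous_wtpct = 40, amorphous_esd = 0.5)
#' @export
phase_assemblage <- function(phases, amorphous_wtpct = 0, amorphous_esd = 0,
                             label = NA_character_, closure_tol = 0.5) {
  needed <- c("phase", "formula", "wtpct", "esd")
  missing <- setdiff(needed, names(phases))
  if (length(missing) > 0) {
    stop("phase table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  phases <- tibble::as_tibble(phases[needed])
  if (anyDuplicated(phases$phase)) {
    stop("duplicate phase name(s): ",
         paste(unique(phases$phase[duplicated(phases$phase)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(phases) > 0) {
    if (!is.numeric(phases$wtpct) || !is.numeric(phases$esd) ||
        anyNA(phases$wtpct) || anyNA(phases$esd)) {
      stop("wtpct and esd must be numeric and non-missing", call. = FALSE)
    }
    if (any(phases$wtpct < 0 | phases$wtpct > 100)) {
      stop("phase weight fractions must lie in [0, 100] wt%", call. = FALSE)
    }
    if (any(phases$esd < 0)) stop("esds must be >= 0", call. = FALSE)
  }
  phases$parsed <- lapply(phases$formula, function(ft) {
    tryCatch(parse_formula(ft), error = function(e) {
      stop("cannot parse formula for phase \"",
           phases$phase[match(ft, phases$formula)], "\": ",
           conditionMessage(e), call. = FALSE)
    })
  })
  stopifnot(amorphous_wtpct >= 0, amorphous_wtpct <= 100, amorphous_esd >= 0)
  total <- sum(phases$wtpct) + amorphous_wtpct
  if (abs(total - 100) > closure_tol) {
    warning(sprintf("assemblage total %.2f wt%% deviates from 100 by more than %.2f",
                    total, closure_tol), call. = FALSE)
  }
  structure(phases,
            class = c("phase_assemblage", class(phases)),
            amorphous_wtpct = amorphous_wtpct,
            amorphous_esd = amorphous_esd,
            label = label)
}

#' @export
print.phase_assemblage <- function(x, ...) {
  lab <- attr(x, "label")
  cat("<phase_assemblage>",
      if (!is.na(lab)) paste0(" ", lab), " -- ", nrow(x),
      " crystalline phases, amorphous ",
      format(attr(x, "amorphous_wtpct")), " +/- ",
      format(attr(x, "amorphous_esd")), " wt%\n", sep = "")
  print(tibble::as_tibble(x[setdiff(names(x), "parsed")]), ...)
  invisible(x)
}

#' Construct a bulk elemental composition
#'
#' Bulk chemical analysis of the ash (XRF, combustion analysis, ion
#' chromatography): per-element concentrations in wt% of the bulk ash with
#' standard deviations, below-detection entries (limit only) and
#' single-measurement entries (no replication, sd treated as 0 downstream).
#'
#' @param elements data frame with columns `element`, `value` (wt%, NA for
#'   below-detection rows), `sd` (wt%), `flag` (one of `""`, `"lt"` for
#'   below detection with `value` holding the limit, `"single"` for a
#'   single measurement).
#' @param label sample label.
#' @return A tibble of class `"bulk_composition"`.
#' @export
bulk_composition <- function(elements, label = NA_character_) {
  needed <- c("element", "value", "sd", "flag")
  missing <- setdiff(needed, names(elements))
  if (length(missing) > 0) {
    stop("bulk table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  el <- tibble::as_tibble(elements[needed])
  if (anyDuplicated(el$element)) {
    stop("duplicate element row(s): ",
         paste(unique(el$element[duplicated(el$element)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(el$element, names(atomic_masses()))
  if (length(bad) > 0) {
    stop("unknown element symbol(s) in bulk table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  el$flag[is.na(el$flag)] <- ""
  stopifnot(all(el$flag %in% c("", "lt", "single")))
  el$sd[is.na(el$sd)] <- 0
  ok <- el$flag != "lt"
  if (any(is.na(el$value[ok]))) stop("measured rows need a value", call. = FALSE)
  if (any(el$value < 0, na.rm = TRUE) || any(el$sd < 0)) {
    stop("values and sds must be >= 0", call. = FALSE)
  }
  structure(el, class = c("bulk_composition", class(el)), label = label)
}

#' @export
print.bulk_composition <- function(x, ...) {
  lab <- attr(x, "label")
  cat("<bulk_composition>", if (!is.na(lab)) paste0(" ", lab),
      " -- ", nrow(x), " elements\n", sep = "")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
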