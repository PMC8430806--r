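#' Built-in phase solubility lookup
#'
#' Reads the water-solubility classification shipped with the package
#' (editable TSV: `phase`, `category`, `g_per_L`, `note`). Categories:
#' `soluble` (dissolves readily, value in g/L where known), `reactive`
#' (decomposes in water releasing soluble species, e.g. fairchildite ->
#' buetschliite -> soluble potassium carbonate), `insoluble`, `unknown`.
#'
#' @param path optional path to an alternative lookup TSV.
#' @return A tibble with the four columns above.
#' @export
solubility_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "solubility.tsv", package = "ashbalance")
  }
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = "")
  needed <- c("phase", "category", "g_per_L", "note")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    stop("solubility table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(tab$category %in% c("soluble", "reactive", "insoluble",
                                    "unknown")))
  tibble::as_tibble(tab[needed])
}

#' Classify the phases of an assemblage by water solubility
#'
#' Every phase receives a category; phases absent from the lookup are
#' returned as `"unknown"` and never silently treated as soluble. Matching
#' is case-insensitive on the phase name.
#'
#' @param assemblage a [phase_assemblage()].
#' @param table solubility lookup, default [solubility_table()].
#' @return A tibble with columns `phase`, `category`, `g_per_L`, `note`,
#'   one row per phase of the assemblage (classification is total).
#' @export
classify_solubility <- function(assemblage, table = solubility_table()) {
  stopifnot(inherits(assemblage, "phase_assemblage"))
  i <- match(tolower(assemblage$phase), tolower(table$phase))
  tibble::tibble(
    phase = assemblage$phase,
    category = ifelse(is.na(i), "unknown", table$category[i]),
    g_per_L = ifelse(is.na(i), NA_real_, table$g_per_L[i]),
    note = ifelse(is.na(i), "phase not in solubility lookup", table$note[i])
  )
}

#' Water-soluble fraction of an element's crystalline budget
#'
#' Fraction of the crystalline inventory of an element held in soluble (or,
#' optionally, reactive) phases: sum over qualifying phases of w_i f_ie,
#' divided by the crystalline total c_e. The amorphous inventory is outside
#' the crystalline budget and is reported separately as "unresolved" by the
#' full report, never folded into this fraction.
#'
#' @param assemblage a [phase_assemblage()].
#' @param budget matching `"element_budget"`.
#' @param records solubility classification from [classify_solubility()].
#' @param element element symbol.
#' @param count_reactive count `"reactive"` phases (fairchildite) with the
#'   soluble pool (default `TRUE`).
#' @return A list with `fraction` (in [0, 1], or `NA` when the element has
#'   no crystalline inventory), `reason` (`NA` or why no value), and
#'   `soluble_phases` (contributing phase names).
#' @export
soluble_element_fraction <- function(assemblage, budget, records, element,
                                     count_reactive = TRUE) {
  stopifnot(inherits(budget, "element_budget"))
  i <- match(element, budget$element)
  c_e <- if (is.na(i)) 0 else budget$crystalline[i]
  if (c_e <= 0) {
    return(list(fraction = NA_real_,
                reason = paste0("no crystalline ", element, " in assemblage"),
                soluble_phases = character(0)))
  }
  cats <- if (count_reactive) c("soluble", "reactive") else "soluble"
  ok_phase <- records$phase[records$category %in% cats]
  bk <- phase_breakdown(budget, element)
  contrib <- bk[names(bk) %in% ok_phase & bk > 0]
  list(fraction = sum(contrib) / c_e, reason = NA_character_,
       soluble_phases = names(contrib))
}

#' Construct a straw elemental composition
#'
#' Dry-matter element concentrations of the straw before combustion, with
#' the ash content at 550 degrees C that links straw and ash mass bases.
#'
#' @param elements data frame with columns `element`, `value`, `sd`,
#'   `unit` (`"mg/kg"` or `"%"`, dry-matter basis), `flag` (`""`, `"lt"`,
#'   `"single"`).
#' @param ash_content ash content at 550 degrees C, % of dry matter.
#' @param ash_content_sd its sd.
#' @param label sample label.
#' @return A tibble of class `"straw_composition"` with attributes
#'   `ash_content`, `ash_content_sd`, `label`.
#' @export
straw_composition <- function(elements, ash_content, ash_content_sd = 0,
                              label = NA_character_) {
  needed <- c("element", "value", "sd", "unit", "flag")
  missing <- setdiff(needed, names(elements))
  if (length(missing) > 0) {
    stop("straw table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  el <- tibble::as_tibble(elements[needed])
  el$flag[is.na(el$flag)] <- ""
  el$sd[is.na(el$sd)] <- 0
  stopifnot(all(el$flag %in% c("", "lt", "single")),
            all(el$unit %in% c("mg/kg", "%")),
            ash_content > 0, ash_content < 100, ash_content_sd >= 0)
  structure(el, class = c("straw_composition", class(el)),
            ash_content = ash_content, ash_content_sd = ash_content_sd,
            label = label)
}

# Straw concentration as a dimensionless dry-matter mass fraction.
straw_mass_fraction <- function(value, unit) {
  switch(unit, "mg/kg" = value * 1e-6, "%" = value / 100,
         stop("unsupported straw unit \"", unit, "\"", call. = FALSE))
}

#' Straw-to-ash element recovery
#'
#' How much of an element present in the straw survives combustion into the
#' ash: r_e = (ash content/100 x ash concentration/100) / straw mass
#' fraction, all on a dry-matter basis. r_e < 1 indicates combustion loss
#' (volatilisation); values slightly above 1 can arise from measurement
#' error and are flagged rather than rejected.
#'
#' @param straw a [straw_composition()].
#' @param ash_bulk a [bulk_composition()] of the ash from the same straw.
#' @param element element symbol.
#' @param tolerance flag threshold: entries with r_e > 1 + tolerance are
#'   marked implausible (default 0.05).
#' @return A one-row tibble: `element`, `recovery`, `straw_value`,
#'   `straw_unit`, `ash_value`, `ash_content`, `flagged`, `reason`
#'   (`NA` on success; recovery is `NA` with a reason when either side is
#'   below detection or missing).
#' @export
element_recovery <- function(straw, ash_bulk, element, tolerance = 0.05) {
  stopifnot(inherits(straw, "straw_composition"),
            inherits(ash_bulk, "bulk_composition"))
  no_value <- function(reason) {
    tibble::tibble(element = element, recovery = NA_real_,
                   straw_value = NA_real_, straw_unit = NA_character_,
                   ash_value = NA_real_,
                   ash_content = attr(straw, "ash_content"),
                   flagged = FALSE, reason = reason)
  }
  i <- match(element, straw$element)
  j <- match(element, ash_bulk$element)
  if (is.na(i)) return(no_value("element not measured in straw"))
  if (is.na(j)) return(no_value("element not measured in ash"))
  if (straw$flag[i] == "lt") return(no_value("below detection in straw"))
  if (ash_bulk$flag[j] == "lt") return(no_value("below detection in ash"))
  sf <- straw_mass_fraction(straw$value[i], straw$unit[i])
  if (sf <= 0) return(no_value("straw concentration is zero"))
  r <- (attr(straw, "ash_content") / 100) * (ash_bulk$value[j] / 100) / sf
  tibble::tibble(element = element, recovery = r,
                 straw_value = straw$value[i], straw_unit = straw$unit[i],
                 ash_value = ash_bulk$value[j],
                 ash_content = attr(straw, "ash_content"),
                 flagged = r > 1 + tolerance, reason = NA_character_)
}
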