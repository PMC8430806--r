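#' Crystalline element totals of a phase assemblage
#'
#' Converts quantified phase fractions into per-element contributions:
#' for element e, c_e = sum_i w_i f_ie, where w_i is phase i's weight
#' fraction (wt% of bulk ash) and f_ie the element's mass fraction in
#' phase i's formula. Phase-fraction esds propagate as
#' sigma_c,e = sqrt(sum_i (f_ie sigma_i)^2); stoichiometric coefficients
#' carry no uncertainty.
#'
#' @param assemblage a [phase_assemblage()].
#' @param masses atomic-mass table, default [atomic_masses()].
#' @return An object of class `"element_budget"`: a tibble with columns
#'   `element`, `crystalline` (wt% of bulk ash), `crystalline_sd`, and a
#'   `breakdown` attribute (matrix phase x element of contributions in
#'   wt%). Elements in canonical order; every element occurring in any
#'   phase formula is present.
#' @examples
#' asm <- phase_assemblage(data.frame(phase = "Sylvite", formula = "KCl",
#'                                    wtpct = 100, esd = 0))
#' crystalline_element_totals(asm)
#' @export
crystalline_element_totals <- function(assemblage, masses = atomic_masses()) {
  stopifnot(inherits(assemblage, "phase_assemblage"))
  els <- element_order(unlist(lapply(assemblage$parsed,
                                     function(f) names(f$composition))))
  np <- nrow(assemblage)
  contrib <- matrix(0, nrow = np, ncol = length(els),
                    dimnames = list(assemblage$phase, els))
  varsum  <- stats::setNames(numeric(length(els)), els)
  for (i in seq_len(np)) {
    fr <- element_mass_fractions(assemblage$parsed[[i]], masses)
    contrib[i, names(fr)] <- fr * assemblage$wtpct[i]
    varsum[names(fr)] <- varsum[names(fr)] + (fr * assemblage$esd[i])^2
  }
  out <- tibble::tibble(
    element = els,
    crystalline = if (np > 0) unname(colSums(contrib)) else numeric(0),
    crystalline_sd = unname(sqrt(varsum))
  )
  structure(out, class = c("element_budget", class(out)),
            breakdown = contrib, label = attr(assemblage, "label"))
}

#' Per-phase contribution of one element
#'
#' @param budget an `"element_budget"`.
#' @param element element symbol.
#' @return Named numeric vector (phase -> wt% of bulk ash); zero-length if
#'   the element occurs in no phase.
#' @export
phase_breakdown <- function(budget, element) {
  stopifnot(inherits(budget, "element_budget"))
  bk <- attr(budget, "breakdown")
  if (!element %in% colnames(bk)) return(stats::setNames(numeric(0), character(0)))
  bk[, element]
}

#' Amorphous elemental composition by difference
#'
#' The elemental makeup of the amorphous (X-ray invisible) fraction is not
#' observable by diffraction; it is estimated per element as bulk minus
#' crystalline, a_e = b_e - c_e, with Gaussian error propagation
#' sigma_a,e = sqrt(sigma_b,e^2 + sigma_c,e^2). Negative raw differences
#' (crystalline allocation exceeding the bulk measurement) are clamped to
#' zero and flagged. Elements measured in bulk but absent from every phase
#' pass through unchanged (a_e = b_e); below-detection bulk entries are
#' excluded (they appear in [closure_report()] diagnostics instead);
#' single-measurement bulk entries contribute sigma_b,e = 0.
#'
#' @param bulk a [bulk_composition()].
#' @param budget an `"element_budget"` from [crystalline_element_totals()]
#'   for the same sample.
#' @return A tibble of class `"amorphous_composition"` with columns
#'   `element`, `bulk`, `bulk_sd`, `crystalline`, `crystalline_sd`,
#'   `amorphous` (wt% of the bulk sample), `amorphous_sd`, `clamped`.
#' @export
amorphous_by_difference <- function(bulk, budget) {
  stopifnot(inherits(bulk, "bulk_composition"),
            inherits(budget, "element_budget"))
  meas <- bulk[bulk$flag != "lt", , drop = FALSE]
  cr <- stats::setNames(budget$crystalline, budget$element)
  cs <- stats::setNames(budget$crystalline_sd, budget$element)
  get0 <- function(v, el) if (el %in% names(v)) v[[el]] else 0
  ord <- element_order(meas$element)
  rows <- lapply(ord, function(el) {
    i <- match(el, meas$element)
    b <- meas$value[i]
    sb <- if (meas$flag[i] == "single") 0 else meas$sd[i]
    c_e <- get0(cr, el); s_c <- get0(cs, el)
    raw <- b - c_e
    tibble::tibble(element = el, bulk = b, bulk_sd = sb,
                   crystalline = c_e, crystalline_sd = s_c,
                   amorphous = max(0, raw),
                   amorphous_sd = sqrt(sb^2 + s_c^2),
                   clamped = raw < 0)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("amorphous_composition", class(out)),
            label = attr(bulk, "label"))
}

#' Mass-balance consistency diagnostics
#'
#' Pure report on a sample: closure of the assemblage (crystalline +
#' amorphous vs 100 wt%), elements whose crystalline allocation exceeds the
#' bulk measurement beyond `k` combined sigmas (over-allocation, the
#' clamped cells), elements present in the phases but not analysed in bulk
#' (typically O, F, Na), and bulk entries below detection.
#'
#' @param assemblage a [phase_assemblage()].
#' @param bulk a [bulk_composition()].
#' @param budget optional precomputed `"element_budget"`; computed from
#'   `assemblage` if omitted.
#' @param k sigma multiplier for the over-allocation test (default 1).
#' @param closure_tol allowed closure deviation in wt% (default 0.5).
#' @return A list of class `"closure_report"` with components `total`,
#'   `closure_deviation`, `closure_ok`, `over_allocated` (tibble),
#'   `unanalysed_elements`, `below_detection` (tibble), `k`, `closure_tol`.
#' @export
closure_report <- function(assemblage, bulk, budget = NULL, k = 1,
                           closure_tol = 0.5) {
  stopifnot(inherits(assemblage, "phase_assemblage"),
            inherits(bulk, "bulk_composition"))
  if (is.null(budget)) budget <- crystalline_element_totals(assemblage)
  total <- sum(assemblage$wtpct) + attr(assemblage, "amorphous_wtpct")
  meas <- bulk[bulk$flag != "lt", , drop = FALSE]
  j <- match(budget$element, meas$element)
  have <- !is.na(j)
  b <- meas$value[j[have]]
  sb <- ifelse(meas$flag[j[have]] == "single", 0, meas$sd[j[have]])
  c_e <- budget$crystalline[have]
  s_c <- budget$crystalline_sd[have]
  excess <- c_e - b
  over <- excess > k * sqrt(sb^2 + s_c^2)
  structure(list(
    label = attr(assemblage, "label"),
    total = total,
    closure_deviation = total - 100,
    closure_ok = abs(total - 100) <= closure_tol,
    over_allocated = tibble::tibble(
      element = budget$element[have][over],
      crystalline = c_e[over], bulk = b[over], excess = excess[over]),
    unanalysed_elements = budget$element[!have],
    below_detection = tibble::as_tibble(
      bulk[bulk$flag == "lt", c("element", "value")]),
    k = k, closure_tol = closure_tol
  ), class = "closure_report")
}

#' @export
print.closure_report <- function(x, ...) {
  cat("<closure_report>", if (!is.na(x$label)) paste0(" ", x$label), "\n",
      sep = "")
  cat(sprintf("  total %.2f wt%% (deviation %+.2f, %s)\n", x$total,
              x$closure_deviation, if (x$closure_ok) "ok" else "WARNING"))
  if (nrow(x$over_allocated) > 0) {
    cat("  over-allocated:",
        paste(x$over_allocated$element, collapse = ", "), "\n")
  }
  if (length(x$unanalysed_elements) > 0) {
    cat("  in phases, not analysed in bulk:",
        paste(x$unanalysed_elements, collapse = ", "), "\n")
  }
  if (nrow(x$below_detection) > 0) {
    cat("  below detection:",
        paste(x$below_detection$element, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Total weight fraction of phosphate phases
#'
#' Sum of the weight fractions of all crystalline phases whose formula
#' contains phosphorus (apatites, pyrophosphates, ...).
#'
#' @param assemblage a [phase_assemblage()].
#' @return Total in wt% of bulk ash.
#' @export
phosphate_phase_fraction <- function(assemblage) {
  stopifnot(inherits(assemblage, "phase_assemblage"))
  has_p <- vapply(assemblage$parsed,
                  function(f) "P" %in% names(f$composition), logical(1))
  sum(assemblage$wtpct[has_p])
}

#' Rescale an amorphous composition to wt% of the amorphous phase
#'
#' The by-difference estimates are expressed in wt% of the bulk sample;
#' dividing by the amorphous weight fraction w_am/100 re-expresses them as
#' wt% of the amorphous phase itself. The esd of w_am propagates in
#' quadrature.
#'
#' @param amorphous an `"amorphous_composition"`.
#' @param amorphous_wtpct amorphous weight fraction (wt% of bulk), > 0.
#' @param amorphous_esd its esd (wt%).
#' @return A tibble with columns `element`, `of_amorphous` (wt% of the
#'   amorphous phase), `of_amorphous_sd`, `clamped`.
#' @export
amorphous_phase_basis <- function(amorphous, amorphous_wtpct,
                                  amorphous_esd = 0) {
  stopifnot(inherits(amorphous, "amorphous_composition"),
            amorphous_wtpct > 0, amorphous_esd >= 0)
  g <- amorphous_wtpct / 100
  val <- amorphous$amorphous / g
  # relative variances add for a ratio (first order)
  rel2 <- ifelse(amorphous$amorphous > 0,
                 (amorphous$amorphous_sd / amorphous$amorphous)^2, 0) +
    (amorphous_esd / amorphous_wtpct)^2
  tibble::tibble(element = amorphous$element,
                 of_amorphous = val,
                 of_amorphous_sd = ifelse(amorphous$amorphous > 0,
                                          val * sqrt(rel2),
                                          amorphous$amorphous_sd / g),
                 clamped = amorphous$clamped)
}
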