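#' Standard atomic masses
#'
#' A pinned table of conventional standard atomic weights (g/mol) for the
#' elements occurring in biomass-ash mineralogy. Values are the IUPAC 2021
#' conventional weights; pinning them makes every downstream mass balance
#' reproducible regardless of the R session.
#'
#' @param symbols optional character vector; if given, the table is
#'   subset to these elements and an error is raised for any symbol the
#'   table does not cover.
#' @return A named numeric vector of atomic masses with attribute
#'   `version` (a text label identifying the mass table).
#' @examples
#' atomic_masses(c("K", "Cl"))
#' @export
atomic_masses <- function(symbols = NULL) {
  masses <- c(
    H  = 1.008,   C  = 12.011,  N  = 14.007,  O  = 15.999,
    F  = 18.998,  Na = 22.990,  Mg = 24.305,  Al = 26.982,
    Si = 28.085,  P  = 30.974,  S  = 32.06,   Cl = 35.45,
    K  = 39.098,  Ca = 40.078,  Ti = 47.867,  Mn = 54.938,
    Fe = 55.845,  Zn = 65.38,   Pb = 207.2
  )
  if (!is.null(symbols)) {
    missing <- setdiff(symbols, names(masses))
    if (length(missing) > 0) {
      stop("no atomic mass for element(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    masses <- masses[symbols]
  }
  attr(masses, "version") <- "IUPAC-2021-conventional"
  masses
}

# Canonical reporting order: Hill-like -- C, H, then alphabetical.
element_order <- function(symbols) {
  symbols <- unique(symbols)
  head <- intersect(c("C", "H"), symbols)
  c(head, sort(setdiff(symbols, head)))
}
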