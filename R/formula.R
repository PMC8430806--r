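#' Parse a mineral chemical formula
#'
#' Parses formulas as printed in quantitative-phase-analysis tables:
#' element symbols with integer or decimal counts (decimals express site
#' occupancies, e.g. `"CaFe0.6Mg0.3Mn0.1(CO3)2"`), nested parenthesised
#' groups with trailing multipliers, and hydrate-style segments separated
#' by a centre dot with leading multipliers
#' (`"3K2CO3·2CaCO3·6H2O"`). Subscript markup such as `"Ca_5_(PO_4_)_3_OH"`
#' is normalised before parsing.
#'
#' Comma groups denoting unresolved solid solutions (`"(Fe,Mg)"`) are
#' rejected: write the site occupancy explicitly with decimal counts
#' instead.
#'
#' @param text a single formula string.
#' @return An object of class `"mineral_formula"`: a list with elements
#'   `source` (the input text), `composition` (named numeric vector of
#'   stoichiometric counts, canonical element order), and `molar_mass`
#'   (g/mol, from [atomic_masses()]).
#' @examples
#' parse_formula("Ca5(PO4)3OH")
#' parse_formula("K_2_Ca(CO_3_)_2_")$composition
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("formula text must be a single non-empty string", call. = FALSE)
  }
  cached <- .formula_cache[[text]]
  if (!is.null(cached)) return(cached)
  src <- text
  s <- normalize_subscripts(trimws(text))
  if (grepl(",", s, fixed = TRUE)) {
    stop("solid-solution comma group in \"", src,
         "\": write site occupancies as decimal counts instead ",
         "(e.g. CaFe0.6Mg0.3Mn0.1(CO3)2)", call. = FALSE)
  }
  segments <- strsplit(s, "[·*]|\\.(?![0-9])", perl = TRUE)[[1]]
  segments <- segments[nzchar(segments)]
  if (length(segments) == 0) stop("empty formula: \"", src, "\"", call. = FALSE)

  total <- numeric(0)
  for (seg in segments) {
    mult <- 1
    m <- regmatches(seg, regexpr("^[0-9]+(\\.[0-9]+)?", seg))
    if (length(m) == 1 && nzchar(m)) {
      mult <- as.numeric(m)
      seg <- substring(seg, nchar(m) + 1)
      if (!nzchar(seg)) stop("segment with multiplier but no formula in \"",
                             src, "\"", call. = FALSE)
    }
    comp <- parse_group(seg, src)
    total <- merge_counts(total, comp * mult)
  }
  if (any(total <= 0)) {
    stop("zero or negative stoichiometric count in \"", src, "\"",
         call. = FALSE)
  }
  known <- names(atomic_masses())
  bad <- setdiff(names(total), known)
  if (length(bad) > 0) {
    stop("unknown element \"", bad[1], "\" in \"", src, "\"", call. = FALSE)
  }
  ord <- element_order(names(total))
  total <- total[ord]
  out <- structure(
    list(source = src, composition = total,
         molar_mass = unname(sum(total * atomic_masses(names(total))))),
    class = "mineral_formula"
  )
  .formula_cache[[src]] <- out
  out
}

# parsing is pure; results are memoised per formula string
.formula_cache <- new.env(parent = emptyenv())

# "_5_" -> "5"; also bare trailing underscores from sloppy markup.
normalize_subscripts <- function(s) {
  s <- gsub("_([0-9.]+)_", "\\1", s)
  gsub("_", "", s)
}

# Recursive descent over one dot-segment. Returns named numeric counts.
parse_group <- function(s, src) {
  pos <- 1L
  n <- nchar(s)
  counts <- numeric(0)
  read_count <- function() {
    m <- regmatches(substring(s, pos), regexpr("^[0-9]+(\\.[0-9]+)?",
                                               substring(s, pos)))
    if (length(m) == 0 || !nzchar(m)) return(1)
    pos <<- pos + nchar(m)
    val <- as.numeric(m)
    if (val <= 0) stop("zero or negative count at position ", pos,
                       " in \"", src, "\"", call. = FALSE)
    val
  }
  while (pos <= n) {
    ch <- substring(s, pos, pos)
    if (ch == "(") {
      depth <- 1L
      j <- pos + 1L
      while (j <= n && depth > 0L) {
        cj <- substring(s, j, j)
        if (cj == "(") depth <- depth + 1L
        if (cj == ")") depth <- depth - 1L
        j <- j + 1L
      }
      if (depth > 0L) stop("unbalanced parentheses in \"", src, "\"",
                           call. = FALSE)
      inner <- substring(s, pos + 1L, j - 2L)
      pos <- j
      mult <- read_count()
      counts <- merge_counts(counts, parse_group(inner, src) * mult)
    } else if (ch == ")") {
      stop("unbalanced parentheses in \"", src, "\"", call. = FALSE)
    } else if (grepl("^[A-Z]$", ch)) {
      sym <- ch
      if (pos < n && grepl("^[a-z]$", substring(s, pos + 1L, pos + 1L))) {
        sym <- substring(s, pos, pos + 1L)
        pos <- pos + 2L
      } else {
        pos <- pos + 1L
      }
      if (!sym %in% names(atomic_masses())) {
        stop("unknown element \"", sym, "\" at position ", pos - nchar(sym),
             " in \"", src, "\"", call. = FALSE)
      }
      cnt <- read_count()
      counts <- merge_counts(counts, stats::setNames(cnt, sym))
    } else {
      stop("unexpected character \"", ch, "\" at position ", pos,
           " in \"", src, "\"", call. = FALSE)
    }
  }
  counts
}

merge_counts <- function(a, b) {
  for (el in names(b)) a[el] <- (if (el %in% names(a)) a[[el]] else 0) + b[[el]]
  a
}

#' Serialise a formula back to text
#'
#' Writes the composition in canonical element order with counts (count 1
#' omitted; occupancies kept as decimals). Re-parsing the result gives an
#' identical composition.
#'
#' @param f a `"mineral_formula"` object.
#' @return A single formula string.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "mineral_formula"))
  cnt <- f$composition
  paste0(vapply(names(cnt), function(el) {
    k <- cnt[[el]]
    if (isTRUE(all.equal(k, 1))) el else paste0(el, format(k, scientific = FALSE))
  }, character(1)), collapse = "")
}

#' @export
print.mineral_formula <- function(x, ...) {
  cat("<mineral_formula> ", x$source, "\n", sep = "")
  cat("  composition:",
      paste(names(x$composition), signif(x$composition, 6),
            sep = ":", collapse = " "), "\n")
  cat("  molar mass:", round(x$molar_mass, 3), "g/mol\n")
  invisible(x)
}

#' Molar mass of a formula
#'
#' @param f a `"mineral_formula"` object (or a formula string, parsed
#'   on the fly).
#' @param masses named numeric vector of atomic masses; defaults to the
#'   built-in table.
#' @return Molar mass in g/mol.
#' @examples
#' molar_mass("CaCO3")
#' @export
molar_mass <- function(f, masses = atomic_masses()) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "mineral_formula"))
  els <- names(f$composition)
  missing <- setdiff(els, names(masses))
  if (length(missing) > 0) {
    stop("no atomic mass for element(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unname(sum(f$composition * masses[els]))
}

#' Element mass fractions of a formula
#'
#' For each element e, fraction(e) = count(e) x atomic mass(e) / molar mass.
#' Fractions sum to one.
#'
#' @inheritParams molar_mass
#' @return Named numeric vector of mass fractions in canonical element order.
#' @examples
#' element_mass_fractions("KCl")
#' @export
element_mass_fractions <- function(f, masses = atomic_masses()) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "mineral_formula"))
  els <- names(f$composition)
  mm <- molar_mass(f, masses)
  f$composition * masses[els] / mm
}
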