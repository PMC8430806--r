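# Independent oracles and generators shared across the suite.

# Brute-force per-atom accounting: for each phase, moles per 100 g of ash
# = wtpct / molar mass; element mass = sum over phases of
# moles x count x atomic mass. No mass-fraction shortcut.
oracle_crystalline_totals <- function(phases) {
  am <- atomic_masses()
  out <- new.env()
  for (i in seq_len(nrow(phases))) {
    f <- parse_formula(phases$formula[i])
    mm <- sum(f$composition * am[names(f$composition)])
    mol <- phases$wtpct[i] / mm
    for (el in names(f$composition)) {
      prev <- if (is.null(out[[el]])) 0 else out[[el]]
      out[[el]] <- prev + mol * f$composition[[el]] * am[[el]]
    }
  }
  unlist(as.list(out))
}

# Random formula generator over the supported grammar: element runs,
# parenthesised groups with multipliers, optional hydrate segments.
random_formula <- function() {
  els <- names(atomic_masses())
  run <- function(n) {
    paste0(vapply(sample(els, n, replace = TRUE), function(e) {
      k <- sample(c("", as.character(2:9), "0.5", "1.5", "2.25"), 1)
      paste0(e, k)
    }, character(1)), collapse = "")
  }
  seg <- function() {
    core <- run(sample(1:3, 1))
    if (stats::runif(1) < 0.5) {
      core <- paste0(core, "(", run(sample(1:2, 1)), ")",
                     sample(2:4, 1))
    }
    core
  }
  n_seg <- sample(1:3, 1)
  parts <- vapply(seq_len(n_seg), function(i) {
    lead <- if (i > 1 || stats::runif(1) < 0.3) sample(2:6, 1) else ""
    paste0(lead, seg())
  }, character(1))
  paste(parts, collapse = "·")
}

# The published amorphous-phase block for the four bundled ashes
# (wt% of the bulk sample, value +/- propagated sd; NA sd for the
# clamped cell, which is printed without an error).
reference_amorphous <- function() {
  tibble::tribble(
    ~element, ~sample, ~value, ~sd,
    "K",  "razinieh_normal",  9.53, 0.13,
    "K",  "razinieh_low",     8.40, 0.12,
    "K",  "della_normal",    16.25, 0.42,
    "K",  "della_low",       11.33, 0.10,
    "Cl", "razinieh_normal",  1.60, 0.08,
    "Cl", "razinieh_low",     6.33, 0.06,
    "Cl", "della_normal",     1.19, 0.10,
    "Cl", "della_low",        1.13, 0.07,
    "Si", "razinieh_normal",  1.24, 0.04,
    "Si", "razinieh_low",     4.44, 0.07,
    "Si", "della_normal",     0.67, 0.05,
    "Si", "della_low",        3.38, 0.04,
    "Ca", "razinieh_normal",  3.18, 0.14,
    "Ca", "razinieh_low",     2.44, 0.18,
    "Ca", "della_normal",     1.51, 0.17,
    "Ca", "della_low",        3.31, 0.14,
    "C",  "razinieh_normal",  0.71, 0.08,
    "C",  "razinieh_low",     0.93, 0.05,
    "C",  "della_normal",     1.54, 0.05,
    "C",  "della_low",        1.34, 0.16,
    "Mg", "razinieh_normal",  0.55, 0.08,
    "Mg", "razinieh_low",     1.19, 0.07,
    "Mg", "della_normal",     0.00, NA,
    "Mg", "della_low",        0.46, 0.08,
    "P",  "razinieh_normal",  0.91, 0.06,
    "P",  "razinieh_low",     0.31, 0.07,
    "P",  "della_normal",     0.41, 0.08,
    "P",  "della_low",        0.67, 0.05
  )
}

tiny_assemblage <- function(wt_kcl = 60, esd = 0) {
  phase_assemblage(
    data.frame(phase = "Sylvite", formula = "KCl", wtpct = wt_kcl,
               esd = esd),
    amorphous_wtpct = 100 - wt_kcl, closure_tol = 0.5)
}
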