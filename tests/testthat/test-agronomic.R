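test_that("solubility classification is total and matches the lookup", {
  asm <- sorghum_ash_phases("razinieh_normal")
  rec <- classify_solubility(asm)
  expect_equal(nrow(rec), nrow(asm))
  expect_equal(rec$category[rec$phase == "Sylvite"], "soluble")
  expect_equal(rec$g_per_L[rec$phase == "Sylvite"], 347)
  expect_equal(rec$g_per_L[rec$phase == "Arcanite"], 111.5)
  expect_equal(rec$category[rec$phase == "Fairchildite"], "reactive")
  expect_equal(rec$category[rec$phase == "Hydroxylapatite"], "insoluble")
  expect_equal(rec$category[rec$phase == "Na-Al-Phosphate"], "unknown")
})

test_that("phases absent from the lookup default to unknown, never soluble", {
  asm <- phase_assemblage(
    data.frame(phase = "Mysteryite", formula = "KCl", wtpct = 50, esd = 0),
    amorphous_wtpct = 50)
  rec <- classify_solubility(asm)
  expect_equal(rec$category, "unknown")
})

test_that("soluble element fractions follow the phase breakdown", {
  asm <- sorghum_ash_phases("razinieh_normal")
  budget <- crystalline_element_totals(asm)
  rec <- classify_solubility(asm)

  k <- soluble_element_fraction(asm, budget, rec, "K")
  expect_equal(k$fraction, 1, tolerance = 1e-12)
  expect_setequal(k$soluble_phases,
                  c("Sylvite", "Arcanite", "Fairchildite"))

  p <- soluble_element_fraction(asm, budget, rec, "P")
  expect_identical(p$fraction, 0)

  # fairchildite K moves out of the soluble pool when reactive is excluded
  k2 <- soluble_element_fraction(asm, budget, rec, "K",
                                 count_reactive = FALSE)
  expect_lt(k2$fraction, 1)
  expect_gt(k2$fraction, 0)

  none <- soluble_element_fraction(asm, budget, rec, "N")
  expect_true(is.na(none$fraction))
  expect_match(none$reason, "no crystalline N")
})

test_that("soluble fractions stay within [0, 1] on random assemblages", {
  set.seed(5)
  lib <- ash_phase_library()
  for (i in 1:15) {
    rows <- lib[sample(nrow(lib), 5), ]
    rows$wtpct <- stats::runif(5, 0.5, 15); rows$esd <- 0
    asm <- phase_assemblage(rows, closure_tol = Inf)
    budget <- crystalline_element_totals(asm)
    rec <- classify_solubility(asm)
    for (el in budget$element[budget$crystalline > 0]) {
      fr <- soluble_element_fraction(asm, budget, rec, el)$fraction
      expect_gte(fr, 0); expect_lte(fr, 1 + 1e-12)
    }
  }
})

test_that("straw-to-ash recovery matches the dry-matter mass balance", {
  straw_n <- sorghum_straw("razinieh_normal")
  ash_n <- sorghum_ash_bulk("razinieh_normal")
  r <- element_recovery(straw_n, ash_n, "P")
  expect_equal(r$recovery, 0.0646 * 0.0263 / 0.00171, tolerance = 1e-9)
  expect_equal(round(r$recovery, 2), 0.99)
  expect_false(r$flagged)

  straw_l <- sorghum_straw("razinieh_low")
  ash_l <- sorghum_ash_bulk("razinieh_low")
  r2 <- element_recovery(straw_l, ash_l, "P")
  expect_equal(round(r2$recovery, 2), 0.97)

  # percent-basis straw rows (Cl) reconcile units
  rcl <- element_recovery(straw_n, ash_n, "Cl")
  expect_equal(rcl$recovery, 0.0646 * 0.107 / 0.0101, tolerance = 1e-9)
})

test_that("recovery is scale invariant and handles edge cases", {
  straw <- straw_composition(
    data.frame(element = "P", value = 1000, sd = 0, unit = "mg/kg",
               flag = ""), ash_content = 5)
  mkash <- function(v) bulk_composition(
    data.frame(element = "P", value = v, sd = 0, flag = ""))
  r1 <- element_recovery(straw, mkash(2), "P")$recovery
  straw2 <- straw_composition(
    data.frame(element = "P", value = 3000, sd = 0, unit = "mg/kg",
               flag = ""), ash_content = 5)
  r2 <- element_recovery(straw2, mkash(6), "P")$recovery
  expect_equal(r1, r2, tolerance = 1e-12)

  expect_equal(element_recovery(straw, mkash(0), "P")$recovery, 0)

  big <- element_recovery(straw, mkash(50), "P")
  expect_true(big$flagged)

  bd <- bulk_composition(
    data.frame(element = "P", value = 0.2, sd = 0, flag = "lt"))
  miss <- element_recovery(straw, bd, "P")
  expect_true(is.na(miss$recovery))
  expect_match(miss$reason, "below detection in ash")

  ti <- element_recovery(sorghum_straw("della_normal"),
                         sorghum_ash_bulk("della_normal"), "Ti")
  expect_true(is.na(ti$recovery))
})
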