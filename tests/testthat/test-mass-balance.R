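test_that("a single pure phase yields its mass fractions times 100", {
  asm <- phase_assemblage(
    data.frame(phase = "Sylvite", formula = "KCl", wtpct = 100, esd = 0))
  tot <- crystalline_element_totals(asm)
  expect_equal(tot$crystalline[tot$element == "K"], 52.45, tolerance = 5e-3)
  expect_equal(tot$crystalline[tot$element == "Cl"], 47.55, tolerance = 5e-3)
  expect_equal(tot$crystalline_sd, c(0, 0))
})

test_that("an empty assemblage gives an empty budget", {
  asm <- phase_assemblage(
    data.frame(phase = character(0), formula = character(0),
               wtpct = numeric(0), esd = numeric(0)),
    amorphous_wtpct = 100)
  tot <- crystalline_element_totals(asm)
  expect_equal(nrow(tot), 0)
})

test_that("crystalline Si of the normal-P Razinieh ash matches the hand oracle", {
  asm <- sorghum_ash_phases("razinieh_normal")
  tot <- crystalline_element_totals(asm)
  f_wol <- element_mass_fractions("CaSiO3")[["Si"]]
  f_sio2 <- element_mass_fractions("SiO2")[["Si"]]
  expect_equal(tot$crystalline[tot$element == "Si"],
               2.26 * f_wol + (0.71 + 0.03) * f_sio2, tolerance = 1e-12)
  expect_equal(round(tot$crystalline[tot$element == "Si"], 2), 0.89)
})

test_that("totals agree with brute-force per-atom accounting", {
  set.seed(11)
  lib <- ash_phase_library()
  for (i in 1:25) {
    k <- sample(1:3, 1)
    rows <- lib[sample(nrow(lib), k), ]
    rows$wtpct <- stats::runif(k, 0.1, 30)
    rows$esd <- 0
    asm <- phase_assemblage(rows, amorphous_wtpct = 0, closure_tol = Inf)
    tot <- crystalline_element_totals(asm)
    oracle <- oracle_crystalline_totals(rows)
    expect_equal(stats::setNames(tot$crystalline, tot$element)[names(oracle)],
                 oracle, tolerance = 1e-10)
  }
})

test_that("totals are additive over assemblage concatenation", {
  lib <- ash_phase_library()
  a <- lib[1:4, ]; a$wtpct <- c(5, 3, 1, 2); a$esd <- 0
  b <- lib[5:8, ]; b$wtpct <- c(10, 4, 2, 8); b$esd <- 0
  asm_a <- phase_assemblage(a, closure_tol = Inf)
  asm_b <- phase_assemblage(b, closure_tol = Inf)
  asm_ab <- phase_assemblage(rbind(a, b), closure_tol = Inf)
  ta <- stats::setNames(crystalline_element_totals(asm_a)$crystalline,
                        crystalline_element_totals(asm_a)$element)
  tb <- stats::setNames(crystalline_element_totals(asm_b)$crystalline,
                        crystalline_element_totals(asm_b)$element)
  tab <- crystalline_element_totals(asm_ab)
  for (el in tab$element) {
    g0 <- function(v) if (el %in% names(v)) v[[el]] else 0
    expect_equal(tab$crystalline[tab$element == el], g0(ta) + g0(tb),
                 tolerance = 1e-12)
  }
})

test_that("per-phase breakdown sums to the element total", {
  asm <- sorghum_ash_phases("della_low")
  tot <- crystalline_element_totals(asm)
  for (el in tot$element) {
    expect_equal(sum(phase_breakdown(tot, el)),
                 tot$crystalline[tot$element == el], tolerance = 1e-12)
  }
})

test_that("by-difference estimates respond exactly to bulk shifts when unclamped", {
  asm <- tiny_assemblage(60)
  tot <- crystalline_element_totals(asm)
  mk <- function(k_val) bulk_composition(
    data.frame(element = c("K", "Cl"), value = c(k_val, 30),
               sd = c(0.1, 0.1), flag = ""))
  a1 <- amorphous_by_difference(mk(40), tot)
  a2 <- amorphous_by_difference(mk(40.7), tot)
  expect_equal(a2$amorphous[a2$element == "K"] -
                 a1$amorphous[a1$element == "K"], 0.7, tolerance = 1e-12)
})

test_that("negative differences clamp to zero with the flag set", {
  asm <- tiny_assemblage(60)
  tot <- crystalline_element_totals(asm)
  blk <- bulk_composition(
    data.frame(element = c("K", "Cl"), value = c(10, 30),
               sd = c(0.1, 0.1), flag = ""))
  a <- amorphous_by_difference(blk, tot)
  expect_identical(a$amorphous[a$element == "K"], 0)
  expect_true(a$clamped[a$element == "K"])
  expect_false(a$clamped[a$element == "Cl"])
})

test_that("bulk equal to crystalline totals gives zero amorphous, unclamped", {
  asm <- tiny_assemblage(60)
  tot <- crystalline_element_totals(asm)
  blk <- bulk_composition(
    data.frame(element = tot$element, value = tot$crystalline,
               sd = 0, flag = ""))
  a <- amorphous_by_difference(blk, tot)
  expect_equal(a$amorphous, rep(0, nrow(a)))
  expect_false(any(a$clamped))
})

test_that("bulk-only elements pass through; below-detection rows are excluded", {
  asm <- tiny_assemblage(60)
  tot <- crystalline_element_totals(asm)
  blk <- bulk_composition(
    data.frame(element = c("K", "Cl", "Si", "Zn"),
               value = c(40, 30, 2.5, 0.2),
               sd = c(0.1, 0.1, 0.05, 0),
               flag = c("", "", "", "lt")))
  a <- amorphous_by_difference(blk, tot)
  expect_false("Zn" %in% a$element)
  expect_equal(a$amorphous[a$element == "Si"], 2.5)
})

test_that("error propagation is Gaussian and single measurements carry no sd", {
  asm <- tiny_assemblage(60, esd = 0.2)
  tot <- crystalline_element_totals(asm)
  f_k <- element_mass_fractions("KCl")[["K"]]
  expect_equal(tot$crystalline_sd[tot$element == "K"], f_k * 0.2,
               tolerance = 1e-12)
  blk <- bulk_composition(
    data.frame(element = c("K", "Cl"), value = c(40, 30),
               sd = c(0.3, 0.4), flag = c("", "single")))
  a <- amorphous_by_difference(blk, tot)
  expect_equal(a$amorphous_sd[a$element == "K"],
               sqrt(0.3^2 + (f_k * 0.2)^2), tolerance = 1e-12)
  f_cl <- element_mass_fractions("KCl")[["Cl"]]
  expect_equal(a$amorphous_sd[a$element == "Cl"], f_cl * 0.2,
               tolerance = 1e-12)
})

test_that("propagated sd is non-decreasing in every input sd", {
  f_k <- element_mass_fractions("KCl")[["K"]]
  base <- tiny_assemblage(60, esd = 0.1)
  more <- tiny_assemblage(60, esd = 0.3)
  blk <- function(sdk) bulk_composition(
    data.frame(element = c("K", "Cl"), value = c(40, 30),
               sd = c(sdk, 0.1), flag = ""))
  sd_of <- function(asm, b) {
    a <- amorphous_by_difference(b, crystalline_element_totals(asm))
    a$amorphous_sd[a$element == "K"]
  }
  expect_gte(sd_of(more, blk(0.1)), sd_of(base, blk(0.1)))
  expect_gte(sd_of(base, blk(0.5)), sd_of(base, blk(0.1)))
})

test_that("closure diagnostics flag bad totals and over-allocation", {
  asm <- sorghum_ash_phases("razinieh_normal")
  blk <- sorghum_ash_bulk("razinieh_normal")
  rep1 <- closure_report(asm, blk)
  expect_equal(rep1$total, 100, tolerance = 1e-9)
  expect_true(rep1$closure_ok)
  expect_true("O" %in% rep1$unanalysed_elements)
  expect_equal(rep1$below_detection$element, "Zn")

  dn <- closure_report(sorghum_ash_phases("della_normal"),
                       sorghum_ash_bulk("della_normal"), k = 1)
  expect_true("Mg" %in% dn$over_allocated$element)

  short <- suppressWarnings(phase_assemblage(
    data.frame(phase = "Sylvite", formula = "KCl", wtpct = 60, esd = 0),
    amorphous_wtpct = 30))
  rep2 <- closure_report(short, blk)
  expect_false(rep2$closure_ok)
})

test_that("phosphate phase fraction sums the P-bearing phases", {
  expect_equal(phosphate_phase_fraction(sorghum_ash_phases("razinieh_normal")),
               6.90 + 1.69 + 0.31 + 0.30, tolerance = 1e-12)
  means <- mean(vapply(sorghum_ash_samples(), function(s)
    phosphate_phase_fraction(sorghum_ash_phases(s)), numeric(1)))
  expect_equal(round(means), 9)
  expect_equal(phosphate_phase_fraction(tiny_assemblage(60)), 0)
})

test_that("rescaling to the amorphous-phase basis divides by its weight fraction", {
  asm <- sorghum_ash_phases("razinieh_normal")
  blk <- sorghum_ash_bulk("razinieh_normal")
  a <- amorphous_by_difference(blk, crystalline_element_totals(asm))
  v <- amorphous_phase_basis(a, amorphous_wtpct = 27.40, amorphous_esd = 0.8)
  i <- match("K", a$element); j <- match("K", v$element)
  expect_equal(v$of_amorphous[j], a$amorphous[i] / 0.274, tolerance = 1e-12)
  expect_gte(v$of_amorphous_sd[j], a$amorphous_sd[i] / 0.274)
})
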