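test_that("single-salt conversions follow hand stoichiometry", {
  # iron sulfate at its MS concentration: 27.85 / 278.01 = 0.1002 mM,
  # released as one Fe2+ and one SO4 2- each
  fe <- salt_ions("FeSO4.7H2O", 27.85)
  expect_equal(round_half_away(fe[["Fe"]], 2), 0.10)
  expect_equal(round_half_away(fe[["SO4"]], 2), 0.10)
  expect_equal(fe[["Fe"]], fe[["SO4"]])
  expect_equal(sum(fe[setdiff(ion_names(), c("Fe", "SO4"))]), 0)

  # calcium chloride dihydrate dosed at exactly its molar mass: 1 mM salt,
  # hence 1 mM Ca2+ and 2 mM Cl-
  ca <- salt_ions("CaCl2.2H2O", 147.02)
  expect_equal(ca[["Ca"]], 1, tolerance = 1e-12)
  expect_equal(ca[["Cl"]], 2, tolerance = 1e-12)

  expect_equal(unname(salt_ions("KNO3", 0)), numeric(18))
  expect_equal(salt_to_millimolar("NH4NO3", 80.04), 1)
  expect_error(salt_to_millimolar("NaCl", 10), "unknown salt")
  expect_error(salt_to_millimolar("KNO3", -1), "negative")
})

test_that("MS recipe reproduces the printed macronutrient profile", {
  prof <- recipe_to_ions(ms_recipe())
  expect_equal(round_half_away(prof[["NH4"]], 2), 20.61)
  expect_equal(round_half_away(prof[["NO3"]], 2), 39.41)
  expect_equal(round_half_away(prof[["K"]], 2), 20.05)
  # sodium arrives only via the di-sodium salts:
  # 2 x 37.25/372.24 + 2 x 0.25/241.95 = 0.2022
  expect_equal(prof[["Na"]], 2 * 37.25 / 372.24 + 2 * 0.25 / 241.95,
               tolerance = 1e-12)
  expect_equal(unname(recipe_to_ions(numeric(0))), numeric(18))
})

test_that("factor scaling matches the printed treatment profiles", {
  expect_equal(
    factors_to_recipe(c(nh4no3 = 1, kno3 = 1, mesos = 1, micros = 1,
                        iron = 1))$concentrations,
    ms_recipe()$concentrations)

  lv5 <- c(nh4no3 = 0.90, kno3 = 0.10, mesos = 0.25, micros = 0.10,
           iron = 1.60)
  p5 <- recipe_to_ions(factors_to_recipe(lv5))
  expect_equal(round_half_away(p5[["NH4"]], 2), 18.55)
  expect_equal(round_half_away(p5[["K"]], 2), 2.19)

  lv4 <- c(nh4no3 = 0.20, kno3 = 0.24, mesos = 3.00, micros = 0.97,
           iron = 1.84)
  expect_equal(round_half_away(recipe_to_ions(factors_to_recipe(lv4))[["Cl"]],
                               2), 17.96)

  expect_warning(
    factors_to_recipe(c(nh4no3 = 2, kno3 = 1, mesos = 1, micros = 1,
                        iron = 1)),
    "outside design range")
})

test_that("ion profiles are linear and additive in the recipe", {
  reg <- salt_registry()
  set.seed(42)
  for (i in 1:5) {
    conc_a <- stats::setNames(stats::runif(nrow(reg), 0, 500), reg$salt)
    conc_b <- stats::setNames(stats::runif(nrow(reg), 0, 500), reg$salt)
    alpha <- stats::runif(1, 0, 3)
    expect_equal(recipe_to_ions(alpha * conc_a),
                 alpha * recipe_to_ions(conc_a), tolerance = 1e-12)
    expect_equal(recipe_to_ions(conc_a + conc_b),
                 recipe_to_ions(conc_a) + recipe_to_ions(conc_b),
                 tolerance = 1e-12)
  }
})

test_that("design-wide ion table composes the per-run conversions", {
  d <- kiwi_design()[1:2, names(factor_groups())]
  X <- design_to_ion_table(d)
  expect_equal(dim(X), c(2L, 18L))
  expect_equal(X[1, ],
               recipe_to_ions(factors_to_recipe(unlist(d[1, ]),
                                                warn_range = FALSE)))
  # magnesium comes only from the mesos group: level x 370/246.48
  d34 <- kiwi_design()[1:34, ]
  X34 <- design_to_ion_table(d34[, names(factor_groups())])
  expect_equal(X34[, "Mg"], d34$mesos * 370 / 246.48, tolerance = 1e-12,
               ignore_attr = TRUE)
  # a single run at 1x is the MS profile
  expect_equal(X34[34, ], recipe_to_ions(ms_recipe()))
})
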