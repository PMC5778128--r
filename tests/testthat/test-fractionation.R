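shiftC2 <- IsotopeShift(deltaO = -37, deltaP = -72, depthO = 50, depthP = 52)

test_that("the mass balance reproduces hand arithmetic on the printed constants", {
  high <- FractionationScenario("high", 1.039)
  low <- FractionationScenario("low", 1.009)
  expect_equal(fractionOxidized(shiftC2, high), 35 / 38, tolerance = 1e-12)
  expect_equal(fractionOxidized(shiftC2, low), 35 / 8, tolerance = 1e-12)
  # zero shift -> zero for every scenario
  zero <- IsotopeShift(-60, -60, 1, 2)
  for (s in defaultScenarios())
    expect_identical(fractionOxidized(zero, s), 0)
  # a bare numeric shift is accepted too
  expect_equal(fractionOxidized(35, high), 35 / 38, tolerance = 1e-12)
})

test_that("degenerate and invalid scenarios are rejected", {
  expect_error(FractionationScenario("bad", 1.001, 1.001), "differ")
  expect_error(FractionationScenario("bad", 0.99), "> 1")
  expect_error(evaluateScenarios(shiftC2, list()), "empty")
})

test_that("the built-in registry holds the six printed alpha values", {
  reg <- defaultScenarios()
  expect_length(reg, 6)
  expect_setequal(vapply(reg, alphaOx, numeric(1)),
                  c(1.009, 1.0174, 1.030, 1.031, 1.032, 1.039))
  expect_true(all(vapply(reg, alphaTrans, numeric(1)) == 1.001))
  # marine S-AOM bounds present
  expect_equal(alphaOx(reg[["S-AOM-marine-low"]]), 1.009)
  expect_equal(alphaOx(reg[["S-AOM-marine-high"]]), 1.039)
  # pure function: identical registries on every call
  expect_identical(vapply(defaultScenarios(), alphaOx, numeric(1)),
                   vapply(defaultScenarios(), alphaOx, numeric(1)))
})

test_that("scenario evaluation flags physically impossible fractions", {
  est <- evaluateScenarios(shiftC2)
  expect_equal(nrow(est), 6)
  # enumerated Eq. values over the registry
  want <- c(`S-AOM-marine-low` = 35 / 8, `S-AOM-marine-high` = 35 / 38,
            `S-AOM-freshwater` = 35 / 29, `Fe-AOM` = 35 / 30,
            `N-AOM` = 35 / 31, `EEL-AOM` = 35 / 16.4)
  expect_equal(est$f_raw[match(names(want), est$scenario)], unname(want),
               tolerance = 1e-12)
  # retained iff 0 <= f_raw <= 1; only the marine high bound survives 35 permil
  expect_equal(est$retained, est$f_raw >= 0 & est$f_raw <= 1)
  expect_equal(est$scenario[est$retained], "S-AOM-marine-high")
  # capped values lie in [0, 1] and match min(max(f, 0), 1)
  expect_equal(est$f_capped, pmin(pmax(est$f_raw, 0), 1))
  # zero shift -> all six retained at zero
  est0 <- evaluateScenarios(0)
  expect_true(all(est0$retained))
  expect_true(all(est0$f_raw == 0))
  # negative shift -> flagged, not an error
  estn <- evaluateScenarios(-5)
  expect_true(all(!estn$retained))
  expect_true(all(estn$f_capped == 0))
})

test_that("the fraction is linear in the shift and monotone in alpha_ox", {
  s1 <- FractionationScenario("a", 1.030)
  expect_equal(fractionOxidized(20, s1) * 2, fractionOxidized(40, s1),
               tolerance = 1e-12)
  alphas <- c(1.009, 1.0174, 1.030, 1.039)
  f <- vapply(alphas, function(a)
    fractionOxidized(35, FractionationScenario("x", a)), numeric(1))
  expect_true(all(diff(f) < 0))  # strictly decreasing in alpha_ox
})

test_that("forwardDelta and fractionOxidized are exact inverses", {
  set.seed(11)
  reg <- defaultScenarios()
  for (k in 1:100) {
    f <- runif(1)
    dp <- runif(1, -90, -55)
    s <- reg[[sample(6, 1)]]
    expect_equal(fractionOxidized(forwardDelta(f, dp, s) - dp, s), f,
                 tolerance = 1e-12)
  }
})

test_that("scenario registries round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeScenarios(defaultScenarios(), f)
  reg <- readScenarios(f)
  expect_equal(vapply(reg, alphaOx, numeric(1)),
               vapply(defaultScenarios(), alphaOx, numeric(1)))
  expect_equal(vapply(reg, alphaTrans, numeric(1)),
               vapply(defaultScenarios(), alphaTrans, numeric(1)))
})
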