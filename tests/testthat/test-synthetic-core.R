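noiseless <- function(preset, seed = 1, ...)
  generateCore(syntheticCoreParams(preset, seed = seed, noiseSdDelta = 0,
                                   noiseSdConc = 0, ...))

test_that("generation is byte-identical for identical parameters and seed", {
  a <- generateCore(syntheticCoreParams("bk2_like", seed = 99))
  b <- generateCore(syntheticCoreParams("bk2_like", seed = 99))
  expect_identical(records(a$profile), records(b$profile))
  c <- generateCore(syntheticCoreParams("bk2_like", seed = 100))
  expect_false(identical(records(a$profile), records(c$profile)))
})

test_that("the c2-like preset reproduces the printed profile landmarks", {
  sim <- noiseless("c2_like")
  rec <- records(sim$profile)
  expect_equal(nrow(rec), 118)
  # methane maximum of 990 uM at the configured peak depth (52 mbsf)
  expect_equal(max(rec$ch4_uM), 990, tolerance = 1e-12)
  expect_equal(rec$depth_mbsf[which.max(rec$ch4_uM)], 52)
  # delta13C extremes are the printed range bounds
  expect_equal(min(rec$d13c_ch4_permil, na.rm = TRUE), -72, tolerance = 1e-9)
  expect_equal(max(rec$d13c_ch4_permil, na.rm = TRUE), -37, tolerance = 1e-9)
  # sulfate declines from its surface plateau to trace levels at depth
  expect_equal(max(rec$so4_mM), 24, tolerance = 1e-6)
  expect_lt(rec$so4_mM[nrow(rec)], 0.4)
  # ice-bonded interval annotated
  expect_true(all(rec$state[rec$depth_mbsf >= 34.5] == "ice_bonded"))
  expect_true(all(rec$state[rec$depth_mbsf < 34.5] == "unfrozen"))
})

test_that("the bk2-like preset carries ~8x methane in the frozen section and a thaw-front SMTZ", {
  sim <- noiseless("bk2_like")
  rec <- records(sim$profile)
  expect_equal(nrow(rec), 80)
  frozen <- rec$state == "ice_bonded"
  expect_gt(mean(rec$ch4_uM[frozen]) / 48, 7.5)
  # opposing sulfate/methane gradients at the permafrost table
  smtz <- detectSmtz(sim$profile)
  expect_s4_class(smtz, "SmtzInterval")
  mid <- mean(sim$truth@smtzInterval)
  expect_lte(smtz@topMbsf, mid)
  expect_gte(smtz@bottomMbsf, mid)
  # frozen-section delta13C within the printed biogenic band, oxidized above
  expect_true(all(rec$d13c_ch4_permil[frozen] >= -71 - 1e-9))
  expect_gte(max(rec$d13c_ch4_permil), -37)
})

test_that("the noiseless pipeline recovers the generating fraction exactly", {
  # default truth under the generating scenario
  sim <- noiseless("c2_like")
  shift <- maxIsotopeShift(sim$profile)
  scen <- defaultScenarios()[["S-AOM-marine-high"]]
  expect_equal(fractionOxidized(shift, scen), sim$truth@fOxTrue,
               tolerance = 1e-12)
  # custom fraction: thresholds widened so the implied crest qualifies
  sim2 <- noiseless("c2_like", fOxTrue = 0.8)
  shift2 <- maxIsotopeShift(sim2$profile, oxThreshold = -45)
  expect_equal(fractionOxidized(shift2, scen), 0.8, tolerance = 1e-12)
  # the forward mass balance ties truth delta_o to f and delta_p
  expect_equal(sim2$truth@deltaOExpected,
               forwardDelta(0.8, -72, scen), tolerance = 1e-12)
})

test_that("the noiseless budget from the generated core equals the recorded truth", {
  sim <- noiseless("bk2_like")
  rec <- records(sim$profile)
  ibp <- rec$state == "ice_bonded"
  conc <- rec$ch4_uM[ibp] * 1e-3
  b <- BudgetInputs(degradationRate = 0.053, ch4Low = min(conc),
                    ch4Mean = mean(conc), ch4High = max(conc),
                    fOxMin = sim$truth@fOxTrue, fOxMax = sim$truth@fOxTrue)
  g <- budgetGrid(b)
  expect_equal(g$oxidized_tg_c_yr, sim$truth@budgetTrue$oxidized_tg_c_yr,
               tolerance = 1e-12)
})

test_that("inconsistent generator parameters are rejected", {
  expect_error(syntheticCoreParams("c2_like", smtzInterval = c(55, 50)),
               "increasing")
  expect_error(syntheticCoreParams("c2_like", smtzInterval = c(50, 70)),
               "within depthRange")
  expect_error(syntheticCoreParams("c2_like", fOxTrue = 1.2), "\\[0, 1\\]")
  expect_error(syntheticCoreParams("c2_like", nonsense = 1), "unknown")
  expect_error(syntheticCoreParams("c2_like", ch4Peak = c(990, 70)),
               "ch4Peak depth")
})
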