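bk2Inputs <- BudgetInputs(degradationRate = 0.053, ch4Low = 0.1,
                          ch4Mean = 0.384, ch4High = 0.5,
                          fOxMin = 0.79, fOxMax = 1)

test_that("release and oxidized carbon match the unit-tracked hand computation", {
  # 0.053 m/yr x 3e12 m2 x 0.4 x 0.384 mol/m3 = 2.44224e10 mol/yr
  rel <- methaneReleaseRate(bk2Inputs, "mean")
  expect_equal(rel, 0.053 * 3e12 * 0.4 * 0.384, tolerance = 1e-12)
  expect_equal(rel, 2.44224e10, tolerance = 1e-12)
  # x 12.011 g/mol / 1e12 g/Tg at f_ox = 1 -> 0.29334 Tg C/yr
  expect_equal(oxidizedCarbon(rel, 1), 2.44224e10 * 12.011 / 1e12,
               tolerance = 1e-12)
  expect_equal(oxidizedCarbon(rel, 1), 0.293337446, tolerance = 1e-8)
  # f_ox = 0 consumes nothing; linearity in release
  expect_identical(oxidizedCarbon(rel, 0), 0)
  expect_equal(oxidizedCarbon(2 * rel, 0.5), 2 * oxidizedCarbon(rel, 0.5),
               tolerance = 1e-12)
})

test_that("invalid budget inputs are rejected", {
  expect_error(BudgetInputs(0.053, 0.5, 0.4, 0.3, 0, 1), "ch4Low <= ch4Mean")
  expect_error(BudgetInputs(0, 0.1, 0.2, 0.3, 0, 1), "positive")
  expect_error(BudgetInputs(0.053, 0.1, 0.2, 0.3, 0.9, 0.1), "fOxMin")
  expect_error(BudgetInputs(0.053, 0.1, 0.2, 0.3, 0, 1.5), "\\[0, 1\\]")
  expect_error(oxidizedCarbon(1e10, 1.2), "\\[0, 1\\]")
  expect_error(oxidizedCarbon(-1, 0.5), "non-negative")
})

test_that("the budget grid equals element-wise recomputation and is bounded by its corners", {
  g <- budgetGrid(bk2Inputs)
  expect_equal(nrow(g), 6)
  # brute-force recomputation oracle, cell by cell
  for (r in seq_len(nrow(g))) {
    conc <- switch(g$level[r], low = 0.1, mean = 0.384, high = 0.5)
    f <- switch(g$f_bound[r], min = 0.79, max = 1)
    expect_equal(g$release_mol_yr[r], 0.053 * 3e12 * 0.4 * conc,
                 tolerance = 1e-12)
    expect_equal(g$oxidized_tg_c_yr[r],
                 0.053 * 3e12 * 0.4 * conc * f * 12.011 / 1e12,
                 tolerance = 1e-12)
  }
  # grid extremes are the monotone corners and bound every cell
  expect_equal(attr(g, "min"),
               oxidizedCarbon(methaneReleaseRate(bk2Inputs, "low"), 0.79),
               tolerance = 1e-12)
  expect_equal(attr(g, "max"),
               oxidizedCarbon(methaneReleaseRate(bk2Inputs, "high"), 1),
               tolerance = 1e-12)
  expect_true(all(g$oxidized_tg_c_yr >= attr(g, "min") - 1e-15))
  expect_true(all(g$oxidized_tg_c_yr <= attr(g, "max") + 1e-15))
})

test_that("a degenerate grid collapses to a single value and release ignores f bounds", {
  b <- BudgetInputs(0.006, 0.048, 0.048, 0.048, fOxMin = 0.5, fOxMax = 0.5)
  g <- budgetGrid(b)
  expect_equal(length(unique(g$oxidized_tg_c_yr)), 1L)
  b2 <- BudgetInputs(0.006, 0.048, 0.048, 0.048, fOxMin = 0.1, fOxMax = 0.9)
  expect_equal(methaneReleaseRate(b, "mean"), methaneReleaseRate(b2, "mean"))
})

test_that("budget configuration round-trips through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(degradation_rate_m_yr = 0.053, area_m2 = 3e12,
                        porewater_volume_fraction = 0.4,
                        ch4_low_mol_m3 = 0.1, ch4_mean_mol_m3 = 0.384,
                        ch4_high_mol_m3 = 0.5, f_ox_min = 0.79,
                        f_ox_max = 1), f)
  b <- readBudgetConfig(f)
  expect_equal(methaneReleaseRate(b, "mean"),
               methaneReleaseRate(bk2Inputs, "mean"))
  yaml::write_yaml(list(degradation_rate_m_yr = 0.053), f)
  expect_error(readBudgetConfig(f), "lacks field")
})
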