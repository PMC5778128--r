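test_that("horizons are partitioned by the delta13C thresholds", {
  p <- makeProfile(depth = 1:4, d13c = c(-35, -70, -45, NA))
  z <- classifyHorizons(p)
  expect_equal(z$label, c("oxidized", "source", "intermediate",
                          "unconstrained"))
  # exactly one label per record, always
  expect_equal(nrow(z), length(p))
  # printed endmember values of a core's range qualify (inclusive bounds)
  z2 <- classifyHorizons(makeProfile(depth = 1:2, d13c = c(-37, -52)))
  expect_equal(z2$label, c("oxidized", "source"))
  expect_error(classifyHorizons(p, oxThreshold = -52, sourceThreshold = -37),
               "oxThreshold must exceed")
})

test_that("the maximal isotope shift recovers the printed C2 extremes", {
  p <- makeProfile(depth = c(50, 52), d13c = c(-37, -72))
  s <- maxIsotopeShift(p)
  expect_equal(isotopeShift(s), 35)
  expect_equal(s@deltaO, -37)
  expect_equal(s@deltaP, -72)
  # no oxidized horizon -> no shift
  expect_null(maxIsotopeShift(makeProfile(depth = 1:3, d13c = rep(-60, 3))))
  # source above oxidized does not qualify (source must be subjacent)
  expect_null(maxIsotopeShift(makeProfile(depth = c(1, 2),
                                          d13c = c(-72, -35))))
})

test_that("maximal shift equals exhaustive pair search on random profiles", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    p <- makeProfile(depth = sort(sample(seq(0.5, 60, by = 0.5), n)),
                     d13c = round(runif(n, -90, -25), 2))
    got <- maxIsotopeShift(p)
    want <- bruteForceMaxShift(p)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(isotopeShift(got), want, tolerance = 1e-12)
    }
  }
})

test_that("maximal shift is invariant under input row permutation", {
  set.seed(7)
  n <- 12
  rec <- data.frame(depth_mbsf = seq_len(n),
                    d13c_ch4_permil = runif(n, -80, -30))
  s1 <- maxIsotopeShift(CoreProfile(rec))
  s2 <- maxIsotopeShift(CoreProfile(rec[sample(n), ]))
  expect_equal(isotopeShift(s1), isotopeShift(s2))
  expect_equal(s1@depthO, s2@depthO)
  expect_equal(s1@depthP, s2@depthP)
})

test_that("shift ties break to the smallest depth separation, then shallowest", {
  # two source horizons with identical delta below one oxidized horizon
  p <- makeProfile(depth = c(10, 20, 30), d13c = c(-35, -70, -70))
  s <- maxIsotopeShift(p)
  expect_equal(s@depthP, 20)  # nearer source wins
  # two oxidized horizons with identical delta above one source horizon
  p2 <- makeProfile(depth = c(10, 20, 30), d13c = c(-35, -35, -70))
  expect_equal(maxIsotopeShift(p2)@depthO, 20)  # smaller separation wins
})

test_that("SMTZ detection brackets the analytic crossing of linear profiles", {
  d <- 20:30
  p <- makeProfile(depth = d, so4 = seq(10, 0, by = -1),
                   ch4 = seq(0, 500, by = 50))
  # normalized curves cross at 25 m
  smtz <- detectSmtz(p)
  expect_s4_class(smtz, "SmtzInterval")
  expect_lte(smtz@topMbsf, 25)
  expect_gte(smtz@bottomMbsf, 25)
  expect_gte(smtz@sulfateAtTop, 1)
  # interval lies inside the profile depth range
  expect_gte(smtz@topMbsf, min(d))
  expect_lte(smtz@bottomMbsf, max(d))
})

test_that("SMTZ detection refuses degenerate inputs", {
  # sulfate identically zero -> none
  expect_null(detectSmtz(makeProfile(depth = 1:5, so4 = rep(0, 5),
                                     ch4 = 1:5)))
  # both profiles increasing -> gradients not opposing -> none
  expect_null(detectSmtz(makeProfile(depth = 1:5, so4 = 1:5, ch4 = 1:5)))
  # sulfate below the floor everywhere -> none
  expect_null(detectSmtz(makeProfile(depth = 1:5,
                                     so4 = c(0.5, 0.4, 0.3, 0.2, 0.1),
                                     ch4 = c(1, 2, 30, 40, 50))))
  # fewer than 3 co-measured horizons -> insufficient-data error
  expect_error(detectSmtz(makeProfile(depth = 1:3, so4 = c(5, 1, NA),
                                      ch4 = c(1, 10, 20))),
               "insufficient data")
})
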