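# The similarity measure, theta estimators, beta, Tajima's D and the HWE
# filter against hand values and independent oracles.

test_that("folding and maximum folded difference follow their closed forms", {
  expect_equal(foldCount(75, 100), 25)
  expect_equal(foldCount(50, 100), 50)
  expect_equal(foldCount(10, 100), 10)
  expect_equal(foldCount(0, 100), 0)
  expect_error(foldCount(101, 100), "count")

  expect_equal(maxFoldedDiff(50, 100), 50)
  expect_equal(maxFoldedDiff(25, 100), 25)
  expect_equal(maxFoldedDiff(10, 100), 40)
  # odd n keeps n/2 as a real number
  expect_equal(maxFoldedDiff(2, 5), 2)    # max(2, 0.5)
  expect_equal(maxFoldedDiff(1, 5), 1.5)  # max(1, 1.5)
  expect_error(maxFoldedDiff(60, 100), "coreFolded")
})

test_that("similarity hits its stated extremes and hand value", {
  # identical folded frequency -> 1; maximum folded difference -> 0
  expect_equal(freqSimilarity(50, 50, 100, p = 2), 1)
  expect_equal(freqSimilarity(10, 50, 100, p = 2), 0)
  # core 50/100, site 25/100, p = 2 -> ((50-25)/50)^2
  expect_equal(freqSimilarity(50, 25, 100, p = 2), 0.25, tolerance = 1e-12)
  # symmetric in derived/ancestral labelling of either site
  expect_equal(freqSimilarity(30, 20, 100, p = 2),
               freqSimilarity(70, 80, 100, p = 2))
})

test_that("similarity bounds and attainment hold over exhaustive pairs", {
  for (n in c(4L, 7L, 12L, 25L)) {
    for (f0 in 1:(n - 1)) {
      fi <- 1:(n - 1)
      d <- freqSimilarity(f0, fi, n, p = 2)
      expect_true(all(d >= 0 & d <= 1))
      g0 <- min(f0, n - f0)
      gi <- pmin(fi, n - fi)
      m <- max(g0, n / 2 - g0)
      expect_identical(d == 1, gi == g0)
      expect_identical(d == 0, abs(g0 - gi) == m)
    }
  }
})

test_that("proportion-scale similarity handles per-site sample sizes", {
  # same ratios, different n: identical folded proportions give d = 1
  expect_equal(freqSimilarity(50, 40, 100, p = 2, nSite = 80), 1)
  # agrees with count scale when n matches
  expect_equal(freqSimilarity(30, 12, 100, p = 2, nSite = 100),
               freqSimilarity(30, 12, 100, p = 2))
})

test_that("Watterson estimator matches its closed form and an oracle", {
  spec <- windowSpectrum(4, c(`1` = 2, `2` = 1), coreCount = 2)
  expect_equal(thetaWatterson(spec), 18 / 11, tolerance = 1e-12)
  expect_equal(thetaWatterson(windowSpectrum(4, coreCount = 1)), 0)
  expect_equal(thetaWatterson(windowSpectrum(2, c(`1` = 5), coreCount = 1)), 5)

  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:60, 1)
    S <- rpois(n - 1, 0.8)
    spec <- windowSpectrum(n, setNames(S, 1:(n - 1)), coreCount = sample(n - 1, 1))
    expect_equal(thetaWatterson(spec), oracleThetaW(S, n), tolerance = 1e-12)
  }
})

test_that("thetaBeta matches hand evaluation and is linear in S", {
  # n = 4, p = 2, core 2: d = (0.25, 1, 0.25), sum 1.5
  s1 <- windowSpectrum(4, c(`1` = 1, `2` = 1), coreCount = 2)
  expect_equal(thetaBeta(s1, p = 2), 1.5, tolerance = 1e-12)
  s2 <- windowSpectrum(4, c(`2` = 2), coreCount = 2)
  expect_equal(thetaBeta(s2, p = 2), 8 / 3, tolerance = 1e-12)
  expect_equal(thetaBeta(windowSpectrum(4, coreCount = 2), p = 2), 0)

  # adding one SNP at class j raises thetaBeta by exactly j*d_j / sum(d)
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    core <- sample(n - 1, 1)
    S <- rpois(n - 1, 0.5)
    j <- sample(n - 1, 1)
    Sj <- S; Sj[j] <- Sj[j] + 1
    base <- windowSpectrum(n, setNames(S, 1:(n - 1)), coreCount = core)
    bump <- windowSpectrum(n, setNames(Sj, 1:(n - 1)), coreCount = core)
    d <- freqSimilarity(core, 1:(n - 1), n, p = 2)
    expect_equal(thetaBeta(bump, 2) - thetaBeta(base, 2),
                 j * d[j] / sum(d), tolerance = 1e-10)
    expect_equal(thetaBeta(base, 2), oracleThetaBeta(S, n, core, 2),
                 tolerance = 1e-10)
  }
})

test_that("beta composes the two estimators and flags empty windows", {
  s1 <- windowSpectrum(4, c(`1` = 1, `2` = 1), coreCount = 2)
  sc <- betaScore(s1, p = 2)
  expect_equal(sc$beta, 1.5 - 12 / 11, tolerance = 1e-12)
  expect_equal(sc$thetaBeta - sc$thetaW, sc$beta)
  expect_equal(sc$foldedFreq, 0.5)

  # all window SNPs at maximum folded distance: thetaBeta 0, beta = -thetaW
  s0 <- windowSpectrum(100, c(`50` = 4), coreCount = 10)
  sc0 <- betaScore(s0, p = 2)
  expect_equal(sc0$thetaBeta, 0)
  expect_equal(sc0$beta, -sc0$thetaW)

  expect_true(is.na(betaScore(windowSpectrum(4, coreCount = 2), 2)$beta))
})

test_that("beta is invariant to permuting sites within the window", {
  set.seed(21)
  cnt <- sample(1:99, 30, replace = TRUE)
  pos <- sort(sample(500:1500, 30))
  ref <- betaScore(spectrumFromSites(SiteCounts(pos, cnt, 100),
                                     coreCount = 40), 2)$beta
  for (perm in 1:5) {
    sites <- SiteCounts(pos, sample(cnt), 100)  # counts shuffled over positions
    expect_equal(betaScore(spectrumFromSites(sites, coreCount = 40), 2)$beta,
                 ref)
  }
})

test_that("folded beta matches its per-class estimator form and relabeling invariance", {
  # n = 4, core folded 2, p = 2, S* = {2:1}: theta*_2 = 2, weights (0.25, 1)
  sf <- windowSpectrum(4, c(`2` = 1), coreCount = 2, folded = TRUE)
  expect_equal(thetaBeta(sf, p = 2), 1.6, tolerance = 1e-12)

  # relabeling any subset of sites leaves the folded score unchanged
  set.seed(33)
  n <- 10
  cnt <- sample(1:(n - 1), 12, replace = TRUE)
  flip <- runif(12) < 0.5
  flipped <- ifelse(flip, n - cnt, cnt)
  pos <- seq(10, 120, by = 10)
  a <- spectrumFromSites(SiteCounts(pos, cnt, n), coreCount = 4, folded = TRUE)
  b <- spectrumFromSites(SiteCounts(pos, flipped, n), coreCount = n - 4,
                         folded = TRUE)
  expect_equal(betaScore(a, 2), betaScore(b, 2))

  # foldSpectrum pools complementary classes
  u <- windowSpectrum(6, c(`1` = 2, `5` = 1, `3` = 1), coreCount = 4)
  f <- foldSpectrum(u)
  expect_equal(unname(classCounts(f)), c(3, 0, 1))
  expect_equal(coreCount(f), 2L)
  expect_equal(thetaWatterson(f), thetaWatterson(u))
})

test_that("Tajima's D agrees with a haplotype-matrix oracle", {
  cases <- list(list(n = 4, S = c(0, 3, 0)),
                list(n = 6, S = c(2, 1, 0, 1, 1)),
                list(n = 10, S = c(3, 2, 1, 0, 1, 0, 0, 2, 1)))
  for (cs in cases) {
    spec <- windowSpectrum(cs$n, setNames(cs$S, seq_along(cs$S)), coreCount = 1)
    expect_equal(tajimasD(spec),
                 oracleTajimaFromMatrix(matrixFromSpectrum(cs$S, cs$n)),
                 tolerance = 1e-10)
  }
  # singleton-free intermediate window: D equals the folded computation
  u <- windowSpectrum(8, c(`2` = 2, `6` = 1, `4` = 1), coreCount = 4)
  expect_equal(tajimasD(u), tajimasD(foldSpectrum(u)), tolerance = 1e-12)
  expect_true(is.na(tajimasD(windowSpectrum(4, coreCount = 2))))
})

test_that("HWE exact test matches exhaustive enumeration", {
  for (N in c(3L, 5L, 6L)) {
    for (nA in 1:(2 * N - 1)) {
      dist <- oracleHWEDistribution(N, nA)
      hVals <- as.integer(names(dist))
      for (hObs in hVals) {
        nAA <- (nA - hObs) / 2
        nBB <- (2 * N - nA - hObs) / 2
        got <- hweExactTest(nAA, hObs, nBB)
        pObs <- dist[[as.character(hObs)]]
        expect_equal(got$pHetExcess, sum(dist[hVals >= hObs]),
                     tolerance = 1e-9)
        expect_equal(got$pTwoSided,
                     sum(dist[as.numeric(dist) <= pObs * (1 + 1e-9)]),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("HWE exact test handles edge inputs", {
  expect_equal(hweExactTest(10, 0, 0), list(pHetExcess = 1, pTwoSided = 1))
  # 2 diploids, one allele of each pair: het counts 0 or 2
  res <- hweExactTest(0, 2, 0)
  # P(h=2) = 2/3 under the conditional distribution
  expect_equal(res$pHetExcess, 2 / 3, tolerance = 1e-12)
  expect_error(hweExactTest(0, 0, 0), "at least one")
  expect_error(hweExactTest(-1, 2, 0), "non-negative")
  res2 <- hweExactTest(25, 50, 25)
  expect_true(res2$pTwoSided > 0 && res2$pTwoSided <= 1)
  expect_true(res2$pHetExcess > 0 && res2$pHetExcess <= 1)
})
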