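# Forward simulator, coalescent null, frequency matching and the power
# harness.  Monte-Carlo checks run on deliberately small configurations.

test_that("overdominance equilibrium frequencies match the fitness scheme", {
  expect_equal(equilibriumFrequency(1.5), 0.75)
  expect_equal(equilibriumFrequency(-0.5, -0.01), 0.25)
  expect_equal(equilibriumFrequency(-0.25, -0.01), 1 / 6)
  expect_equal(equilibriumFrequency(1.25), 5 / 6)
  expect_equal(equilibriumFrequency(100), 100 / 199)

  # numerical cross-check: the deterministic per-generation change
  # q' = q(q*wHom + (1-q)*wHet) / wBar vanishes at the closed form
  deltaQ <- function(q, h, s) {
    wHet <- 1 + h * s; wHom <- 1 + s
    wBar <- q^2 * wHom + 2 * q * (1 - q) * wHet + (1 - q)^2
    q * (q * wHom + (1 - q) * wHet) / wBar - q
  }
  for (hs in list(c(1.5, 0.01), c(-0.5, -0.01), c(100, 0.01), c(1.25, 1e-4))) {
    q <- equilibriumFrequency(hs[1], hs[2])
    expect_equal(deltaQ(q, hs[1], hs[2]), 0, tolerance = 1e-12)
    # stability: displacement decays back towards q*
    expect_lt(deltaQ(q + 0.05, hs[1], hs[2]), 0)
    expect_gt(deltaQ(q - 0.05, hs[1], hs[2]), 0)
  }

  expect_error(equilibriumFrequency(0.5), "no stable interior equilibrium")
  expect_error(equilibriumFrequency(1.5, -0.01), "protected")
  expect_equal(hForEquilibrium(0.75), 1.5)
  expect_error(hForEquilibrium(0.5), "diverges")
})

test_that("forward runs are bit-identical under a fixed seed", {
  cfg <- miniSimConfig(seed = 4242)
  a <- runForward(cfg, balanced = TRUE)
  b <- runForward(cfg, balanced = TRUE)
  expect_identical(as.data.frame(simSites(a)), as.data.frame(simSites(b)))
  expect_identical(substitutions(a), substitutions(b))
  expect_identical(a@balancedCount, b@balancedCount)
  c <- runForward(simConfig(Ne = 500, mu = 1e-6, r = 1e-6, L = 2000,
                            burnIn = 4000, splitGens = 3000, tSel = 3000,
                            nSample = 20L, seed = 4243), balanced = TRUE)
  expect_false(identical(as.data.frame(simSites(a)), as.data.frame(simSites(c))))
})

test_that("neutral forward segregating sites match Watterson's expectation", {
  # theta = 4*500*1e-6*2000 = 4; E[S] = theta * a_19 ~ 14.2
  reps <- lapply(1:60, function(i)
    runForward(miniSimConfig(seed = 100 + i, outgroup = FALSE), FALSE))
  S <- vapply(reps, function(r) length(simSites(r)), numeric(1))
  theta <- 4 * 500 * 1e-6 * 2000
  expS <- theta * sum(1 / 1:19)
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expS), 3 * se + 1e-9)
  # counts are in 1..n-1
  expect_true(all(vapply(reps, function(r) {
    cnt <- derivedCounts(simSites(r))
    all(cnt >= 1 & cnt <= 19)
  }, logical(1))))
})

test_that("coalescent replicates match the forward neutral arm and D ~ 0", {
  cfg <- simConfig(Ne = 500, mu = 1e-6, r = 1e-6, L = 2000, nSample = 20L,
                   seed = 314)
  reps <- runNeutralCoalescent(cfg, 150)
  S <- vapply(reps, function(r) length(simSites(r)), numeric(1))
  theta <- 4 * 500 * 1e-6 * 2000
  expS <- theta * sum(1 / 1:19)
  expect_lt(abs(mean(S) - expS), 3 * sd(S) / sqrt(length(S)))

  D <- vapply(reps, function(r) {
    s <- simSites(r)
    if (length(s) < 2) return(NA_real_)
    tajimasD(spectrumFromSites(s, coreCount = derivedCounts(s)[1]))
  }, numeric(1))
  D <- D[!is.na(D)]
  expect_lt(abs(mean(D)), 3 * sd(D) / sqrt(length(D)) + 0.05)

  # reproducibility under the config seed
  again <- runNeutralCoalescent(cfg, 150)
  expect_identical(as.data.frame(simSites(reps[[7]])),
                   as.data.frame(simSites(again[[7]])))
})

test_that("rescaling by Q preserves diversity at matched theta and times", {
  base <- lapply(1:40, function(i)
    runForward(simConfig(Ne = 400, mu = 2.5e-6, r = 2.5e-6, L = 1000,
                         burnIn = 4000, splitGens = 2000, tSel = 2000,
                         nSample = 20L, outgroup = FALSE, seed = 9000 + i),
               FALSE))
  scaled <- lapply(1:40, function(i)
    runForward(simConfig(Ne = 400, mu = 2.5e-6, r = 2.5e-6, L = 1000,
                         burnIn = 4000, splitGens = 2000, tSel = 2000,
                         nSample = 20L, outgroup = FALSE, rescaleQ = 4,
                         seed = 9500 + i), FALSE))
  S1 <- vapply(base, function(r) length(simSites(r)), numeric(1))
  S2 <- vapply(scaled, function(r) length(simSites(r)), numeric(1))
  se <- sqrt(var(S1) / length(S1) + var(S2) / length(S2))
  expect_lt(abs(mean(S1) - mean(S2)), 3 * se)
})

test_that("balanced runs are conditioned on maintenance and hit equilibrium", {
  reps <- lapply(1:40, function(i)
    runForward(miniSimConfig(seed = 7000 + i, outgroup = FALSE, s = 0.05),
               balanced = TRUE))
  freq <- vapply(reps, function(r) r@balancedCount / 20, numeric(1))
  # never lost at sampling (population-level conditioning)
  expect_true(all(vapply(reps, function(r) r@balancedCount >= 0, logical(1))))
  # h = 1.5: equilibrium 0.75; binomial + drift scatter around it
  expect_lt(abs(mean(freq) - 0.75), 3 * sd(freq) / sqrt(length(freq)) + 0.02)
  expect_true(any(vapply(reps, function(r) r@restarts > 0, logical(1))))
  # the balanced site is reported at the region centre
  expect_true(all(vapply(reps, function(r)
    abs(r@balancedPosition - 1001) <= 2, logical(1))))
})

test_that("substitutions accumulate on both lineages after the split", {
  reps <- lapply(1:20, function(i)
    runForward(miniSimConfig(seed = 3000 + i), FALSE))
  nSub <- vapply(reps, function(r) length(substitutions(r)), numeric(1))
  # expected ~ 2 * splitGens * mu * L fixed differences plus sorted
  # ancestral polymorphism; must be positive and of that order
  expSub <- 2 * 3000 * 1e-6 * 2000
  expect_gt(mean(nSub), expSub * 0.5)
  expect_lt(mean(nSub), expSub * 3)
})

test_that("frequency matching selects the stated bands", {
  sites <- SiteCounts(c(10L, 20L, 30L, 40L), c(44L, 50L, 54L, 70L), 100L)
  res <- list(new("SimResult", sites = sites),
              new("SimResult", sites = SiteCounts(5L, 10L, 100L)))
  # relative band: 0.5 +/- 10% -> [0.45, 0.55]
  m <- suppressMessages(matchNeutralCores(res, 0.5, tolerance = 0.10))
  expect_equal(m$position, c(20L, 30L))  # 0.44 just outside, 0.70 outside
  expect_equal(attr(m, "skipped"), 1L)
  # absolute band: 0.5 +/- 0.10 -> [0.40, 0.60]
  mAbs <- suppressMessages(matchNeutralCores(res, 0.5, tolerance = 0.10,
                                             relative = FALSE))
  expect_equal(mAbs$position, c(10L, 20L, 30L))
  # exact hit is accepted; closest-first capping
  m1 <- suppressMessages(matchNeutralCores(res, 0.5, maxPerReplicate = 1))
  expect_equal(m1$position, 20L)
})

test_that("power analysis reproduces separable, null and Gaussian cases", {
  # fully separable scores -> power 1 at any FPR
  sep <- powerAnalysis(101:200, 1:100)
  expect_equal(sep$power$power, c(1, 1))
  expect_equal(sep$auc, 1)

  # identical distributions -> power ~ FPR
  set.seed(12)
  x <- rnorm(4000); y <- rnorm(4000)
  nul <- powerAnalysis(x, y, fprGrid = 0.05)
  expect_lt(abs(nul$power$power - 0.05), 0.03)

  # N(1,1) vs N(0,1) at FPR 0.05: power = Phi(1 - z_0.95) ~ 0.26
  b <- rnorm(20000, mean = 1)
  n <- rnorm(20000)
  g <- powerAnalysis(b, n, fprGrid = 0.05)
  expect_lt(abs(g$power$power - pnorm(1 - qnorm(0.95))), 0.03)

  expect_warning(powerAnalysis(rep(1, 10), rep(1, 10)), "degenerate")
})

test_that("build-up fractions require a core site and respect the band", {
  sites <- SiteCounts(c(100L, 200L, 300L, 400L), c(48L, 50L, 10L, 52L), 100L)
  res <- new("SimResult", sites = sites)
  # core 200 (0.50): neighbours folded 0.48, 0.10, 0.48 -> 2/3 within 0.05
  expect_equal(classBuildupFraction(res, 200L, windowBp = 1000), 2 / 3)
  expect_error(classBuildupFraction(res, 999L), "not a segregating site")
  lone <- new("SimResult", sites = SiteCounts(c(100L, 5000L), c(50L, 40L), 100L))
  expect_true(is.na(classBuildupFraction(lone, 100L, windowBp = 1000)))
})
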