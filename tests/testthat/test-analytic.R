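test_that("closed-form total population has the right limits", {
  p <- refParams(N0 = 1000, XStarOffsetIn = 1)
  sol <- analyticSolution(p)
  expect_equal(totalPopulation(sol, 0), 1000)
  expect_error(totalPopulation(sol, -1), ">= 0")

  # no-mutation limit: pure exponential at the linear growth rate
  p0 <- refParams(N0 = 1000, XStarOffsetIn = 1, pMutatedDaughter = 0)
  sol0 <- analyticSolution(p0)
  tt <- c(0.5, 1, 2, 4)
  expect_equal(totalPopulation(sol0, tt), 1000 * exp(-0.7 * 1 * tt))
})

test_that("selection off collapses mutation factors to plain Poisson bookkeeping", {
  # b -> 0: every per-class factor exp(m_i[(e^{g t}-1)/g - t]) -> 1, so the
  # total reduces to N0 (zero growth at any affinity) and per-count
  # subpopulations are exactly N0 * Poisson(m_i t)
  p <- modelParams(b = 1e-9, N0 = 1e4, XStarOffsetIn = 1)
  rt <- deriveRates(p)
  sol <- analyticSolution(p, singleBeneficial())
  t <- 2.5
  expect_equal(totalPopulation(sol, t), 1e4 * exp(-1e-9 * t), tolerance = 1e-9)
  for (j in 0:6)
    expect_equal(subpopulationSize(sol, t, 1L, j),
                 1e4 * exp(-p@b * 1 * t) * dpois(j, rt@mAff * t),
                 tolerance = 1e-6)
  # continuity in b near 0 against the default selection strength scale
  pEps <- modelParams(b = 1e-6, N0 = 1e4, XStarOffsetIn = 1)
  expect_equal(totalPopulation(analyticSolution(pEps, singleBeneficial()), t),
               totalPopulation(sol, t), tolerance = 1e-4)
})

test_that("single-class subpopulations sum to the total population", {
  p <- refParams(N0 = 500, XStarOffsetIn = 1)
  sol <- analyticSolution(p, singleBeneficial())
  for (t in c(0.5, 2, 5)) {
    js <- 0:80
    expect_equal(sum(subpopulationSize(sol, t, 1L, js)),
                 totalPopulation(sol, t), tolerance = 1e-12)
  }
  expect_error(subpopulationSize(sol, 1, 1L, -1), "non-negative")
})

test_that("multi-class totals factor into per-class mutation factors", {
  p <- refParams(N0 = 100, XStarOffsetIn = 1)
  sp <- defaultSpectrum()
  full <- totalPopulation(analyticSolution(p, sp), 3)
  # product of single-class factors over the common growth term
  growth <- 100 * exp(-0.7 * 1 * 3)
  fac <- 1
  rt <- deriveRates(p)
  for (i in seq_along(sp@offsets)) {
    g <- -p@b * sp@offsets[i]
    m <- rt@mAff * sp@weights[i]
    fac <- fac * exp(m * ((exp(g * 3) - 1) / g - 3))
  }
  expect_equal(full, growth * fac, tolerance = 1e-12)
})

test_that("subpopulations grow like t^j at short times (mutation-fed regime)", {
  p <- refParams(N0 = 1e6, XStarOffsetIn = 1)
  sol <- analyticSolution(p, singleBeneficial())
  tt <- seq(0.002, 0.01, length.out = 5) / (p@b * p@h) # t << 1/bh
  for (j in 1:3) {
    nj <- vapply(tt, function(t) subpopulationSize(sol, t, 1L, j), numeric(1))
    slope <- coef(lm(log(nj) ~ log(tt)))[2]
    expect_equal(unname(slope), j, tolerance = 0.02)
  }
})

test_that("the largest subpopulation index is the Poisson mode and advances in t", {
  p <- refParams(N0 = 100, XStarOffsetIn = 1)
  sol <- analyticSolution(p, singleBeneficial())
  rt <- deriveRates(p)
  expect_equal(peakMutationCount(sol, 1e-9), 0L)
  # recompute lambda independently and check the floor at several times
  for (t in c(1, 3, 6, 9)) {
    g <- 0.7 * 0.5
    lam <- rt@mAff * (exp(g * t) - 1) / g
    expect_equal(peakMutationCount(sol, t), as.integer(floor(lam)))
  }
  pk <- vapply(seq(0.1, 10, by = 0.1), function(t) peakMutationCount(sol, t),
               integer(1))
  expect_true(all(diff(pk) >= 0))
  solDel <- analyticSolution(p, singleDeleterious())
  expect_error(peakMutationCount(solDel, 1), "beneficial")
})

test_that("Gaussian initial profiles drift at -b sigma^2 per day with fixed width", {
  p <- refParams(N0 = 1000, XStarOffsetIn = 0.5)
  sol <- analyticSolution(p, Xin = 0.5, N0 = 1000, sigma = 0.4)
  x <- seq(-6, 6, by = 0.001)
  expect_equal(gaussianProfile(sol, x, 0), 1000 * dnorm(x, 0.5, 0.4))
  for (t in c(1, 3)) {
    prof <- gaussianProfile(sol, x, t)
    m <- sum(x * prof) / sum(prof) # numeric quadrature
    expect_equal(m, 0.5 - 0.7 * 0.4^2 * t, tolerance = 1e-6)
    # integral equals the mutation-free closed-form total
    pm <- modelParams(b = 0.7, pMutatedDaughter = 0, XStarOffsetIn = 0.5, N0 = 1000)
    solm <- analyticSolution(pm, Xin = 0.5, N0 = 1000, sigma = 0.4)
    expect_equal(sum(prof) * 0.001, totalPopulation(solm, t), tolerance = 1e-5)
  }
  expect_error(analyticSolution(p, sigma = -1), "sigma")
})

test_that("evaluation warns when the linear-growth assumption breaks down", {
  # strongly beneficial class pushes the dominant subpopulation past -D
  p <- refParams(N0 = 1e6, XStarOffsetIn = 1)
  sol <- analyticSolution(p, mutationSpectrum(-1, 1, binWidth = 0.5))
  expect_warning(totalPopulation(sol, 12), "saturation|linear-growth")
  expect_silent(totalPopulation(sol, 0.5))
})
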