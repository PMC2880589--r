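test_that("a lone bin evolves by the closed-form growth factor when mutation is off", {
  p <- modelParams(pMutatedDaughter = 0, N0 = 1000, XStarOffsetIn = 1)
  g <- gcGrid(p)
  st <- populationState(g, ifelse(g == 1, 1000, 0))
  dt <- 0.01 / (p@b * p@h) # 0.02857 d
  st2 <- stepPopulation(st, p, dt = dt)
  expect_equal(max(st2@counts), 1000 * exp(-0.7 * dt)) # factor 0.9802
  expect_equal(sum(st2@counts > 0), 1L)
  expect_equal(st2@time, dt)
})

test_that("mutation influx matches the first-order rate and respects the cutoff", {
  p <- refParams(N0 = 1000, XStarOffsetIn = 1)
  rt <- deriveRates(p)
  g <- gcGrid(p)
  dt <- 1e-4
  st <- populationState(g, ifelse(g == 1, 1000, 0))
  st2 <- stepPopulation(st, p, spectrum = singleBeneficial(), dt = dt)
  gained <- st2@counts[g == 0.5]
  expect_equal(gained, 1000 * rt@mAff * dt, tolerance = 1e-2)

  # a sub-unity source bin is frozen: no growth, no decay, no emission
  stSub <- populationState(g, ifelse(g == 1, 0.5, 0))
  st3 <- stepPopulation(stSub, p, spectrum = singleBeneficial(), dt = 0.02)
  expect_equal(st3@counts, stSub@counts)
})

test_that("the mutation operator conserves cells when growth and lethality are off", {
  p <- modelParams(b = 1e-12, fLethal = 0, fSilent = 0.5, fAffinity = 0.5,
                   N0 = 1000, XStarOffsetIn = 0)
  g <- seq(-10, 10, by = 0.5)
  st <- populationState(g, rep(10, length(g)))
  for (i in 1:5) st <- stepPopulation(st, p, dt = 0.02, cutoff = FALSE)
  expect_equal(sum(st@counts) + sum(st@edgeLoss), 10 * length(g),
               tolerance = 1e-12)
})

test_that("stepper rejects degenerate input", {
  p <- refParams()
  g <- gcGrid(p)
  st <- populationState(g, ifelse(g == 1, 10, 0))
  expect_error(stepPopulation(st, p, dt = 0), "dt")
  expect_error(simulateGC(refParams(XStarOffsetIn = 30)), "outside the grid")
})

test_that("halving the time step leaves the trajectory essentially unchanged", {
  # decreasing stage: smooth convergence; after the bottleneck the one-cell
  # cutoff makes bin activation times shift with dt and the exponential
  # regrowth amplifies them, so the day-14 improvement converges more slowly
  for (tm in c(3, 6)) {
    p <- refParams(N0 = 1e5, tMax = tm)
    a <- simulateGC(p, termination = "horizon_only", dtFactor = 0.01)
    b <- simulateGC(p, termination = "horizon_only", dtFactor = 0.005)
    expect_equal(tail(a@Ntot, 1), tail(b@Ntot, 1), tolerance = 5e-3)
  }
  p <- refParams(N0 = 1e5)
  a <- simulateGC(p, termination = "fixed_window_14d", dtFactor = 0.01)
  b <- simulateGC(p, termination = "fixed_window_14d", dtFactor = 0.005)
  expect_equal(improvement(a), improvement(b), tolerance = 5e-2)
})

test_that("populations shrink through a bottleneck and then regrow", {
  # germline binding one bin weaker than neutral, large initial population
  p <- refParams(N0 = 1e6, XStarOffsetIn = 1)
  tr <- simulateGC(p, termination = "recovery_unbounded")
  expect_equal(tr@status, "recovered")
  expect_gt(tr@bottleneckTime, 1)
  expect_lt(tr@bottleneckDepth, 0.05 * p@N0)
  expect_lt(tr@tEnd, p@tMax)
  # N decreases to the bottleneck and increases after it
  ib <- which.min(tr@Ntot)
  expect_true(all(diff(tr@Ntot[1:ib]) <= 1e-9))
  expect_gt(tail(tr@Ntot, 1), tr@bottleneckDepth)
  expect_gte(tail(tr@Ntot, 1), p@N0)
})

test_that("small founding populations go extinct at the bottleneck", {
  pSmall <- refParams(N0 = 500, XStarOffsetIn = 1)
  trS <- simulateGC(pSmall, termination = "recovery_unbounded")
  expect_equal(trS@status, "extinct")
  expect_equal(improvement(trS), 0)
  # the same binding level is survivable for a large enough population
  pBig <- refParams(N0 = 1e5, XStarOffsetIn = 1)
  expect_equal(simulateGC(pBig, termination = "recovery_unbounded")@status,
               "recovered")
})

test_that("a supercritical start recovers immediately with no bottleneck", {
  p <- refParams(N0 = 1000, XStarOffsetIn = -1)
  tr <- simulateGC(p, termination = "recovery_unbounded")
  expect_equal(tr@status, "recovered")
  expect_equal(tr@bottleneckTime, 0)
  expect_true(all(diff(tr@Ntot) > 0))
})

test_that("the strong fraction is non-decreasing once strong cells appear", {
  tr <- simulateGC(refParams(N0 = 1e5), termination = "recovery_unbounded")
  i0 <- which(tr@F > 0)[1]
  expect_true(all(diff(tr@F[i0:length(tr@F)]) >= -1e-9))
})

test_that("edge losses are dynamically negligible on the default grid", {
  p <- refParams(N0 = 1e5)
  tr <- simulateGC(p, termination = "recovery_unbounded")
  expect_lt(sum(tr@edgeLoss), 1e-3 * max(tr@Ntot))
  # widening the grid further does not change the result
  trWide <- simulateGC(p, termination = "recovery_unbounded",
                       grid = seq(-8, 12, by = 0.5))
  expect_equal(improvement(tr), improvement(trWide), tolerance = 1e-6)
  expect_equal(tr@tEnd, trWide@tEnd)
})

test_that("improvement reports A(t_end)/A(0) with the extinct-run convention", {
  p <- refParams(N0 = 1e5)
  tr <- simulateGC(p, termination = "fixed_window_14d")
  expect_equal(improvement(tr), tail(tr@A, 1) / tr@A0)
  expect_gt(tr@A0, 0)
  expect_true(all(tr@A > 0))
})

test_that("the 14-day window truncates slow recoveries", {
  p <- refParams(N0 = 1e5, XStarOffsetIn = 1)
  trA <- simulateGC(p, termination = "fixed_window_14d")
  trB <- simulateGC(p, termination = "recovery_unbounded")
  expect_equal(trA@status, "timed_out")
  expect_lte(trA@tEnd, 14 + 0.03)
  expect_equal(trB@status, "recovered")
  expect_gt(trB@tEnd, 14)
  expect_lte(improvement(trA), improvement(trB))
})

test_that("trajectory TSV export carries provenance and parses back", {
  tr <- simulateGC(refParams(N0 = 1e5, tMax = 2), termination = "horizon_only")
  f <- tempfile(fileext = ".tsv")
  writeTrajectory(tr, f, header = c("prov line"), every = 10L)
  lines <- readLines(f)
  expect_true(any(grepl("^# prov line", lines)))
  tab <- read.delim(f, comment.char = "#")
  expect_equal(names(tab), c("t_days", "N_tot", "A_over_A0", "F"))
  expect_equal(tab$N_tot[1], tr@Ntot[1])
  expect_equal(tail(tab$t_days, 1), tr@tEnd, tolerance = 1e-6)
})
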