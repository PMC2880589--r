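test_that("ddG values are binned to nearest centers, verified independently", {
  vals <- c(-0.6, -0.4, 0.2, 0.3, 0.7, 1.3)
  sp <- spectrumFromDdg(vals, h = 0.5)
  # independent brute-force assignment (helper): -0.5 x2, 0.0, 0.5 x2, 1.5
  bf <- bruteForceBin(vals, 0.5)
  expect_equal(sp@offsets, sort(unique(bf)))
  expect_equal(sp@weights,
               as.numeric(table(bf)[as.character(sort(unique(bf)))]) / length(vals))
  expect_equal(sp@offsets, c(-0.5, 0.0, 0.5, 1.5))
  expect_equal(sp@weights, c(2, 1, 2, 1) / 6)

  expect_equal(spectrumFromDdg(0.5)@weights, 1)
  expect_equal(spectrumFromDdg(0.5)@offsets, 0.5)
  expect_error(spectrumFromDdg(numeric(0)), "empty")
  expect_error(spectrumFromDdg(c(0.5, NA, 1)), "row 2")
})

test_that("half-way ties round away from zero", {
  expect_equal(spectrumFromDdg(0.25, h = 0.5)@offsets, 0.5)
  expect_equal(spectrumFromDdg(-0.25, h = 0.5)@offsets, -0.5)
  expect_equal(spectrumFromDdg(0.75, h = 0.5)@offsets, 1.0)
})

test_that("spectra are invariant under permutation of the input table", {
  set.seed(3)
  vals <- rnorm(200)
  a <- spectrumFromDdg(vals)
  b <- spectrumFromDdg(sample(vals))
  expect_equal(a@offsets, b@offsets)
  expect_equal(a@weights, b@weights)
})

test_that("packaged default spectrum satisfies the published constraints", {
  sp <- defaultSpectrum()
  expect_equal(sum(sp@weights), 1)
  s <- spectrumSummary(sp)
  expect_equal(s$beneficialFraction, 0.049) # 4.9% of mutations improve affinity
  expect_equal(s$strongBeneficialFraction, 0.014) # 1.4% improve at least 5-fold
  # 5-fold in Ka is less than two bin widths
  expect_lt(-0.59 * log(5), -0.5)
  expect_gt(-0.59 * log(5), -1.0)
  # weighted mean beneficial step of the packaged weights
  expect_equal(s$meanBeneficialStep, (0.035 * 0.5 + 0.014 * 1.0) / 0.049)
  # deleterious side decays
  del <- sp@weights[sp@offsets > 0]
  expect_true(all(diff(del) < 0))
})

test_that("single-bin spectrum summarizes trivially", {
  s <- spectrumSummary(singleBeneficial())
  expect_equal(s$beneficialFraction, 1)
  expect_equal(s$meanBeneficialStep, 0.5)
  expect_true(is.na(s$meanDeleteriousStep))
})

test_that("re-binning samples from a known spectrum recovers its weights", {
  sp <- defaultSpectrum()
  n <- 1e5
  set.seed(42)
  centers <- sample(sp@offsets, n, replace = TRUE, prob = sp@weights)
  vals <- centers + runif(n, -0.12, 0.12) # stays within the source bin
  rec <- spectrumFromDdg(vals, h = 0.5)
  expect_equal(rec@offsets, sp@offsets)
  # binomial Monte-Carlo error, 4 sigma
  tol <- 4 * sqrt(sp@weights * (1 - sp@weights) / n)
  expect_true(all(abs(rec@weights - sp@weights) < tol))
})

test_that("spectrum TSV round-trips and ddG tables parse with extra columns", {
  sp <- defaultSpectrum()
  f <- tempfile(fileext = ".tsv")
  writeSpectrum(sp, f, header = "test")
  back <- readSpectrum(f)
  expect_equal(back@offsets, sp@offsets)
  expect_equal(back@weights, sp@weights, tolerance = 1e-9)

  g <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "mutation\tddG_kcal_per_mol\tnote",
               "A12V\t-0.6\tx", "K3R\t0.7\ty"), g)
  tab <- readDdgTable(g)
  expect_equal(tab@offsets, c(-0.5, 0.5))
  expect_error(readDdgTable(tempfile()), "not found")
  writeLines("a\tb\n1\t2", g)
  expect_error(readDdgTable(g), "ddG_kcal_per_mol")
})

test_that("spectrum validity rejects malformed inputs", {
  expect_error(mutationSpectrum(c(0.5, 0.5), c(0.5, 0.5)), "strictly increasing")
  expect_error(mutationSpectrum(0.3, 1, binWidth = 0.5), "multiples")
  expect_error(mutationSpectrum(c(-0.5, 0.5), c(0.6, 0.6)), "sum to 1")
})
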