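test_that("a one-cell grid reduces to a single simulation", {
  sw <- sweepGrid(pGrid = 0.5, kaGrid = 0.18, b = 0.7, N0 = 1e5, mode = "A")
  tr <- simulateGC(modelParams(b = 0.7, pMutatedDaughter = 0.5,
                               XStarOffsetIn = -0.59 * log(0.18), N0 = 1e5),
                   termination = "fixed_window_14d")
  expect_equal(sw@improvement[1, 1], improvement(tr))
  expect_equal(sw@status[1, 1], tr@status)
  expect_equal(sw@tEnd[1, 1], tr@tEnd)
})

test_that("optimum finding breaks ties toward faster and lower-mutation cells", {
  mk <- function(imp, tend) new("SweepResult",
    pGrid = c(0.4, 0.5), kaGrid = c(0.2, 0.5), b = 0.7, mode = "B",
    improvement = imp, survival = (imp > 0) * 1,
    status = matrix("recovered", 2, 2), tEnd = tend)
  # unique maximum
  sw <- mk(matrix(c(1, 5, 2, 3), 2, 2), matrix(10, 2, 2))
  opt <- findOptimum(sw)
  expect_equal(opt$improvement, 5)
  expect_equal(opt$p, 0.5)
  expect_equal(opt$kaIn, 0.2)
  # tie broken toward smaller tEnd
  sw2 <- mk(matrix(c(5, 5, 1, 1), 2, 2), matrix(c(12, 9, 5, 5), 2, 2))
  expect_equal(findOptimum(sw2)$tEnd, 9)
  # then toward smaller p
  sw3 <- mk(matrix(c(5, 5, 1, 1), 2, 2), matrix(10, 2, 2))
  expect_equal(findOptimum(sw3)$p, 0.4)
  # all-extinct grid errors
  sw4 <- mk(matrix(0, 2, 2), matrix(NA_real_, 2, 2))
  expect_error(findOptimum(sw4), "no surviving")
})

test_that("truncating at 14 days can only reduce the improvement", {
  ka <- c(1, 0.45, 0.285)
  swA <- sweepGrid(pGrid = c(0.5, 0.6), kaGrid = ka, N0 = 3000, mode = "A")
  swB <- sweepGrid(pGrid = c(0.5, 0.6), kaGrid = ka, N0 = 3000, mode = "B")
  both <- swA@status == "recovered" & swB@status == "recovered"
  expect_true(any(both))
  expect_true(all(swA@improvement[both] <= swB@improvement[both] + 1e-9))
})

test_that("weaker initial binding improves affinity more, up to extinction", {
  ka <- c(1, 0.66, 0.45, 0.285, 0.18, 0.05)
  sw <- sweepGrid(pGrid = 0.5, kaGrid = ka, N0 = 3000, mode = "B")
  imp <- sw@improvement[1, ]
  rec <- sw@status[1, ] == "recovered"
  # improvement grows as ka decreases while the population still recovers
  expect_true(all(diff(imp[rec]) >= -1e-9))
  # and an extinction region exists at weak binding
  expect_true(any(!rec))
  expect_true(all(imp[!rec] == 0))
})

test_that("identical sweep arms give a migration ratio of one", {
  mc <- migrationComparison(pGrid = c(0.5, 0.6), kaGrid = c(0.45, 0.285),
                            pooledN0 = 3000, isolatedN0 = 3000,
                            pooledMode = "B", isolatedMode = "B")
  expect_equal(mc$ratio, 1)
  expect_equal(mc$pooled$improvement, mc$isolated$improvement)
})

test_that("part of the migration advantage is the affordable binding level", {
  # restricting the pooled arm to the isolated arm's optimal (stronger)
  # binding level forfeits improvement, shrinking the pooled/isolated ratio
  pg <- c(0.5, 0.6)
  full <- migrationComparison(pGrid = pg, kaGrid = c(1, 0.45, 0.285))
  iso <- full$isolated
  restricted <- sweepGrid(pGrid = pg, kaGrid = iso$kaIn, N0 = 1e5, mode = "A")
  ratioRestricted <- findOptimum(restricted)$improvement / iso$improvement
  expect_lte(ratioRestricted, full$ratio + 1e-9)
})

test_that("sweep TSV export is long-format with provenance", {
  sw <- sweepGrid(pGrid = c(0.5, 0.6), kaGrid = c(0.45, 1), N0 = 3000, mode = "A")
  f <- tempfile(fileext = ".tsv")
  writeSweep(sw, f, header = "prov")
  tab <- read.delim(f, comment.char = "#")
  expect_equal(nrow(tab), 4)
  expect_equal(names(tab), c("p", "ka_in_ratio", "b", "improvement",
                             "survival", "status", "t_end_days"))
  expect_equal(sort(unique(tab$p)), c(0.5, 0.6))
})
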