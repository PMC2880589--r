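#' @include AllClasses.R AllGenerics.R params.R spectrum.R simulate.R stochastic.R
NULL

#' Default sweep axes
#'
#' Mutated-daughter fractions 0.1..0.9 and 12 log-spaced initial binding
#' levels Ka_in/Ka* in [0.01, 1].
#'
#' @name sweepDefaults
#' @export
defaultPGrid <- function() seq(0.1, 0.9, by = 0.1)

#' @rdname sweepDefaults
#' @export
defaultKaGrid <- function() exp(seq(log(0.01), log(1), length.out = 12))

#' Sweep the (mutation load x initial binding) parameter plane
#'
#' Runs the deterministic integrator for every grid cell and collects the
#' fold-improvement of total affinity (0 for extinct cells), per-cell
#' termination status and time, and a survival layer: either the
#' deterministic 0/1 indicator (recovered or not) or, when
#' `stochasticSurvival = TRUE`, a branching-process estimate from
#' [survivalProbability()].
#'
#' @param pGrid mutated-daughter fractions.
#' @param kaGrid initial binding levels Ka_in/Ka*.
#' @param b selection strength.
#' @param N0 initial population (1e5 pooled spleen; 3000 isolated GC).
#' @param mode `"A"` (fixed 14-day window, pooled-spleen convention) or
#'   `"B"` (recovery however long it takes).
#' @param spectrum a [MutationSpectrum-class].
#' @param params template [ModelParams-class] supplying the remaining
#'   constants.
#' @param stochasticSurvival estimate survival stochastically.
#' @param replicates,baseSeed for the stochastic survival layer.
#' @param ... passed to [simulateGC()].
#' @return a [SweepResult-class].
#' @export
sweepGrid <- function(pGrid = defaultPGrid(), kaGrid = defaultKaGrid(),
                      b = 0.7, N0 = 1e5, mode = c("A", "B"),
                      spectrum = defaultSpectrum(),
                      params = modelParams(b = b, N0 = N0),
                      stochasticSurvival = FALSE, replicates = 100L,
                      baseSeed = 1L, ...) {
  mode <- match.arg(mode)
  stopifnot(length(pGrid) >= 1, length(kaGrid) >= 1)
  term <- if (mode == "A") "fixed_window_14d" else "recovery_unbounded"
  np <- length(pGrid); nk <- length(kaGrid)
  imp <- matrix(0, np, nk); surv <- matrix(0, np, nk)
  stat <- matrix("", np, nk); tend <- matrix(NA_real_, np, nk)
  for (i in seq_len(np)) for (j in seq_len(nk)) {
    pr <- modelParams(b = b, pMutatedDaughter = pGrid[i],
                      XStarOffsetIn = -params@kT * log(kaGrid[j]),
                      N0 = N0, divisionsPerDay = params@divisionsPerDay,
                      kT = params@kT, h = params@h, fSilent = params@fSilent,
                      fLethal = params@fLethal, fAffinity = params@fAffinity,
                      tMax = params@tMax)
    tr <- tryCatch(simulateGC(pr, spectrum, termination = term, ...),
                   error = function(e) e)
    if (inherits(tr, "error")) {
      stat[i, j] <- paste0("error: ", conditionMessage(tr))
      next
    }
    imp[i, j] <- improvement(tr)
    stat[i, j] <- tr@status
    tend[i, j] <- tr@tEnd
    surv[i, j] <- if (stochasticSurvival) {
      survivalProbability(pr, spectrum, replicates = replicates,
                          baseSeed = baseSeed + 1000L * i + j)$probability
    } else as.numeric(tr@status == "recovered")
  }
  new("SweepResult", pGrid = pGrid, kaGrid = kaGrid, b = b, mode = mode,
      improvement = imp, survival = surv, status = stat, tEnd = tend)
}

#' @describeIn findOptimum argmax of the improvement matrix; ties are broken
#'   toward smaller termination time, then smaller mutation load.
#' @return a list: `p`, `kaIn`, `b`, `improvement`, `tEnd`, `i`, `j`.
#' @export
setMethod("findOptimum", "SweepResult", function(object, ...) {
  ok <- object@improvement > 0
  if (!any(ok)) stop("no surviving parameter cell")
  best <- max(object@improvement)
  cand <- which(object@improvement == best, arr.ind = TRUE)
  if (nrow(cand) > 1) {
    te <- object@tEnd[cand]
    cand <- cand[order(te, object@pGrid[cand[, 1]]), , drop = FALSE]
  }
  i <- cand[1, 1]; j <- cand[1, 2]
  list(p = object@pGrid[i], kaIn = object@kaGrid[j], b = object@b,
       improvement = best, tEnd = object@tEnd[i, j], i = i, j = j)
})

#' Affinity-improvement enhancement from inter-GC migration
#'
#' Ratio of the pooled-spleen optimum (fast-migration limit, `N0 = 1e5`,
#' 14-day-window termination) to the isolated-GC optimum (`N0 = 3000`,
#' recovery-based termination), each maximized over its own
#' (mutation load, initial binding) grid.
#'
#' @param spectrum a [MutationSpectrum-class].
#' @param b selection strength.
#' @param pGrid,kaGrid sweep axes shared by both arms.
#' @param pooledN0,isolatedN0 arm population sizes.
#' @param pooledMode,isolatedMode arm termination conventions.
#' @param ... passed to [sweepGrid()].
#' @return a list: `ratio`, `pooled` and `isolated` optimum records.
#' @export
migrationComparison <- function(spectrum = defaultSpectrum(), b = 0.7,
                                pGrid = defaultPGrid(), kaGrid = defaultKaGrid(),
                                pooledN0 = 1e5, isolatedN0 = 3000,
                                pooledMode = "A", isolatedMode = "B", ...) {
  pooled <- findOptimum(sweepGrid(pGrid, kaGrid, b = b, N0 = pooledN0,
                                  mode = pooledMode, spectrum = spectrum, ...))
  isolated <- findOptimum(sweepGrid(pGrid, kaGrid, b = b, N0 = isolatedN0,
                                    mode = isolatedMode, spectrum = spectrum, ...))
  list(ratio = pooled$improvement / isolated$improvement,
       pooled = pooled, isolated = isolated)
}

#' Write a sweep result as long-format TSV
#'
#' Columns: p, ka_in_ratio, b, improvement, survival, status, t_end_days.
#'
#' @param result a [SweepResult-class].
#' @param path output file.
#' @param header optional provenance lines (without the `#`).
#' @return `path`, invisibly.
#' @export
writeSweep <- function(result, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines("p\tka_in_ratio\tb\timprovement\tsurvival\tstatus\tt_end_days", con)
  for (i in seq_along(result@pGrid)) for (j in seq_along(result@kaGrid)) {
    writeLines(sprintf("%.4g\t%.6g\t%.4g\t%.8g\t%.4g\t%s\t%.6g",
                       result@pGrid[i], result@kaGrid[j], result@b,
                       result@improvement[i, j], result@survival[i, j],
                       result@status[i, j], result@tEnd[i, j]), con)
  }
  invisible(path)
}

#' @describeIn SweepResult-class compact display
#' @param object a `SweepResult` object
#' @export
setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult (mode %s, b = %.3g): %d x %d grid\n",
              object@mode, object@b, length(object@pGrid), length(object@kaGrid)))
  opt <- tryCatch(findOptimum(object), error = function(e) NULL)
  if (is.null(opt)) {
    cat("  all cells extinct\n")
  } else {
    cat(sprintf("  optimum: %.4g-fold at p = %.2g, Ka_in/Ka* = %.3g, t_end = %.3g days\n",
                opt$improvement, opt$p, opt$kaIn, opt$tEnd))
  }
  cat(sprintf("  %d/%d cells extinct\n", sum(object@status == "extinct"),
              length(object@status)))
})
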