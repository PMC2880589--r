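#' @include AllClasses.R AllGenerics.R params.R spectrum.R simulate.R
NULL

## run fn with a private RNG stream; global .Random.seed is untouched
.withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Simulate one stochastic realization of the branching process
#'
#' Tau-leaping realization of the linear birth-death-mutation process whose
#' mean is the cutoff-free deterministic model: per bin and step, division
#' events (one cell replaced by two daughters) are Poisson with rate
#' `r*N*dt`; lethal-mutation deaths with rate `mLethal*N*dt`; apoptosis with
#' rate `d(X)*N*dt` where `d(X) = max(0, b*(X - X*) + (r - mLethal))`; and
#' affinity-affecting mutations with rate `mAff*N*dt`, each moving one cell
#' by an offset drawn from the spectrum (silent mutations have no effect and
#' are not simulated explicitly). The net per-capita mean growth at offset X
#' is exactly `growthRate(X)`, keeping the stochastic and deterministic
#' modules mutually consistent.
#'
#' @param params a [ModelParams-class].
#' @param spectrum a [MutationSpectrum-class].
#' @param seed integer seed; required, every run must be reproducible.
#' @param grid affinity grid (default [gcGrid()]).
#' @param dt leap step (days). The default 0.005 keeps the per-step
#'   linearization bias of the leap well below sampling noise.
#' @param tMax horizon (days); defaults to `params@tMax`.
#' @param recordEvery record the total every this many steps.
#' @param detectRecovery stop (outcome `survived`) once the population has
#'   re-established itself after the bottleneck; set `FALSE` to integrate to
#'   `tMax` regardless, e.g. when validating replicate means against the
#'   mean-field trajectory, where stopping at a threshold would censor the
#'   sample.
#' @param recoveryFactor survival requires `N >= recoveryFactor * N0`.
#'   Unlike the deterministic integrator, a stochastic run starting at `N0`
#'   re-crosses `N0` in its first steps by Poisson fluctuation alone even
#'   when it is doomed, so bare re-crossing is not evidence of having passed
#'   the bottleneck; demanding a multiple of `N0` (default 3) is, because a
#'   subcritical population cannot sustain growth against its drift while a
#'   genuinely recovered one (net growth of order 1/day) reaches it within
#'   a day.
#' @return a [StochasticRun-class]; outcome is `survived` when the
#'   population re-establishes itself (reaches `recoveryFactor * N0`) after
#'   the bottleneck, `extinct` when it reaches zero, else `timed_out`.
#' @export
simulateRealization <- function(params, spectrum = defaultSpectrum(params@kT),
                                seed, grid = gcGrid(params), dt = 0.005,
                                tMax = params@tMax, recordEvery = 10L,
                                detectRecovery = TRUE, recoveryFactor = 3) {
  if (missing(seed) || is.null(seed)) stop("explicit integer 'seed' is required")
  if (params@N0 != round(params@N0) || params@N0 < 1)
    stop("stochastic runs require an integer N0 >= 1")
  rates <- deriveRates(params)
  .withSeed(seed, function() {
    nb <- length(grid)
    N <- numeric(nb)
    N[which.min(abs(grid - params@XStarOffsetIn))] <- params@N0
    d <- pmax(0, params@b * grid + (params@r - rates@mLethal))
    shifts <- as.integer(round(spectrum@offsets / params@h))
    w <- spectrum@weights
    nstep <- ceiling(tMax / dt)
    tRec <- numeric(floor(nstep / recordEvery) + 2L)
    nRec <- numeric(length(tRec))
    nRec[1] <- sum(N); iRec <- 1L
    bdepth <- sum(N); btime <- 0
    outcome <- "timed_out"; t <- 0
    for (s in seq_len(nstep)) {
      occ <- which(N > 0)
      if (!length(occ)) { outcome <- "extinct"; break }
      n <- N[occ]
      births <- stats::rpois(length(occ), params@r * n * dt)
      lethal <- stats::rpois(length(occ), rates@mLethal * n * dt)
      apop <- stats::rpois(length(occ), d[occ] * n * dt)
      nmut <- stats::rpois(length(occ), rates@mAff * n * dt)
      rem <- lethal + apop + nmut
      over <- rem > n
      if (any(over)) {
        ## cannot remove more cells than the bin holds; thin the event lists
        f <- n[over] / rem[over]
        lethal[over] <- floor(lethal[over] * f)
        apop[over] <- floor(apop[over] * f)
        nmut[over] <- pmin(nmut[over], n[over] - lethal[over] - apop[over])
      }
      N[occ] <- N[occ] + births - lethal - apop - nmut
      mv <- which(nmut > 0)
      for (i in mv) {
        dest <- occ[i] + sample(shifts, nmut[i], replace = TRUE, prob = w)
        dest <- dest[dest >= 1L & dest <= nb] # off-grid mutants are lost
        if (length(dest)) {
          tb <- tabulate(dest, nbins = nb)
          N <- N + tb
        }
      }
      t <- s * dt
      nt <- sum(N)
      if (s %% recordEvery == 0L) {
        iRec <- iRec + 1L
        tRec[iRec] <- t; nRec[iRec] <- nt
      }
      if (nt == 0) { outcome <- "extinct"; break }
      if (nt < bdepth) { bdepth <- nt; btime <- t }
      if (detectRecovery && nt >= recoveryFactor * params@N0 && t > btime) {
        outcome <- "survived"; break
      }
    }
    if (iRec == 0L || tRec[iRec] < t) {
      iRec <- iRec + 1L
      tRec[iRec] <- t; nRec[iRec] <- sum(N)
    }
    new("StochasticRun",
      seed = as.integer(seed), time = tRec[seq_len(iRec)],
      Ntot = nRec[seq_len(iRec)], outcome = outcome, tEnd = t,
      finalCounts = N, grid = grid)
  })
}

#' Estimate the bottleneck-survival probability
#'
#' Fraction of stochastic realizations that re-establish themselves (reach
#' `recoveryFactor * N0`) after passing the bottleneck, with a Wilson score
#' interval.
#' Per-replicate seeds are derived deterministically from `baseSeed`
#' (counter-based), so maps built from many calls are reproducible.
#'
#' @param params a [ModelParams-class].
#' @param spectrum a [MutationSpectrum-class].
#' @param replicates number of realizations (>= 10).
#' @param baseSeed integer seed for replicate 1; replicate i uses
#'   `baseSeed + i - 1`.
#' @param ... passed to [simulateRealization()].
#' @return a list: `probability`, `se` (binomial), `lower`/`upper` (95%
#'   Wilson), `replicates`, `outcomes` (table).
#' @export
survivalProbability <- function(params, spectrum = defaultSpectrum(params@kT),
                                replicates = 100L, baseSeed, ...) {
  if (replicates < 10) stop("at least 10 replicates required")
  if (missing(baseSeed)) stop("explicit 'baseSeed' is required")
  outcomes <- vapply(seq_len(replicates), function(i) {
    simulateRealization(params, spectrum, seed = baseSeed + i - 1L, ...)@outcome
  }, character(1))
  k <- sum(outcomes == "survived")
  n <- replicates
  phat <- k / n
  z <- stats::qnorm(0.975)
  den <- 1 + z^2 / n
  ctr <- (phat + z^2 / (2 * n)) / den
  hw <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
  list(probability = phat,
       se = sqrt(phat * (1 - phat) / n),
       lower = max(0, ctr - hw), upper = min(1, ctr + hw),
       replicates = n, outcomes = table(factor(outcomes,
         levels = c("survived", "extinct", "timed_out"))))
}

#' @describeIn StochasticRun-class compact display
#' @param object a `StochasticRun` object
#' @export
setMethod("show", "StochasticRun", function(object) {
  cat(sprintf("StochasticRun (seed %d): %s at t = %.3g days, final N = %d\n",
              object@seed, object@outcome, object@tEnd,
              as.integer(sum(object@finalCounts))))
})
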