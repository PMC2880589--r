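#' @include AllClasses.R AllGenerics.R params.R spectrum.R
NULL

#' Default affinity grid
#'
#' Bin centers spanning `[lo, hi]` kcal/mol around the neutral affinity at
#' spacing `params@h`. The default range covers the >1000-fold improvements
#' reachable from weak initial binding plus the deleterious tail.
#'
#' @param params a [ModelParams-class].
#' @param lo,hi grid bounds (offsets from neutral, kcal/mol). The high
#'   (deleterious) bound extends well past the initial bin so that
#'   multi-step deleterious mutants decay on the grid instead of being
#'   dropped at the edge.
#' @return numeric vector of bin centers.
#' @export
gcGrid <- function(params, lo = -6, hi = 7) {
  seq(lo, hi, by = params@h)
}

#' Construct a population state
#'
#' @param grid bin centers (offsets from neutral, kcal/mol).
#' @param counts cell counts per bin.
#' @param time current time (days).
#' @return a [PopulationState-class].
#' @export
populationState <- function(grid, counts, time = 0) {
  new("PopulationState", grid = grid, counts = counts, time = time,
      edgeLoss = c(0, 0))
}

## k-fold convolution kernels of the spectrum on the bin lattice.
## Returns a list of length KMax; element k holds integer bin shifts and the
## corresponding probabilities of a net displacement after k mutations.
.spectrumKernels <- function(spectrum, h, KMax) {
  shifts <- round(spectrum@offsets / h)
  if (any(abs(shifts * h - spectrum@offsets) > 1e-8))
    stop("spectrum offsets are not commensurate with the grid spacing")
  shifts <- as.integer(shifts)
  kern <- vector("list", KMax)
  agg <- function(s, w) {
    v <- tapply(w, s, sum)
    list(shift = as.integer(names(v)), w = as.numeric(v))
  }
  kern[[1]] <- agg(shifts, spectrum@weights)
  if (KMax >= 2) for (k in 2:KMax) {
    prev <- kern[[k - 1]]
    kern[[k]] <- agg(as.vector(outer(prev$shift, shifts, `+`)),
                     as.vector(outer(prev$w, spectrum@weights)))
  }
  kern
}

## Precomputed single-step operator on raw count vectors.
## The mutation operator uses Poisson step probabilities q_k = P(k mutations
## in dt) for k = 1..KMax and a staying factor 1 - sum(q_k), so it conserves
## cells exactly (up to the k > KMax tail folded into the staying factor)
## when growth and lethality are switched off.
.makeStepper <- function(params, rates, spectrum, grid, dt,
                         KMax = 3L, cutoff = TRUE, subunityDecay = FALSE) {
  nb <- length(grid)
  gfac <- exp(growthRate(grid, params, rates) * dt)
  kern <- .spectrumKernels(spectrum, params@h, KMax)
  lam <- rates@mAff * dt
  qk <- stats::dpois(seq_len(KMax), lam)
  stay <- 1 - sum(qk)
  decayfac <- pmin(gfac, 1) # for the subunityDecay variant: decay only
  function(counts, edgeLoss) {
    if (any(is.na(counts))) stop("NaN in population state")
    el <- if (cutoff) counts >= 1 else counts > 0
    if (!any(el)) return(list(counts = counts, edgeLoss = edgeLoss, active = FALSE))
    grown <- counts * gfac
    new <- counts
    new[el] <- grown[el] * stay
    if (cutoff && subunityDecay) {
      sub <- !el & counts > 0
      new[sub] <- counts[sub] * decayfac[sub]
    }
    src <- which(el)
    if (lam > 0) for (k in seq_along(kern)) {
      amt <- grown[src] * qk[k]
      ks <- kern[[k]]$shift
      kw <- kern[[k]]$w
      for (j in seq_along(ks)) {
        dest <- src + ks[j]
        ok <- dest >= 1L & dest <= nb
        if (any(ok)) {
          d <- dest[ok]
          new[d] <- new[d] + amt[ok] * kw[j]
        }
        if (!all(ok)) {
          lost <- sum(amt[!ok] * kw[j])
          if (ks[j] < 0) edgeLoss[1] <- edgeLoss[1] + lost
          else edgeLoss[2] <- edgeLoss[2] + lost
        }
      }
    }
    list(counts = new, edgeLoss = edgeLoss, active = TRUE)
  }
}

#' Advance a population state by one time step
#'
#' One step of the finite-population deterministic scheme: bins holding at
#' least one cell ("eligible") are multiplied by `exp(B(X) dt)` and emit
#' mutants into destination bins with Poisson step probabilities for
#' k = 1..`KMax` mutations per step (spectrum convolved k times); bins below
#' one cell are frozen -- no growth, no decay, no emission -- and only
#' accumulate influx until they reach one cell. Mass mutated beyond the grid
#' edges accumulates in the state's edge-loss counters. The mutation
#' operator conserves cells exactly when growth and lethality are off.
#'
#' @param state a [PopulationState-class].
#' @param params a [ModelParams-class].
#' @param spectrum a [MutationSpectrum-class].
#' @param dt time step (days); default `0.01/(b*h)`.
#' @param KMax maximum mutations per step (default 3; at the default step
#'   the probability of more is below 1e-10).
#' @param cutoff apply the one-cell rule; `FALSE` recovers the
#'   infinite-population (mean-field) scheme.
#' @param subunityDecay alternative sub-unity rule for sensitivity checks:
#'   frozen bins still decay (never grow) at their bin rate.
#' @return the advanced [PopulationState-class].
#' @export
stepPopulation <- function(state, params, spectrum = defaultSpectrum(params@kT),
                           dt = 0.01 / (params@b * params@h), KMax = 3L,
                           cutoff = TRUE, subunityDecay = FALSE) {
  if (dt <= 0) stop("dt must be > 0")
  rates <- deriveRates(params)
  stepper <- .makeStepper(params, rates, spectrum, state@grid, dt,
                          KMax = KMax, cutoff = cutoff,
                          subunityDecay = subunityDecay)
  out <- stepper(state@counts, state@edgeLoss)
  new("PopulationState", grid = state@grid, counts = out$counts,
      time = state@time + dt, edgeLoss = out$edgeLoss)
}

#' Simulate a germinal-center trajectory
#'
#' Integrates the finite-population scheme from a delta initial condition
#' (`N0` cells in the bin containing the germline offset `XStarOffsetIn`)
#' and records total population, total affinity
#' `A(t) = sum(N * Ka/Ka*)`, and the strong-affinity fraction
#' `F(t)` (mass at offsets <= 0) every step.
#'
#' Termination:
#' \describe{
#'   \item{`fixed_window_14d`}{stop at the first recovery to `N >= N0` after
#'     the bottleneck, or at `window` = 14 days, whichever comes first.}
#'   \item{`recovery_unbounded`}{stop at recovery, however long it takes,
#'     guarded by `params@tMax` (status `timed_out` if hit).}
#'   \item{`horizon_only`}{integrate to `params@tMax` regardless.}
#' }
#' A state in which every bin holds less than one cell cannot evolve further
#' under the cutoff and is classified `extinct`. Recovery requires
#' `t > bottleneckTime`, so a run starting at `N0` does not instantly
#' "recover".
#'
#' @param params a [ModelParams-class].
#' @param spectrum a [MutationSpectrum-class].
#' @param termination termination mode (see Details).
#' @param grid affinity grid; default [gcGrid()].
#' @param dtFactor time step in units of `1/(b*h)` (default 0.01).
#' @param KMax,cutoff,subunityDecay passed to the stepper, see
#'   [stepPopulation()].
#' @param window fixed observation window for `fixed_window_14d` (days).
#' @return a [Trajectory-class].
#' @examples
#' tr <- simulateGC(modelParams(N0 = 1e5), termination = "fixed_window_14d")
#' tr
#' improvement(tr)
#' @export
simulateGC <- function(params, spectrum = defaultSpectrum(params@kT),
                       termination = c("fixed_window_14d", "recovery_unbounded",
                                       "horizon_only"),
                       grid = gcGrid(params), dtFactor = 0.01, KMax = 3L,
                       cutoff = TRUE, subunityDecay = FALSE, window = 14) {
  termination <- match.arg(termination)
  rates <- deriveRates(params)
  dt <- dtFactor / (params@b * params@h)
  Xin <- params@XStarOffsetIn
  if (Xin < min(grid) - params@h / 2 || Xin > max(grid) + params@h / 2)
    stop(sprintf("initial offset %.3g kcal/mol lies outside the grid [%g, %g]",
                 Xin, min(grid), max(grid)))
  counts <- numeric(length(grid))
  counts[which.min(abs(grid - Xin))] <- params@N0
  Ka <- exp(-grid / params@kT)
  strong <- grid <= 0
  stepper <- .makeStepper(params, rates, spectrum, grid, dt,
                          KMax = KMax, cutoff = cutoff,
                          subunityDecay = subunityDecay)
  tLimit <- if (termination == "fixed_window_14d") min(window, params@tMax)
            else params@tMax
  nstep <- ceiling(tLimit / dt)
  time <- numeric(nstep + 1); Ntot <- numeric(nstep + 1)
  A <- numeric(nstep + 1); Fr <- numeric(nstep + 1)
  Ntot[1] <- sum(counts); A[1] <- sum(counts * Ka)
  Fr[1] <- sum(counts[strong]) / Ntot[1]
  edgeLoss <- c(0, 0)
  bdepth <- Ntot[1]; btime <- 0
  status <- "timed_out"; last <- 1L; t <- 0
  for (s in seq_len(nstep)) {
    out <- stepper(counts, edgeLoss)
    if (!out$active) { status <- "extinct"; break }
    counts <- out$counts; edgeLoss <- out$edgeLoss
    t <- s * dt
    nt <- sum(counts)
    last <- s + 1L
    time[last] <- t; Ntot[last] <- nt
    A[last] <- sum(counts * Ka)
    Fr[last] <- if (nt > 0) sum(counts[strong]) / nt else 0
    if (nt < bdepth) { bdepth <- nt; btime <- t }
    if (termination != "horizon_only" && nt >= params@N0 && t > btime) {
      status <- "recovered"; break
    }
  }
  keep <- seq_len(last)
  new("Trajectory",
    time = time[keep], Ntot = Ntot[keep], A = A[keep], F = Fr[keep],
    status = status, tEnd = time[last],
    bottleneckTime = btime, bottleneckDepth = bdepth,
    A0 = A[1], N0 = params@N0, edgeLoss = edgeLoss,
    finalState = new("PopulationState", grid = grid, counts = counts,
                     time = time[last], edgeLoss = edgeLoss))
}

#' @describeIn improvement fold-improvement `A(tEnd)/A(0)` of a simulated
#'   trajectory; an extinct run reports 0 by convention.
#' @export
setMethod("improvement", "Trajectory", function(object, ...) {
  if (object@status == "extinct") return(0)
  object@A[length(object@A)] / object@A0
})

#' Write a trajectory as TSV
#'
#' Columns `t_days`, `N_tot`, `A_over_A0`, `F`; provenance lines are
#' `#`-prefixed.
#'
#' @param traj a [Trajectory-class].
#' @param path output file.
#' @param header optional provenance lines (without the `#`).
#' @param every keep every `every`-th sample to limit file size.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path, header = character(), every = 1L) {
  idx <- unique(c(seq(1, length(traj@time), by = every), length(traj@time)))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(sprintf("# status: %s  t_end: %.6g  bottleneck: t=%.6g depth=%.6g",
                     traj@status, traj@tEnd, traj@bottleneckTime,
                     traj@bottleneckDepth), con)
  writeLines("t_days\tN_tot\tA_over_A0\tF", con)
  writeLines(sprintf("%.6g\t%.8g\t%.8g\t%.8g", traj@time[idx], traj@Ntot[idx],
                     traj@A[idx] / traj@A0, traj@F[idx]), con)
  invisible(path)
}

#' @describeIn Trajectory-class compact display
#' @param object a `Trajectory` object
#' @export
setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %s at t = %.3g days (%d samples)\n",
              object@status, object@tEnd, length(object@time)))
  cat(sprintf("  N0 = %.4g, bottleneck %.4g cells at t = %.3g days\n",
              object@N0, object@bottleneckDepth, object@bottleneckTime))
  cat(sprintf("  A improvement = %.4g-fold, terminal F = %.3g\n",
              improvement(object), object@F[length(object@F)]))
})

#' @describeIn PopulationState-class compact display
#' @param object a `PopulationState` object
#' @export
setMethod("show", "PopulationState", function(object) {
  nt <- sum(object@counts)
  occ <- which(object@counts >= 1)
  cat(sprintf("PopulationState at t = %.3g days: %.4g cells in %d bins >= 1 cell\n",
              object@time, nt, length(occ)))
  if (length(occ))
    cat(sprintf("  occupied offsets: [%.3g, %.3g] kcal/mol\n",
                object@grid[min(occ)], object@grid[max(occ)]))
  if (sum(object@edgeLoss) > 0)
    cat(sprintf("  edge loss: %.3g (low) / %.3g (high)\n",
                object@edgeLoss[1], object@edgeLoss[2]))
})
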