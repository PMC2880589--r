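#' @include AllClasses.R
NULL

#' Construct model parameters
#'
#' User-facing constructor for [ModelParams-class]. B cells divide
#' `divisionsPerDay` times a day, giving the exponential birth rate
#' `r = divisionsPerDay * log(2)` (about 2.8/day at 4 divisions/day) unless
#' `r` is supplied explicitly. A fraction `pMutatedDaughter` of daughter
#' cells carry at least one mutation; mutations are silent, lethal or
#' affinity-affecting with fractions `fSilent`, `fLethal`, `fAffinity`
#' (defaults 0.5/0.3/0.2). Selection enters through a death rate linear in
#' the binding free energy with slope `b`, saturating to zero death at
#' strong binding.
#'
#' `kT = 0.59` kcal/mol converts free-energy offsets to association-constant
#' ratios: one bin of width 0.5 kcal/mol corresponds to a 2.3-fold change in
#' Ka, and 1 kcal/mol to a Ka ratio of 0.18.
#'
#' @param b selection strength (1/day per kcal/mol).
#' @param pMutatedDaughter fraction of mutated daughter cells, in [0, 1).
#' @param XStarOffsetIn germline binding offset from neutral (kcal/mol);
#'   positive = weaker than neutral. `+1` corresponds to Ka_in/Ka* = 0.18.
#' @param N0 initial B-cell count: `1e5` for the pooled-spleen
#'   (fast-migration) limit, `3000` for an isolated germinal center.
#' @param divisionsPerDay divisions per day (default 4).
#' @param kT thermal energy (kcal/mol).
#' @param h affinity bin width (kcal/mol).
#' @param fSilent,fLethal,fAffinity mutation-class fractions (sum to 1).
#' @param tMax hard simulation horizon (days).
#' @param r per-capita birth rate (1/day); derived from `divisionsPerDay`
#'   when missing.
#' @return a validated [ModelParams-class] object.
#' @examples
#' p <- modelParams(b = 0.7, pMutatedDaughter = 0.5)
#' deriveRates(p)
#' @export
modelParams <- function(b = 0.7, pMutatedDaughter = 0.5, XStarOffsetIn = 1.0,
                        N0 = 1e5, divisionsPerDay = 4L, kT = 0.59, h = 0.5,
                        fSilent = 0.5, fLethal = 0.3, fAffinity = 0.2,
                        tMax = 100, r = divisionsPerDay * log(2)) {
  new("ModelParams",
    r = as.numeric(r), divisionsPerDay = as.integer(divisionsPerDay),
    kT = kT, b = b, h = h, pMutatedDaughter = pMutatedDaughter,
    fSilent = fSilent, fLethal = fLethal, fAffinity = fAffinity,
    XStarOffsetIn = XStarOffsetIn, N0 = N0, tMax = tMax)
}

#' Derive mutation rates and model scales from parameters
#'
#' The number of mutations per daughter cell per division is Poisson with
#' mean `mu = -log(1 - p)`, so that the fraction of mutated daughters is
#' `p = 1 - exp(-mu)`. The total mutation rate is
#' `mTotal = divisionsPerDay * mu` (2.77/day, printed 2.8/day, at p = 0.5
#' with 4 divisions/day), split into lethal and affinity-affecting rates by
#' the class fractions; `mAff = 0.55`/day/gene at the defaults. Also derived:
#' the saturation offset `D = (r - mLethal)/b` below which the death rate is
#' zero, and the recycling-round time scale `tau = 1/(b*kT)`.
#'
#' @param params a [ModelParams-class] object.
#' @return a [DerivedRates-class] object.
#' @export
deriveRates <- function(params) {
  stopifnot(is(params, "ModelParams"))
  p <- params@pMutatedDaughter
  if (p >= 1) stop("degenerate mutation load: pMutatedDaughter = 1 (mu diverges)")
  mu <- -log1p(-p)
  mTotal <- params@divisionsPerDay * mu
  new("DerivedRates",
    mu = mu,
    mTotal = mTotal,
    mLethal = params@fLethal * mTotal,
    mAff = params@fAffinity * mTotal,
    D = (params@r - params@fLethal * mTotal) / params@b,
    tau = 1 / (params@b * params@kT))
}

#' Association-constant ratio for a free-energy offset
#'
#' Free energies add while affinities multiply:
#' `kaRatio(deltaX) = exp(-deltaX / kT)`. Measured relative to the neutral
#' level, `kaRatio(X - X*) = Ka/Ka*`.
#'
#' @param deltaX binding free-energy difference (kcal/mol); vectorized.
#' @param kT thermal energy (kcal/mol).
#' @return dimensionless Ka ratio(s).
#' @examples
#' kaRatio(1.0)   # ~0.18: 1 kcal/mol weaker binding
#' kaRatio(-0.5)  # ~2.3-fold stronger, one bin width
#' @export
kaRatio <- function(deltaX, kT = 0.59) {
  stopifnot(kT > 0)
  exp(-deltaX / kT)
}

#' Net per-capita growth rate as a function of affinity
#'
#' The exponential growth rate of the subpopulation at binding offset
#' `XOffset = X - X*`:
#' \deqn{B(X) = \min(-b (X - X^*),\; r - m_{lethal})}
#' Linear in the offset (selection-dominated) down to the saturation point
#' `-D = -(r - mLethal)/b`, where the Langmuir survival probability
#' saturates at 1 and growth is capped at the net replicative rate.
#' `B(X*) = 0` defines the neutral affinity.
#'
#' @param XOffset affinity offset(s) from neutral (kcal/mol); vectorized.
#' @param params a [ModelParams-class].
#' @param rates the matching [DerivedRates-class]; derived when missing.
#' @return growth rate(s), 1/day.
#' @export
growthRate <- function(XOffset, params, rates = deriveRates(params)) {
  pmin(-params@b * XOffset, params@r - rates@mLethal)
}

#' @describeIn ModelParams-class compact display
#' @param object a `ModelParams` object
#' @export
setMethod("show", "ModelParams", function(object) {
  rt <- deriveRates(object)
  cat("ModelParams\n")
  cat(sprintf("  r        = %.4g/day (%d divisions/day)\n", object@r, object@divisionsPerDay))
  cat(sprintf("  b        = %.3g/day/(kcal/mol)   kT = %.3g kcal/mol   h = %.3g kcal/mol\n",
              object@b, object@kT, object@h))
  cat(sprintf("  p        = %.3g mutated daughters (mTotal = %.3g/day, mAff = %.3g/day)\n",
              object@pMutatedDaughter, rt@mTotal, rt@mAff))
  cat(sprintf("  X_in-X*  = %+.3g kcal/mol (Ka_in/Ka* = %.3g)\n",
              object@XStarOffsetIn, kaRatio(object@XStarOffsetIn, object@kT)))
  cat(sprintf("  N0       = %.4g cells   tMax = %.4g days\n", object@N0, object@tMax))
})

#' @describeIn DerivedRates-class compact display
#' @param object a `DerivedRates` object
#' @export
setMethod("show", "DerivedRates", function(object) {
  cat("DerivedRates\n")
  cat(sprintf("  mu = %.4g /daughter/division   mTotal = %.4g/day\n", object@mu, object@mTotal))
  cat(sprintf("  mLethal = %.4g/day   mAff = %.4g/day\n", object@mLethal, object@mAff))
  cat(sprintf("  D = %.4g kcal/mol   tau = %.4g days\n", object@D, object@tau))
})
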