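#' @include AllClasses.R AllGenerics.R params.R spectrum.R
NULL

## (e^{g t} - 1)/g with the g -> 0 limit taken by series expansion
.expm1_over_g <- function(g, t) {
  ifelse(abs(g * t) < 1e-6, t + g * t^2 / 2, expm1(g * t) / g)
}

#' Construct an analytic solution of the mean-field model
#'
#' Bundles parameters, spectrum and initial condition for closed-form
#' evaluation in the linear-growth regime. Each mutation class i (offset
#' `delta_i`, weight `w_i`) carries an individual rate `m_i = mAff * w_i`
#' and a growth-rate increment `g_i = -b * delta_i`; the total population is
#' a product of per-class Poisson factors over the mutation-free growth.
#'
#' @param params a [ModelParams-class].
#' @param spectrum a [MutationSpectrum-class].
#' @param Xin initial affinity offset from neutral (kcal/mol); defaults to
#'   `params@XStarOffsetIn`.
#' @param N0 initial mass; defaults to `params@N0`.
#' @param sigma Gaussian initial-condition width; `NA` for a delta initial
#'   condition.
#' @return an [AnalyticSolution-class].
#' @examples
#' sol <- analyticSolution(modelParams(), defaultSpectrum())
#' totalPopulation(sol, c(0, 1, 3))
#' @export
analyticSolution <- function(params, spectrum = defaultSpectrum(params@kT),
                             Xin = params@XStarOffsetIn, N0 = params@N0,
                             sigma = NA_real_) {
  new("AnalyticSolution",
    params = params, rates = deriveRates(params), spectrum = spectrum,
    icType = if (is.na(sigma)) "delta" else "gaussian",
    Xin = Xin, sigma = sigma, N0 = N0)
}

## per-class intensity lambda_i(t) = m_i (e^{g_i t} - 1)/g_i (time-integrated
## mutation rate weighted by the relative growth of the mutant lineage)
.classLambda <- function(sol, t, classIndex) {
  d <- sol@spectrum@offsets[classIndex]
  g <- -sol@params@b * d
  m <- sol@rates@mAff * sol@spectrum@weights[classIndex]
  list(g = g, m = m, lambda = m * .expm1_over_g(g, t), delta = d)
}

#' @describeIn totalPopulation closed-form total population. For a delta
#'   initial condition at offset `Xin`,
#'   \deqn{N(t) = N_0 e^{B(X_{in}) t} \prod_i
#'     \exp\{m_i [(e^{g_i t} - 1)/g_i - t]\}}
#'   with `g_i = -b delta_i` and `m_i = mAff w_i`; beneficial classes
#'   (`g_i > 0`) contribute super-exponential growth, deleterious classes an
#'   `exp(-m_i t)`-type reduction. A Gaussian initial condition multiplies in
#'   `exp(b^2 sigma^2 t^2 / 2)`. Linear growth (no saturation cap) is
#'   assumed; a warning is issued when the mean displacement crosses the cap
#'   point `-D`.
#' @export
setMethod("totalPopulation", "AnalyticSolution", function(object, t, ...) {
  if (any(t < 0)) stop("t must be >= 0")
  g <- -object@params@b * object@spectrum@offsets
  m <- object@rates@mAff * object@spectrum@weights
  vapply(t, function(tt) {
    lam <- m * .expm1_over_g(g, tt)
    meanShift <- sum(lam * object@spectrum@offsets)
    if (object@Xin + meanShift < -object@rates@D)
      warning("dominant subpopulation crossed the saturation point -D; ",
              "the linear-growth assumption no longer holds", call. = FALSE)
    expo <- -object@params@b * object@Xin * tt + sum(lam - m * tt)
    if (object@icType == "gaussian")
      expo <- expo + (object@params@b * object@sigma)^2 * tt^2 / 2
    object@N0 * exp(expo)
  }, numeric(1))
})

#' Expected size of the j-mutation subpopulation for one mutation class
#'
#' Single-class Poisson bookkeeping: the subpopulation having undergone
#' exactly `j` mutations of class `i` is
#' \deqn{N_j(t) = N_0 e^{B(X_{in}) t} e^{-m_i t} \lambda_i(t)^j / j!}
#' with \eqn{\lambda_i(t) = m_i (e^{g_i t} - 1)/g_i}, sitting at affinity
#' `Xin + j * delta_i`. In the `b -> 0` limit this collapses to
#' `N0 e^{Bt} Poisson(m_i t)(j)`. For a single-class spectrum the sum over
#' j equals [totalPopulation()].
#'
#' @param sol an [AnalyticSolution-class] with a delta initial condition.
#' @param t time (days).
#' @param classIndex index into the spectrum's bins.
#' @param j mutation count(s), non-negative integer; vectorized.
#' @return expected cell count(s).
#' @export
subpopulationSize <- function(sol, t, classIndex = 1L, j = 0L) {
  if (any(j < 0) || any(j != round(j))) stop("j must be a non-negative integer")
  cl <- .classLambda(sol, t, classIndex)
  base <- -sol@params@b * sol@Xin * t - cl$m * t
  sol@N0 * exp(base + j * log(cl$lambda) - lgamma(j + 1))
}

#' Mutation count of the largest subpopulation
#'
#' For a beneficial class (`g_i > 0`) the largest j-mutation subpopulation
#' is the mode of the Poisson profile, `floor(lambda_i(t))`; at long times
#' `lambda_i` grows like `e^{g_i t}`, so the peak advances exponentially
#' fast.
#'
#' @inheritParams subpopulationSize
#' @return integer mutation count of the peak.
#' @export
peakMutationCount <- function(sol, t, classIndex = 1L) {
  cl <- .classLambda(sol, t, classIndex)
  if (cl$g <= 0) stop("peak defined for beneficial classes only")
  as.integer(floor(cl$lambda))
}

#' Mutation-free population profile for a Gaussian initial condition
#'
#' The exact mean-field profile when `mAff = 0`:
#' \deqn{N(X, t) = N_0\, G(X; X_{in}, \sigma)\, e^{-b X t}}
#' (offsets from neutral). Completing the square shows the profile stays
#' Gaussian with unchanged width and mean drifting as
#' `Xin - b sigma^2 t`; its integral equals [totalPopulation()] with
#' `mAff = 0`.
#'
#' @param sol an [AnalyticSolution-class] with `icType == "gaussian"`.
#' @param X affinity offset(s) from neutral (kcal/mol); vectorized.
#' @param t time (days).
#' @return density value(s) (cells per kcal/mol).
#' @export
gaussianProfile <- function(sol, X, t) {
  if (sol@icType != "gaussian") stop("gaussianProfile requires a Gaussian initial condition")
  if (is.na(sol@sigma) || sol@sigma <= 0) stop("sigma must be > 0")
  sol@N0 * stats::dnorm(X, mean = sol@Xin, sd = sol@sigma) *
    exp(-sol@params@b * X * t)
}

#' @describeIn AnalyticSolution-class compact display
#' @param object an `AnalyticSolution` object
#' @export
setMethod("show", "AnalyticSolution", function(object) {
  cat(sprintf("AnalyticSolution (%s initial condition)\n", object@icType))
  cat(sprintf("  Xin - X* = %+.3g kcal/mol, N0 = %.4g\n", object@Xin, object@N0))
  if (object@icType == "gaussian") cat(sprintf("  sigma = %.3g kcal/mol\n", object@sigma))
  cat(sprintf("  %d mutation classes, mAff = %.4g/day\n",
              length(object@spectrum@offsets), object@rates@mAff))
})
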