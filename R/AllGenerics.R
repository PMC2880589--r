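#' @include AllClasses.R
NULL

#' Fold-improvement of total affinity
#'
#' @param object a [Trajectory-class] (or other result carrying a total
#'   affinity series).
#' @param ... further arguments for methods.
#' @return `A(tEnd)/A(0)`; 0 for an extinct run by convention.
#' @export
setGeneric("improvement", function(object, ...) standardGeneric("improvement"))

#' Total expected population size
#'
#' @param object an [AnalyticSolution-class].
#' @param t time in days (vectorized, `t >= 0`).
#' @param ... further arguments for methods.
#' @export
setGeneric("totalPopulation", function(object, t, ...) standardGeneric("totalPopulation"))

#' Summary statistics of a mutation spectrum
#'
#' @param object a [MutationSpectrum-class].
#' @param ... further arguments for methods.
#' @export
setGeneric("spectrumSummary", function(object, ...) standardGeneric("spectrumSummary"))

#' Locate the optimum of a parameter sweep
#'
#' @param object a [SweepResult-class].
#' @param ... further arguments for methods.
#' @export
setGeneric("findOptimum", function(object, ...) standardGeneric("findOptimum"))

#' Strong-affinity fraction time series
#'
#' @param object a [Trajectory-class].
#' @param ... further arguments for methods.
#' @export
setGeneric("strongFraction", function(object, ...) standardGeneric("strongFraction"))

#' Distribution of the strong-affinity fraction over random observation times
#'
#' @param object a [Trajectory-class].
#' @param nBins number of F bins on [0, 1].
#' @param ... further arguments for methods.
#' @export
setGeneric("fractionDistribution", function(object, nBins = 20L, ...)
  standardGeneric("fractionDistribution"))
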