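#' @include AllClasses.R AllGenerics.R simulate.R
NULL

#' @describeIn strongFraction time series of the fraction of strong-affinity
#'   B cells, `F(t)` = (mass at offsets at or below the neutral affinity) /
#'   (total population), as recorded along a trajectory. Errors on extinct
#'   runs, where the terminal fraction is undefined.
#' @return a data.frame with columns `time` and `F`.
#' @export
setMethod("strongFraction", "Trajectory", function(object, ...) {
  if (object@status == "extinct")
    stop("strong-affinity fraction is undefined for an extinct trajectory")
  data.frame(time = object@time, F = object@F)
})

#' @describeIn fractionDistribution distribution P(F) of the strong-affinity
#'   fraction across an ensemble of identically parameterized germinal
#'   centers with random start times. Observing that ensemble at one moment
#'   is equivalent to observing a single trajectory at a uniformly random
#'   time, so P(F) ~ dt(F)/dF; the estimator used is the robust discrete
#'   equivalent: the fraction of total run time the trajectory spends with F
#'   in each bin. Bins F never visits get zero mass, and plateaus in F(t)
#'   (where dt/dF diverges) are handled naturally.
#' @export
setMethod("fractionDistribution", "Trajectory", function(object, nBins = 20L, ...) {
  if (nBins < 2) stop("nBins must be >= 2")
  if (object@status == "extinct")
    stop("fraction distribution is undefined for an extinct trajectory")
  breaks <- seq(0, 1, length.out = nBins + 1)
  dt <- diff(object@time)
  ## time spent in each F-bin: each inter-sample interval is attributed to
  ## the bin of its left endpoint
  f <- object@F[-length(object@F)]
  idx <- pmin(pmax(findInterval(f, breaks, rightmost.closed = TRUE), 1L), nBins)
  mass <- vapply(seq_len(nBins), function(k) sum(dt[idx == k]), numeric(1))
  mass <- mass / sum(mass)
  new("FractionDistribution", breaks = breaks, mass = mass, tEnd = object@tEnd)
})

#' Write a fraction distribution as TSV
#'
#' Columns `f_lo`, `f_hi`, `mass`.
#'
#' @param dist a [FractionDistribution-class].
#' @param path output file.
#' @param header optional provenance lines (without the `#`).
#' @return `path`, invisibly.
#' @export
writeFractionDistribution <- function(dist, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines("f_lo\tf_hi\tmass", con)
  n <- length(dist@mass)
  writeLines(sprintf("%.6g\t%.6g\t%.8g", dist@breaks[-(n + 1)],
                     dist@breaks[-1], dist@mass), con)
  invisible(path)
}

#' @describeIn FractionDistribution-class compact display
#' @param object a `FractionDistribution` object
#' @export
setMethod("show", "FractionDistribution", function(object) {
  n <- length(object@mass)
  cat(sprintf("FractionDistribution: %d bins over [0, 1], from a %.3g-day trajectory\n",
              n, object@tEnd))
  lo <- object@mass[1]; hi <- object@mass[n]
  cat(sprintf("  mass in first bin %.3g, last visited bin %.3g, max middle %.3g\n",
              lo, object@mass[max(which(object@mass > 0))],
              max(object@mass[-c(1, n)])))
})
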