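#' @include AllClasses.R AllGenerics.R
NULL

## Packaged synthetic spectrum. Beneficial side pinned to the published
## constraints (4.9% improving, 1.4% improving at least 5-fold, i.e. by at
## least kT*ln 5 = 0.95 kcal/mol); deleterious side is an exponential-decay
## shape with scale 1 kcal/mol renormalized to 0.951.
.DEFAULT_OFFSETS <- c(-1.0, -0.5, 0.5, 1.0, 1.5, 2.0, 2.5, 3.0)
.DEFAULT_WEIGHTS <- c(0.014, 0.035, 0.300, 0.240, 0.170, 0.120, 0.070, 0.051)

#' Construct a mutation spectrum from offsets and weights
#'
#' @param offsets bin centers (kcal/mol), integer multiples of `binWidth`.
#' @param weights probabilities; normalized if `normalize = TRUE`.
#' @param binWidth bin width `h` (kcal/mol).
#' @param normalize divide weights by their sum.
#' @return a [MutationSpectrum-class].
#' @export
mutationSpectrum <- function(offsets, weights, binWidth = 0.5, normalize = FALSE) {
  o <- order(offsets)
  w <- weights[o]
  if (normalize) w <- w / sum(w)
  new("MutationSpectrum", binWidth = binWidth, offsets = offsets[o], weights = w)
}

#' The packaged default mutation-effect spectrum
#'
#' A synthetic discretization of the distribution of binding free-energy
#' changes upon affinity-affecting point mutations, as estimated from
#' protein-interaction mutant data: 4.9% of affinity-affecting mutations
#' improve affinity, 1.4% improve it strongly (at least 5-fold, i.e. by at
#' least `kT*log(5)` = 0.95 kcal/mol). The deleterious side decays roughly
#' exponentially. All eight weights are packaged constants, so downstream
#' results are reproducible bit-for-bit.
#'
#' @param kT thermal energy (kcal/mol); recorded only to document the
#'   5-fold threshold, the packaged weights do not depend on it.
#' @return a [MutationSpectrum-class] on offsets
#'   (-1.0, -0.5, 0.5, 1.0, 1.5, 2.0, 2.5, 3.0) with bin width 0.5.
#' @examples
#' sp <- defaultSpectrum()
#' spectrumSummary(sp)
#' @export
defaultSpectrum <- function(kT = 0.59) {
  mutationSpectrum(.DEFAULT_OFFSETS, .DEFAULT_WEIGHTS, binWidth = 0.5)
}

#' Bin a table of per-mutation ddG values into a spectrum
#'
#' Each value is assigned to the bin whose center `i*h` is nearest; exact
#' ties (a value halfway between two centers) round half away from zero.
#' The sign convention follows the free-energy picture: negative ddG =
#' improved binding.
#'
#' @param values numeric vector of binding free-energy changes (kcal/mol).
#' @param h bin width (kcal/mol).
#' @return a [MutationSpectrum-class] with weights = counts/total.
#' @examples
#' spectrumFromDdg(c(-0.6, -0.4, 0.2, 0.3, 0.7, 1.3), h = 0.5)
#' @export
spectrumFromDdg <- function(values, h = 0.5) {
  if (length(values) < 1) stop("ddG input is empty: at least one value required")
  bad <- which(!is.finite(values))
  if (length(bad))
    stop(sprintf("non-finite ddG value at row %s", paste(bad, collapse = ", ")))
  stopifnot(h > 0)
  ## round half away from zero, so +/-0.25 at h = 0.5 goes to +/-0.5
  idx <- sign(values) * floor(abs(values) / h + 0.5)
  tab <- table(idx)
  centers <- as.numeric(names(tab)) * h
  mutationSpectrum(centers, as.numeric(tab), binWidth = h, normalize = TRUE)
}

#' Read a ddG table (TSV) into a mutation spectrum
#'
#' Expects a header with a column `ddG_kcal_per_mol`; other columns are
#' ignored. Lines starting with `#` are treated as comments.
#'
#' @param path TSV file path.
#' @param h bin width (kcal/mol).
#' @return a [MutationSpectrum-class].
#' @export
readDdgTable <- function(path, h = 0.5) {
  if (!file.exists(path)) stop(sprintf("ddG table not found: %s", path))
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  if (!"ddG_kcal_per_mol" %in% names(tab))
    stop("ddG table must have a column 'ddG_kcal_per_mol'")
  spectrumFromDdg(tab[["ddG_kcal_per_mol"]], h = h)
}

#' Write / read a spectrum as TSV
#'
#' Columns `offset_kcal_per_mol` and `weight`.
#'
#' @param spectrum a [MutationSpectrum-class].
#' @param path output file.
#' @param header optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines("offset_kcal_per_mol\tweight", con)
  writeLines(sprintf("%.6g\t%.10g", spectrum@offsets, spectrum@weights), con)
  invisible(path)
}

#' @rdname writeSpectrum
#' @param binWidth bin width of the stored spectrum.
#' @export
readSpectrum <- function(path, binWidth = 0.5) {
  tab <- utils::read.delim(path, comment.char = "#")
  mutationSpectrum(tab$offset_kcal_per_mol, tab$weight, binWidth = binWidth)
}

#' @describeIn spectrumSummary beneficial and strong-beneficial fractions,
#'   mean beneficial step size and mean deleterious step.
#' @param kT thermal energy used for the 5-fold ("strong") threshold
#'   `-kT*log(5)`.
#' @return a list with `beneficialFraction`, `strongBeneficialFraction`,
#'   `meanBeneficialStep` (mean |delta| over improving bins, kcal/mol) and
#'   `meanDeleteriousStep` (mean delta over worsening bins).
#' @export
setMethod("spectrumSummary", "MutationSpectrum", function(object, kT = 0.59) {
  ben <- object@offsets < 0
  del <- object@offsets > 0
  wb <- sum(object@weights[ben])
  thr <- -kT * log(5)
  list(
    beneficialFraction = wb,
    strongBeneficialFraction = sum(object@weights[object@offsets <= thr]),
    meanBeneficialStep = if (wb > 0)
      sum(object@weights[ben] * abs(object@offsets[ben])) / wb else NA_real_,
    meanDeleteriousStep = if (sum(object@weights[del]) > 0)
      sum(object@weights[del] * object@offsets[del]) / sum(object@weights[del]) else NA_real_
  )
})

#' @describeIn MutationSpectrum-class compact display
#' @param object a `MutationSpectrum` object
#' @export
setMethod("show", "MutationSpectrum", function(object) {
  s <- spectrumSummary(object)
  cat(sprintf("MutationSpectrum: %d bins, h = %.3g kcal/mol\n",
              length(object@offsets), object@binWidth))
  cat(sprintf("  beneficial %.1f%% (strong %.1f%%), mean beneficial step %.3g kcal/mol\n",
              100 * s$beneficialFraction, 100 * s$strongBeneficialFraction,
              s$meanBeneficialStep))
  df <- data.frame(offset = object@offsets, weight = object@weights)
  print(df, row.names = FALSE)
})
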