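# shared fixtures, all built in code

# defaults used throughout: b = 0.7, p = 0.5, germline one bin above neutral
refParams <- function(...) modelParams(...)

# a one-class beneficial spectrum (every mutation improves by one bin)
singleBeneficial <- function() mutationSpectrum(-0.5, 1, binWidth = 0.5)

# a one-class deleterious spectrum
singleDeleterious <- function() mutationSpectrum(0.5, 1, binWidth = 0.5)

# wide grid for mean-field comparisons (keeps decaying mutants on-grid)
wideGrid <- function(params = refParams()) seq(-8, 12, by = params@h)

# brute-force nearest-center binning, independent of spectrumFromDdg():
# scan candidate centers over a wide lattice and pick the closest by
# explicit comparison, half-way ties away from zero
bruteForceBin <- function(values, h) {
  centers <- seq(-50, 50) * h
  vapply(values, function(v) {
    d <- abs(centers - v)
    cand <- centers[d < min(d) + 1e-12]
    if (length(cand) > 1) cand <- cand[which.max(abs(cand))]
    cand
  }, numeric(1))
}
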