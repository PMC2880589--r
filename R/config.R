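#' @include AllClasses.R params.R spectrum.R
NULL

.CONFIG_KEYS <- c(
  "p_mutated_daughter", "divisions_per_day", "kT", "b", "h",
  "f_silent", "f_lethal", "f_affinity", "ka_in_ratio", "x_offset_in",
  "N0", "t_max", "spectrum", "termination", "p_grid", "ka_in_grid",
  "n_bins", "replicates", "seed"
)

.CONFIG_DEFAULTS <- list(
  p_mutated_daughter = 0.5, divisions_per_day = 4L, kT = 0.59, b = 0.7,
  h = 0.5, f_silent = 0.5, f_lethal = 0.3, f_affinity = 0.2,
  ka_in_ratio = 0.18, N0 = 1e5, t_max = 100, spectrum = "default",
  termination = "fixed_window_14d", n_bins = 20L, replicates = 100L,
  seed = 1L
)

.configHash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(x), tmp)
  unname(tools::md5sum(tmp))
}

.configToList <- function(cfg) {
  p <- cfg@params
  list(
    p_mutated_daughter = p@pMutatedDaughter,
    divisions_per_day = p@divisionsPerDay,
    kT = p@kT, b = p@b, h = p@h,
    f_silent = p@fSilent, f_lethal = p@fLethal, f_affinity = p@fAffinity,
    ka_in_ratio = kaRatio(p@XStarOffsetIn, p@kT),
    N0 = p@N0, t_max = p@tMax,
    spectrum = cfg@spectrumSource,
    termination = cfg@termination,
    p_grid = cfg@pGrid, ka_in_grid = cfg@kaGrid,
    n_bins = cfg@nBins, replicates = cfg@replicates, seed = cfg@seed
  )
}

.buildConfig <- function(vals) {
  filled <- utils::modifyList(.CONFIG_DEFAULTS, vals)
  rangeCheck <- function(key, lo, hi) {
    v <- filled[[key]]
    if (!is.numeric(v) || any(v < lo) || any(v > hi))
      stop(sprintf("config value out of range: %s must lie in [%g, %g]", key, lo, hi))
  }
  rangeCheck("p_mutated_daughter", 0, 1 - 1e-12)
  rangeCheck("ka_in_ratio", 1e-12, Inf)
  rangeCheck("b", 1e-12, Inf)
  if (!filled$termination %in% c("fixed_window_14d", "recovery_unbounded", "horizon_only"))
    stop(sprintf("unknown termination mode: %s", filled$termination))
  Xin <- if (!is.null(vals$x_offset_in)) vals$x_offset_in
         else -filled$kT * log(filled$ka_in_ratio)
  params <- modelParams(
    b = filled$b, pMutatedDaughter = filled$p_mutated_daughter,
    XStarOffsetIn = Xin, N0 = filled$N0,
    divisionsPerDay = filled$divisions_per_day, kT = filled$kT,
    h = filled$h, fSilent = filled$f_silent, fLethal = filled$f_lethal,
    fAffinity = filled$f_affinity, tMax = filled$t_max)
  cfg <- new("RunConfig",
    params = params,
    spectrumSource = as.character(filled$spectrum),
    termination = filled$termination,
    pGrid = if (is.null(filled$p_grid)) defaultPGrid() else as.numeric(filled$p_grid),
    kaGrid = if (is.null(filled$ka_in_grid)) defaultKaGrid() else as.numeric(filled$ka_in_grid),
    nBins = as.integer(filled$n_bins),
    replicates = as.integer(filled$replicates),
    seed = as.integer(filled$seed),
    hash = "")
  cfg@hash <- .configHash(.configToList(cfg))
  cfg
}

#' Parse a run configuration file
#'
#' Reads a flat YAML (or JSON; both parse through the YAML reader) file of
#' key/value pairs, rejects unknown keys by name, range-checks values, fills
#' every missing key with its default, and attaches a provenance hash that
#' all tabular outputs carry. The germline binding level may be given either
#' as `ka_in_ratio` (Ka_in/Ka*) or directly as `x_offset_in` (kcal/mol).
#'
#' @param path configuration file.
#' @return a validated [RunConfig-class].
#' @seealso [serializeConfig()] for the lossless inverse.
#' @export
parseConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  nm <- names(vals)
  if ("p" %in% nm) { # short alias
    vals$p_mutated_daughter <- vals$p
    vals$p <- NULL; nm <- names(vals)
  }
  unknown <- setdiff(nm, .CONFIG_KEYS)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- .buildConfig(vals)
  if (cfg@spectrumSource != "default" && !file.exists(cfg@spectrumSource))
    stop(sprintf("spectrum file not found: %s", cfg@spectrumSource))
  cfg
}

#' Serialize a run configuration
#'
#' Writes the full key set as YAML; `parseConfig(serializeConfig(cfg))`
#' round-trips losslessly.
#'
#' @param cfg a [RunConfig-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
serializeConfig <- function(cfg, path) {
  yaml::write_yaml(.configToList(cfg), path)
  invisible(path)
}

#' Resolve the mutation spectrum a configuration names
#'
#' @param cfg a [RunConfig-class].
#' @return a [MutationSpectrum-class]: the packaged default, or the binned
#'   ddG table the config points to.
#' @export
configSpectrum <- function(cfg) {
  if (cfg@spectrumSource == "default") defaultSpectrum(cfg@params@kT)
  else readDdgTable(cfg@spectrumSource, h = cfg@params@h)
}

#' Provenance header lines for tabular outputs
#'
#' @param cfg a [RunConfig-class].
#' @return character vector of header lines (without the leading `#`).
#' @export
provenanceHeader <- function(cfg) {
  c(sprintf("gcmature %s", as.character(utils::packageVersion("gcmature"))),
    sprintf("config_hash: %s", cfg@hash))
}

#' Generate the reference fixtures
#'
#' Writes (i) a synthetic ddG table of `nDdg` rows sampled from the packaged
#' default spectrum (bin centers jittered uniformly within a quarter bin, so
#' re-binning recovers the spectrum weights), and (ii) the three reference
#' configurations: pooled-spleen optimization, isolated-GC optimization, and
#' the all-or-none distribution run (Ka_in/Ka* = 0.5, 50% mutated daughters,
#' b = 0.7, N0 = 3000). Output is byte-identical for a given seed.
#'
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @param nDdg rows in the synthetic ddG table.
#' @return named character vector of the files written, invisibly.
#' @export
makeFixtures <- function(seed, dir, nDdg = 500L) {
  if (missing(seed)) stop("explicit 'seed' is required")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- defaultSpectrum()
  ddgPath <- file.path(dir, "ddg_synthetic.tsv")
  .withSeed(seed, function() {
    centers <- sample(sp@offsets, nDdg, replace = TRUE, prob = sp@weights)
    vals <- centers + stats::runif(nDdg, -sp@binWidth / 4, sp@binWidth / 4)
    con <- file(ddgPath, "w")
    on.exit(close(con))
    writeLines(c("# synthetic ddG values sampled from the packaged default spectrum",
                 sprintf("# seed: %d", seed),
                 "ddG_kcal_per_mol"), con)
    writeLines(sprintf("%.6f", vals), con)
  })
  cfgs <- list(
    pooled_spleen = list(p_mutated_daughter = 0.5, b = 0.7, N0 = 1e5,
                         ka_in_ratio = 0.18, termination = "fixed_window_14d",
                         seed = seed),
    isolated_gc = list(p_mutated_daughter = 0.6, b = 0.7, N0 = 3000,
                       ka_in_ratio = 0.5, termination = "recovery_unbounded",
                       seed = seed),
    all_or_none = list(p_mutated_daughter = 0.5, b = 0.7, N0 = 3000,
                       ka_in_ratio = 0.5, termination = "recovery_unbounded",
                       n_bins = 20L, seed = seed)
  )
  paths <- c(ddg = ddgPath)
  for (nm in names(cfgs)) {
    p <- file.path(dir, paste0(nm, ".yaml"))
    yaml::write_yaml(cfgs[[nm]], p)
    paths[nm] <- p
  }
  invisible(paths)
}

#' @describeIn RunConfig-class compact display
#' @param object a `RunConfig` object
#' @export
setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig (hash %s)\n", substr(object@hash, 1, 8)))
  cat(sprintf("  termination: %s, spectrum: %s, seed: %d\n",
              object@termination, object@spectrumSource, object@seed))
  show(object@params)
})
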