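#' @include experiments.R
NULL

# hash of the run configuration; the output location does not change what is
# computed, so it is excluded to keep re-runs relocatable
configHash <- function(cfg) {
  cfg$output_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end demographic-inference pipeline
#'
#' Stages, in order: `simulate` (or load a provided VCF), `filter`, `sfs`,
#' `fit`, `report`.  Each stage writes its outputs under `output_dir`; every
#' output embeds the master seed and the config hash, and the final manifest
#' records per-stage file checksums so that identical configs and seeds give
#' identical runs.  Configuration errors (e.g. a VCF input without a
#' popmap, or a missing model file) fail during validation, before any
#' compute.
#'
#' @param config a list or the path of a YAML file with fields:
#'   `output_dir`, `seed`, `model` (model YAML path), and optionally `vcf` +
#'   `popmap` (analyse existing genotypes instead of simulating),
#'   `n_sites`, `locus_length`, `missing_rate`, `filter`
#'   (`r`, `p`, `min_mac`, `max_obs_het`, `overall_rate`), `schedule`
#'   (`n_starts`, `n_cycles`, `n_sims`), `free` (searched parameter names).
#' @param resume skip stages whose outputs already exist.
#' @return the manifest list, invisibly (also written as `manifest.json`).
#' @export
runPipeline <- function(config, resume = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config

  ## ---- validation (fail fast, before any compute) ----
  for (field in c("output_dir", "seed", "model"))
    if (is.null(cfg[[field]])) stop("config is missing required field: ", field)
  if (!file.exists(cfg$model)) stop("model file not found: ", cfg$model)
  if (!is.null(cfg$vcf)) {
    if (is.null(cfg$popmap)) stop("config provides a vcf but no popmap")
    if (!file.exists(cfg$vcf)) stop("vcf not found: ", cfg$vcf)
    if (!file.exists(cfg$popmap)) stop("popmap not found: ", cfg$popmap)
  } else if (is.null(cfg$n_sites)) {
    stop("config must provide n_sites when simulating")
  }
  seed <- as.integer(cfg$seed)
  hash <- configHash(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  outPath <- function(...) file.path(cfg$output_dir, ...)
  stamp <- c(sprintf("##coalSFS_seed=%d", seed),
             sprintf("##coalSFS_config_hash=%s", hash))
  model <- readModelYAML(cfg$model)
  locusLength <- cfg$locus_length %||% 51
  stages <- character(0)
  log <- function(...) message("[coalSFS] ", ...)

  ## ---- stage 1: simulate (or ingest) ----
  vcfPath <- outPath("genotypes.vcf")
  popmapPath <- outPath("popmap.tsv")
  if (!(resume && file.exists(vcfPath))) {
    if (!is.null(cfg$vcf)) {
      g <- readVCF(cfg$vcf, cfg$popmap)
      writeVCF(g, vcfPath, header = stamp)
    } else {
      log("simulating ", cfg$n_sites, " loci under model '", model@id, "'")
      g <- simulateGenotypes(model, cfg$n_sites, locusLength = locusLength,
                             seed = deriveSeed(seed, 1))
      if (!is.null(cfg$missing_rate) && cfg$missing_rate > 0)
        g <- applyMissingness(g, cfg$missing_rate, seed = deriveSeed(seed, 2))
      writeVCF(g, vcfPath, header = stamp)
    }
    writeLines(c(paste0("# ", stamp),
                 paste(colnames(genotypes(g)), populations(g), sep = "\t")),
               popmapPath)
  } else {
    g <- readVCF(vcfPath, popmapPath)
  }
  stages <- c(stages, "simulate")

  ## ---- stage 2: filter ----
  fcfg <- do.call(FilterConfig, c(list(), cfg$filter))
  filteredPath <- outPath("filtered.vcf")
  if (!(resume && file.exists(filteredPath))) {
    gf <- filterSites(g, fcfg)
    writeVCF(gf, filteredPath, header = stamp)
  } else {
    gf <- readVCF(filteredPath, popmapPath)
  }
  stages <- c(stages, "filter")

  ## ---- stage 3: pairwise 2D-mSFS ----
  obs <- buildPairwiseSFS(gf, seed = deriveSeed(seed, 3))
  for (nm in names(obs))
    writeSFS(obs[[nm]], outPath(sprintf("sfs_%s.tsv", gsub("\\|", "_", nm))),
             header = sub("^##", "", stamp))
  stages <- c(stages, "sfs")

  ## ---- stage 4: fit ----
  sch <- cfg$schedule %||% list()
  schedule <- FitSchedule(nStarts = sch$n_starts %||% 3,
                          nCycles = sch$n_cycles %||% 10,
                          nSims = sch$n_sims %||% 5000,
                          seed = deriveSeed(seed, 4))
  free <- unlist(cfg$free) %||% NULL
  log("fitting model '", model@id, "' (",
      if (is.null(free)) nrow(freeParams(model)) else length(free),
      " free parameters)")
  fit <- ecmFit(model, obs, schedule = schedule, free = free,
                locusLength = locusLength)
  jsonlite::write_json(
    list(seed = seed, config_hash = hash, model = model@id,
         params = as.list(fittedParams(fit)), lnL = fit@lnL, k = fit@k,
         AIC = fit@AIC, trace = fit@trace, converged = fit@converged),
    outPath("fit.json"), auto_unbox = TRUE, digits = NA)
  stages <- c(stages, "fit")

  ## ---- stage 5: report / manifest ----
  outputs <- list.files(cfg$output_dir, full.names = TRUE)
  outputs <- setdiff(outputs, outPath("manifest.json"))
  manifest <- list(
    seed = seed, config_hash = hash,
    package_version = as.character(utils::packageVersion("coalSFS")),
    stages = stages <- c(stages, "report"),
    checksums = as.list(setNames(unname(tools::md5sum(outputs)),
                                 basename(outputs))))
  jsonlite::write_json(manifest, outPath("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
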