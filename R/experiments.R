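#' @include fit.R catalog.R
NULL

#' Simulate a full pairwise 2D-mSFS dataset under a model
#'
#' Convenience driver: simulate genotypes, (optionally) thin them with
#' per-genotype missingness, and build all pairwise folded spectra with
#' bootstrap completion.
#'
#' @param model a [DemographicModel-class].
#' @param nSites number of loci.
#' @param seed master seed.
#' @param missingRate per-genotype missing probability (default 0).
#' @param locusLength mutation opportunity in bp.
#' @return named list of [SFS2D-class] over all deme pairs.
#' @export
simulateSFSData <- function(model, nSites, seed = NULL, missingRate = 0,
                            locusLength = 51) {
  g <- simulateGenotypes(model, nSites, locusLength = locusLength,
                         seed = deriveSeed(seed, 1))
  if (missingRate > 0)
    g <- applyMissingness(g, missingRate, seed = deriveSeed(seed, 2))
  buildPairwiseSFS(g, seed = deriveSeed(seed, 3))
}

#' Divergence-time recovery experiment
#'
#' Simulates a pairwise 2D-mSFS dataset under `model` with its current
#' parameter values as truth, then refits the named free parameters (all
#' other parameters stay fixed at truth) and reports estimates alongside
#' truth, with event times also converted to thousands of years (kya).
#'
#' @param model a [DemographicModel-class] whose current values are truth.
#' @param free names of the free parameters to refit.
#' @param nSites loci in the simulated dataset.
#' @param schedule a [FitSchedule-class] (e.g. [deskSchedule()]).
#' @param seed master seed (data seed and fit seed are derived from it).
#' @param ts a [TimeScale-class] for the kya conversion.
#' @param locusLength mutation opportunity in bp.
#' @return list with `fit` (a [FitResult-class]) and `comparison`
#'   (data.frame: param, truth, estimate, truth_kya, estimate_kya — kya
#'   columns only for parameters ending up as event times).
#' @export
recoveryExperiment <- function(model, free, nSites = 50000,
                               schedule = deskSchedule(), seed = 1,
                               ts = TimeScale(), locusLength = 51) {
  truth <- getModelParams(model)[free]
  obs <- simulateSFSData(model, nSites, seed = deriveSeed(seed, 17),
                         locusLength = locusLength)
  sched <- FitSchedule(nStarts = schedule@nStarts, nCycles = schedule@nCycles,
                       nSims = schedule@nSims, seed = deriveSeed(seed, 23))
  fit <- ecmFit(model, obs, schedule = sched, free = free,
                locusLength = locusLength)
  est <- fittedParams(fit)[free]
  isTime <- vapply(free, function(nm) {
    tg <- parseTarget(strsplit(
      model@freeParams$targets[match(nm, model@freeParams$name)],
      ";", fixed = TRUE)[[1]][1])
    tg$kind == "time"
  }, logical(1))
  comparison <- data.frame(
    param = free, truth = unname(truth), estimate = unname(est),
    truth_kya = ifelse(isTime, generationsToYears(unname(truth), ts) / 1000,
                       NA_real_),
    estimate_kya = ifelse(isTime, generationsToYears(unname(est), ts) / 1000,
                          NA_real_),
    stringsAsFactors = FALSE)
  list(fit = fit, comparison = comparison)
}

#' Six-taxon (e1) divergence-time recovery experiment
#'
#' Data are simulated under [modelE1()] with the published point estimates
#' as truth; the five divergence times are refitted (sizes, the size-change
#' time and migration fixed at truth) with a scaled-down ECM schedule.
#'
#' @param nSites simulated loci (default 50,000).
#' @param schedule fit schedule (default [deskSchedule()]: 3 starts, 10
#'   cycles, 5000 simulations per likelihood evaluation).
#' @param seed master seed.
#' @return as [recoveryExperiment()].
#' @export
e1RecoveryExperiment <- function(nSites = 50000, schedule = deskSchedule(),
                                 seed = 1) {
  recoveryExperiment(modelE1(), free = c("T1", "T2", "T3", "T4", "T5"),
                     nSites = nSites, schedule = schedule, seed = seed)
}

#' Five-ecotype (g2) recovery experiment
#'
#' Data are simulated under [modelG2()] with the published point estimates
#' as truth; the four divergence times and the shared recent-reduction time
#' are refitted (size magnitudes and migration fixed at truth).
#'
#' @inheritParams e1RecoveryExperiment
#' @export
g2RecoveryExperiment <- function(nSites = 50000, schedule = deskSchedule(),
                                 seed = 1) {
  recoveryExperiment(modelG2(), free = c("T2", "T3", "T_SG", "T1", "T_red"),
                     nSites = nSites, schedule = schedule, seed = seed)
}

#' Migration-recovery runs: do refitted migrant numbers stay below one?
#'
#' Alternating e1/g2 recovery fits with migration free: for each run, true
#' per-generation migrant numbers are drawn uniformly inside
#' `migrantRange` (the published estimate range), converted to forward
#' fractions via the destination deme size, data are simulated, and the
#' migration fractions are refitted (everything else fixed at truth).  The
#' summary of interest is the largest refitted migrant number per generation
#' across all deme pairs and runs.
#'
#' @param nRuns number of seeded runs (default 10).
#' @param nSites loci per run.
#' @param schedule fit schedule for the migration-only refits.
#' @param seed master seed.
#' @param migrantRange range of true migrant numbers per generation.
#' @param searchMaxMigrants upper search bound for each migration fraction,
#'   expressed as migrant numbers per generation (default 5 — an order of
#'   magnitude above the bound of interest, while keeping the coalescent
#'   simulations tractable; near-panmictic fractions would be both
#'   biologically meaningless here and dominated by migration events).
#' @return list with `perRun` (max refitted migrant number per run) and
#'   `maxMigrants` (overall maximum).
#' @export
migrationRecoveryRuns <- function(nRuns = 10, nSites = 50000,
                                  schedule = FitSchedule(nStarts = 1,
                                                         nCycles = 5,
                                                         nSims = 2000),
                                  seed = 1,
                                  migrantRange = c(0.020, 0.511),
                                  searchMaxMigrants = 5) {
  perRun <- numeric(nRuns)
  for (r in seq_len(nRuns)) {
    model <- if (r %% 2L == 1L) modelE1() else modelG2()
    migNames <- grep("^m_", model@freeParams$name, value = TRUE)
    N <- setNames(model@populations$N_current, model@populations$name)
    destOf <- vapply(migNames, function(nm) strsplit(nm, "_")[[1]][3],
                     character(1))
    truth <- withSeed(deriveSeed(seed, 31, r), {
      vapply(seq_along(migNames), function(i)
        runif(1, migrantRange[1], migrantRange[2]) / N[[destOf[i]]],
        numeric(1))
    })
    names(truth) <- migNames
    idx <- match(migNames, model@freeParams$name)
    model@freeParams$upper[idx] <-
      pmin(model@freeParams$upper[idx], searchMaxMigrants / N[destOf])
    model <- setModelParams(model, truth)
    obs <- simulateSFSData(model, nSites, seed = deriveSeed(seed, 37, r))
    sched <- FitSchedule(nStarts = schedule@nStarts,
                         nCycles = schedule@nCycles,
                         nSims = schedule@nSims,
                         seed = deriveSeed(seed, 41, r))
    fit <- ecmFit(model, obs, schedule = sched, free = migNames)
    fitted <- setModelParams(model, fittedParams(fit))
    perRun[r] <- max(migrantNumbers(fitted)$migrants_per_generation)
  }
  list(perRun = perRun, maxMigrants = max(perRun))
}
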