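#' @include sfs.R
NULL

## ---- composite likelihood ---------------------------------------------------

llOnePair <- function(counts, p, minProb) {
  if (!all(dim(counts) == dim(p))) stop("obs/expected shape mismatch")
  sum(counts * log(pmax(p, minProb)))
}

#' Natural-log composite likelihood of observed 2D-mSFS data
#'
#' `lnL = sum over pairs, sum over cells of count * ln(max(p, minProb))`.
#' Pairs are combined by summation (composite likelihood over population
#' pairs, treating sites — and pairs — as independent).  `minProb` guards
#' cells whose simulated probability is zero at finite simulation effort;
#' [ecmFit()] uses `1 / (10 * nSims)`.
#'
#' @param obs an [SFS2D-class] or named list of them.
#' @param expected probability matrix or list matching `obs` (entries sum
#'   to 1 per pair, monomorphic cell included).
#' @param minProb floor for simulated cell probabilities (default `1e-8`).
#' @return the log composite likelihood (a single number).
#' @export
compositeLogLik <- function(obs, expected, minProb = 1e-8) {
  if (is(obs, "SFS2D")) obs <- list(obs)
  if (is.matrix(expected)) expected <- list(expected)
  if (length(obs) != length(expected)) stop("obs/expected length mismatch")
  if (!is.null(names(obs)) && !is.null(names(expected)))
    expected <- expected[names(obs)]
  sum(vapply(seq_along(obs), function(i)
    llOnePair(sfsCounts(obs[[i]]), expected[[i]], minProb), numeric(1)))
}

## ---- ECM fitting ------------------------------------------------------------

obsPairs <- function(obs) {
  lapply(obs, function(s) s@pair)
}

checkObsAgainstModel <- function(model, obs) {
  pops <- model@populations
  for (s in obs) {
    i <- match(s@pair, pops$name)
    if (anyNA(i))
      stop("observed SFS pair (", pairKey(s@pair[1], s@pair[2]),
           ") references demes absent from the model")
    if (s@n1 != 2L * pops$n_diploid[i[1]] || s@n2 != 2L * pops$n_diploid[i[2]])
      stop("observed SFS sample sizes do not match the model's n_diploid")
  }
  invisible(TRUE)
}

#' Fit a demographic model by composite-likelihood ECM maximization
#'
#' For each random start (log-uniform within the free-parameter bounds), the
#' optimizer runs cycles of conditional one-dimensional maximization over
#' each free parameter in turn (Brent search on the log10 scale within the
#' declared bounds), with the expected spectra per likelihood evaluation
#' estimated by [expectedSFSAll()].  Evaluations share a common-random-number
#' simulation seed within each cycle (`crn = "cycle"`, the default), which
#' makes each cycle's conditional searches deterministic while letting
#' successive cycles average over independent Monte-Carlo surfaces;
#' `crn = "global"` reuses one seed for the whole start, making the
#' accepted-likelihood trace exactly non-decreasing.  Parameter update order
#' is the declaration order in the model; a cycle improving its own
#' (same-seed) likelihood by less than `tolLnL` stops the start early.
#'
#' @param model a [DemographicModel-class] with free parameters.
#' @param obs named list of [SFS2D-class] (or a single one).
#' @param schedule a [FitSchedule-class].
#' @param free optional character vector restricting which declared free
#'   parameters are searched (the rest stay fixed at their current values).
#' @param start optional named vector used as the first start (natural
#'   scale), e.g. bootstrap refits starting at the MLE.
#' @param locusLength mutation opportunity in bp per locus.
#' @param minProb probability floor; default `1 / (10 * nSims)`.
#' @param tolLnL early-stop threshold on the per-cycle improvement.
#' @param crn common-random-number regime: `"cycle"` (default) or
#'   `"global"`.
#' @return a [FitResult-class].
#' @export
ecmFit <- function(model, obs, schedule = FitSchedule(), free = NULL,
                   start = NULL, locusLength = 51, minProb = NULL,
                   tolLnL = 0.01, crn = c("cycle", "global")) {
  stopifnot(is(model, "DemographicModel"), is(schedule, "FitSchedule"))
  crn <- match.arg(crn)
  if (is(obs, "SFS2D")) obs <- setNames(list(obs),
                                        pairKey(obs@pair[1], obs@pair[2]))
  checkObsAgainstModel(model, obs)
  pairs <- obsPairs(obs)
  fp <- model@freeParams
  if (!is.null(free)) {
    missing <- setdiff(free, fp$name)
    if (length(missing))
      stop("not free parameters of the model: ", paste(missing, collapse = ", "))
    fp <- fp[fp$name %in% free, , drop = FALSE]
  }
  k <- nrow(fp)
  nSims <- schedule@nSims
  if (is.null(minProb)) minProb <- 1 / (10 * nSims)

  objectiveAt <- function(values, evalSeed) {
    m2 <- setModelParams(model, values, check = FALSE)
    if (!modelParamsValid(m2)) return(-1e18)
    ex <- expectedSFSAll(m2, pairs = pairs, nSims = nSims, seed = evalSeed,
                         locusLength = locusLength)
    compositeLogLik(obs, ex, minProb = minProb)
  }

  if (k == 0L) {
    lnL <- objectiveAt(numeric(0), deriveSeed(schedule@seed, 200))
    return(new("FitResult", modelId = model@id, params = numeric(0),
               lnL = lnL, k = 0L, AIC = -2 * lnL, trace = lnL,
               converged = TRUE))
  }

  lo <- log10(fp$lower); hi <- log10(fp$upper)
  best <- NULL
  for (s in seq_len(schedule@nStarts)) {
    evalSeed <- deriveSeed(schedule@seed, 200, s)
    objective <- function(logv) {
      objectiveAt(setNames(10^logv, fp$name), evalSeed)
    }
    cur <- NULL
    if (s == 1L && !is.null(start)) {
      if (!all(fp$name %in% names(start)))
        stop("start must name every searched free parameter")
      cur <- pmin(pmax(log10(start[fp$name]), lo), hi)
    } else {
      # draw log-uniform starts until the proposal is a legal history
      cur <- withSeed(deriveSeed(schedule@seed, 100, s), {
        for (try in 1:100) {
          v <- runif(k, lo, hi)
          m2 <- setModelParams(model, setNames(10^v, fp$name), check = FALSE)
          if (modelParamsValid(m2)) break
        }
        v
      })
    }
    trace <- numeric(0)
    converged <- FALSE
    fCur <- NA_real_
    for (cyc in seq_len(schedule@nCycles)) {
      if (crn == "cycle") evalSeed <- deriveSeed(schedule@seed, 200, s, cyc)
      if (crn == "cycle" || cyc == 1L) fCur <- objective(cur)
      fStart <- fCur
      for (j in seq_len(k)) {
        g <- function(x) { v <- cur; v[j] <- x; objective(v) }
        opt <- optimize(g, lower = lo[j], upper = hi[j], maximum = TRUE,
                        tol = 2e-3)
        if (is.finite(opt$objective) && opt$objective > fCur) {
          cur[j] <- opt$maximum
          fCur <- opt$objective
        }
      }
      trace <- c(trace, fCur)
      if (fCur - fStart < tolLnL) {
        converged <- TRUE
        break
      }
    }
    if (is.null(best) || fCur > best$lnL)
      best <- list(par = cur, lnL = fCur, trace = trace,
                   converged = converged || schedule@nCycles == 1L)
  }
  if (!is.finite(best$lnL) || best$lnL <= -1e17)
    stop("no start achieved a finite composite likelihood")
  params <- setNames(10^best$par, fp$name)
  new("FitResult", modelId = model@id, params = params, lnL = best$lnL,
      k = k, AIC = 2 * k - 2 * best$lnL, trace = best$trace,
      converged = best$converged)
}

## ---- model selection --------------------------------------------------------

#' Select the best model by AIC
#'
#' Returns the fit with the lowest AIC and a delta-AIC table.  Exact AIC ties
#' go to the model with fewer parameters; remaining ties break
#' lexicographically on the model id (documented, deterministic).  The
#' result is invariant to the order of `fits`.
#'
#' @param fits list of [FitResult-class] objects.
#' @return list with `best` (a FitResult) and `table` (data.frame with
#'   `model_id`, `k`, `lnL`, `AIC`, `dAIC`, sorted by dAIC).
#' @export
selectBest <- function(fits) {
  if (!length(fits)) stop("no fits supplied")
  tab <- data.frame(
    model_id = vapply(fits, function(f) f@modelId, character(1)),
    k = vapply(fits, function(f) f@k, integer(1)),
    lnL = vapply(fits, function(f) f@lnL, numeric(1)),
    AIC = vapply(fits, function(f) f@AIC, numeric(1)),
    stringsAsFactors = FALSE)
  ord <- order(tab$AIC, tab$k, tab$model_id)
  tab <- tab[ord, , drop = FALSE]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  list(best = fits[[ord[1]]], table = tab)
}

## ---- stepwise model-building driver -----------------------------------------

#' Stepwise divergence-model search over growing taxon subsets
#'
#' Implements the ladder strategy for building many-taxon divergence models:
#' each step enumerates candidate rooted divergence orderings of its taxon
#' subset (constrained by the clades won at previous steps), fits every
#' candidate by [ecmFit()], and selects the AIC-best.  The winning clades
#' are added to the constraint set for later steps.
#'
#' @param plan list of character vectors, the taxon subset of each step in
#'   order.
#' @param data named list of [SFS2D-class] over all needed pairs.
#' @param schedule a [FitSchedule-class].
#' @param populations population table (as in [DemographicModel-class])
#'   covering all taxa.
#' @param mu mutation rate for candidate models.
#' @param timeBounds divergence-time search bounds in generations.
#' @param locusLength mutation opportunity in bp.
#' @return list with `path` (per step: taxa, winner id, dAIC table) and
#'   `best` (the last step's winning [FitResult-class]).
#' @export
stepwiseSearch <- function(plan, data, schedule, populations, mu,
                           timeBounds = c(1e2, 1e5), locusLength = 51) {
  allTaxa <- unique(unlist(plan))
  dataTaxa <- unique(unlist(obsPairs(data)))
  absent <- setdiff(allTaxa, dataTaxa)
  if (length(absent))
    stop("step references taxa absent from data: ",
         paste(absent, collapse = ", "))
  constraints <- list()
  path <- list()
  lastBest <- NULL
  for (stepI in seq_along(plan)) {
    taxa <- plan[[stepI]]
    cands <- enumerateCandidates(taxa, constraints, allTaxa = allTaxa)
    if (!length(cands)) stop("constraints eliminated every candidate")
    stepObs <- Filter(function(s) all(s@pair %in% taxa), data)
    fits <- lapply(cands, function(cand) {
      m <- candidateToModel(cand, populations, mu, timeBounds = timeBounds)
      ecmFit(m, stepObs, schedule = schedule, locusLength = locusLength)
    })
    sel <- selectBest(fits)
    winner <- cands[[match(sel$best@modelId,
                           vapply(cands, `[[`, character(1), "id"))]]
    constraints <- c(constraints, winner$clades)
    path[[stepI]] <- list(taxa = taxa, winner = winner$id, table = sel$table)
    lastBest <- sel$best
  }
  list(path = path, best = lastBest)
}

## ---- parametric bootstrap ---------------------------------------------------

#' Parametric-bootstrap confidence intervals for a fitted model
#'
#' Simulates `nReps` replicate 2D-mSFS datasets at the maximum-likelihood
#' estimates (multinomial draws per pair, with the observed per-pair site
#' totals, from the model's expected spectrum), refits each starting from
#' the MLE with the bootstrap schedule, and forms percentile 95% intervals
#' (2.5% and 97.5% quantiles, linear interpolation).  Replicate refits that
#' fail are logged and dropped, not fatal.
#'
#' @param best the [FitResult-class] of the model on the real data.
#' @param model the fitted [DemographicModel-class].
#' @param obs the observed data used for the fit (named list of
#'   [SFS2D-class]); supplies per-pair site totals.
#' @param schedule bootstrap refit schedule (the full-scale analysis uses 15
#'   ECM cycles and a single start from the MLE).
#' @param nReps number of bootstrap replicates (default 100).
#' @param seed master seed.
#' @param expectedSims simulations used to estimate the MLE spectrum the
#'   replicates are drawn from (default `schedule@nSims`).
#' @param locusLength mutation opportunity in bp.
#' @return a [BootstrapResult-class].
#' @export
parametricBootstrap <- function(best, model, obs, schedule, nReps = 100,
                                seed = 1, expectedSims = NULL,
                                locusLength = 51) {
  stopifnot(is(best, "FitResult"))
  if (best@k == 0L)
    return(new("BootstrapResult", replicates = data.frame(),
               ci = data.frame(param = character(), lower = numeric(),
                               upper = numeric()),
               failures = 0L))
  mle <- fittedParams(best)
  mleModel <- setModelParams(model, mle)
  pairs <- obsPairs(obs)
  expectedSims <- expectedSims %||% schedule@nSims
  pHat <- expectedSFSAll(mleModel, pairs = pairs, nSims = expectedSims,
                         seed = deriveSeed(seed, 7), locusLength = locusLength)
  totals <- vapply(obs, function(s) sum(sfsCounts(s)), numeric(1))
  rows <- list()
  failures <- 0L
  for (r in seq_len(nReps)) {
    simObs <- withSeed(deriveSeed(seed, 11, r), {
      out <- lapply(seq_along(obs), function(i) {
        p <- pHat[[i]]
        cnt <- matrix(rmultinom(1, totals[i], as.vector(p)),
                      nrow(p), ncol(p))
        SFS2D(obs[[i]]@pair, obs[[i]]@n1, obs[[i]]@n2, cnt)
      })
      names(out) <- names(obs)
      out
    })
    fit <- tryCatch(
      ecmFit(mleModel, simObs,
             schedule = FitSchedule(nStarts = 1, nCycles = schedule@nCycles,
                                    nSims = schedule@nSims,
                                    seed = deriveSeed(seed, 13, r)),
             free = names(mle), start = mle, locusLength = locusLength),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit@lnL)) {
      failures <- failures + 1L
      next
    }
    rows[[length(rows) + 1L]] <- as.data.frame(as.list(fittedParams(fit)))
  }
  reps <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(numeric(0)), length(mle)), names(mle)))
  ci <- data.frame(
    param = names(mle),
    lower = vapply(names(mle), function(p)
      if (nrow(reps)) quantile(reps[[p]], 0.025, names = FALSE) else NA_real_,
      numeric(1)),
    upper = vapply(names(mle), function(p)
      if (nrow(reps)) quantile(reps[[p]], 0.975, names = FALSE) else NA_real_,
      numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  new("BootstrapResult", replicates = reps, ci = ci, failures = failures)
}

## ---- goodness of fit --------------------------------------------------------

#' Pearson residuals between an observed and a fitted 2D-mSFS
#'
#' Per-cell residuals `(obs - E) / sqrt(E)` with `E = total * p`, plus their
#' sum of squares as an aggregate statistic.  Cells with `E = 0` and no
#' observations contribute zero; `p` is floored at `minProb` otherwise.
#'
#' @param obs an [SFS2D-class] (or named list).
#' @param expected matching probability matrix (or list).
#' @param minProb probability floor.
#' @return list with `residuals` (matrix or list of matrices) and
#'   `aggregate` (sum of squared residuals over all pairs).
#' @export
gofResiduals <- function(obs, expected, minProb = 1e-8) {
  one <- function(s, p) {
    counts <- sfsCounts(s)
    if (!all(dim(counts) == dim(p))) stop("obs/expected shape mismatch")
    total <- sum(counts)
    E <- total * pmax(p, ifelse(counts > 0, minProb, 0))
    r <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
    nz <- E > 0
    r[nz] <- (counts[nz] - E[nz]) / sqrt(E[nz])
    r
  }
  if (is(obs, "SFS2D")) {
    r <- one(obs, expected)
    return(list(residuals = r, aggregate = sum(r^2)))
  }
  if (!is.null(names(obs)) && !is.null(names(expected)))
    expected <- expected[names(obs)]
  rs <- lapply(seq_along(obs), function(i) one(obs[[i]], expected[[i]]))
  names(rs) <- names(obs)
  list(residuals = rs, aggregate = sum(vapply(rs, function(r) sum(r^2),
                                              numeric(1))))
}

#' Side-by-side heat map of observed vs expected spectra
#'
#' @param obs an [SFS2D-class].
#' @param expected matching probability matrix.
#' @param main title prefix.
#' @export
plotSFSComparison <- function(obs, expected, main = "") {
  counts <- sfsCounts(obs)
  E <- sum(counts) * expected
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  for (panel in list(list(z = counts, lab = "observed"),
                     list(z = E, lab = "expected"))) {
    graphics::image(x = 0:(nrow(counts) - 1), y = 0:(ncol(counts) - 1),
                    z = log10(panel$z + 1), xlab = obs@pair[1],
                    ylab = obs@pair[2],
                    main = paste(main, panel$lab), col = grDevices::hcl.colors(32))
  }
  invisible(NULL)
}
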