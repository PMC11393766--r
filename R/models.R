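#' @include AllClasses.R
NULL

## ---- time conversions -------------------------------------------------------

#' Convert between generations and years
#'
#' @param t_gen time in generations before present (non-negative).
#' @param ts a [TimeScale-class] (default 5 years per generation) or a single
#'   positive number of years per generation.
#' @return time in years (or generations for the inverse).
#' @examples
#' generationsToYears(34140)            # 170700 years = 170.7 kya
#' yearsToGenerations(170700)           # 34140 generations
#' @export
generationsToYears <- function(t_gen, ts = TimeScale()) {
  g <- if (is(ts, "TimeScale")) ts@generationTimeYears else as.numeric(ts)
  if (!is.finite(g) || g <= 0) stop("generation time must be positive")
  if (any(t_gen < 0)) stop("time must be non-negative")
  t_gen * g
}

#' @param t_years time in years before present (non-negative).
#' @rdname generationsToYears
#' @export
yearsToGenerations <- function(t_years, ts = TimeScale()) {
  g <- if (is(ts, "TimeScale")) ts@generationTimeYears else as.numeric(ts)
  if (!is.finite(g) || g <= 0) stop("generation time must be positive")
  if (any(t_years < 0)) stop("time must be non-negative")
  t_years / g
}

## ---- model construction -----------------------------------------------------

normalizeEvents <- function(events) {
  ev <- data.frame(time = as.numeric(events$time),
                   kind = as.character(events$kind),
                   source = as.character(events$source),
                   sink = if (is.null(events$sink)) NA_character_
                          else as.character(events$sink),
                   new_size = if (is.null(events$new_size)) NA_real_
                              else as.numeric(events$new_size),
                   stringsAsFactors = FALSE)
  ev[order(ev$time), , drop = FALSE]
}

# Replay the event list backward in time and check structural legality:
# divergences must reference demes still extant at that time and exactly one
# ancestral lineage must remain beyond the oldest divergence.
checkTopology <- function(populations, events, stopOnError = TRUE) {
  fail <- function(msg) {
    if (stopOnError) stop(msg, call. = FALSE) else return(FALSE)
  }
  alive <- setNames(rep(TRUE, nrow(populations)), populations$name)
  ev <- events[order(events$time), , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    if (ev$time[i] < 0) return(fail("event times must be non-negative"))
    if (ev$kind[i] == "divergence") {
      src <- ev$source[i]; snk <- ev$sink[i]
      if (is.na(snk) || src == snk)
        return(fail("divergence needs two distinct demes"))
      if (!src %in% names(alive) || !snk %in% names(alive))
        return(fail(sprintf("divergence references unknown deme '%s' or '%s'",
                            src, snk)))
      if (!alive[src] || !alive[snk])
        return(fail(sprintf(
          "divergence at t=%g references deme already merged ('%s' -> '%s')",
          ev$time[i], src, snk)))
      alive[src] <- FALSE
    } else if (ev$kind[i] == "size_change") {
      if (!ev$source[i] %in% names(alive))
        return(fail(sprintf("size change references unknown deme '%s'",
                            ev$source[i])))
      if (is.na(ev$new_size[i]) || ev$new_size[i] <= 0)
        return(fail("size_change needs a positive new_size"))
    } else {
      return(fail(sprintf("unknown event kind '%s'", ev$kind[i])))
    }
  }
  if (sum(alive) != 1L)
    return(fail(sprintf(
      "model must leave exactly one ancestral lineage (found %d)", sum(alive))))
  TRUE
}

#' Build a validated demographic model
#'
#' Materializes a [DemographicModel-class] from a structured description (an R
#' list, typically parsed from a YAML config; see [readModelYAML()]).  All
#' type invariants are checked: positive sizes and sample counts, legal event
#' topology (a divergence may not reference a deme already merged at a more
#' recent time; exactly one ancestral lineage must remain), migration only
#' within the same island group, and every free parameter bound to at least
#' one model slot.
#'
#' @param spec a list with elements `id`, `populations`, `events`, optional
#'   `migration`, `mu`, optional `free_params`.
#' @return a validated [DemographicModel-class] with events sorted by time.
#' @export
buildModel <- function(spec) {
  pops <- do.call(rbind, lapply(spec$populations, function(p)
    data.frame(name = as.character(p$name),
               island_group = as.character(p$island_group),
               n_diploid = as.integer(p$n_diploid),
               N_current = as.numeric(p$N_current),
               stringsAsFactors = FALSE)))
  if (is.null(pops) || !nrow(pops)) stop("model needs at least one population")
  if (anyDuplicated(pops$name)) stop("population names must be unique")
  if (any(pops$n_diploid < 1)) stop("n_diploid must be >= 1")
  if (any(!is.finite(pops$N_current) | pops$N_current <= 0))
    stop("N_current must be positive")
  if (any(is.na(pops$island_group) | !nzchar(pops$island_group)))
    stop("island_group is required for every population")

  events <- if (length(spec$events)) {
    raw <- do.call(rbind, lapply(spec$events, function(e)
      data.frame(time = e$time, kind = e$kind, source = e$source,
                 sink = e$sink %||% NA_character_,
                 new_size = e$new_size %||% NA_real_,
                 stringsAsFactors = FALSE)))
    # parameter bindings and ordering constraints address events by row, so
    # when any are present the event list must already be in time order
    if ((length(spec$free_params) || length(spec$order_constraints)) &&
        is.unsorted(raw$time))
      stop("list events in time order when binding parameters by event index")
    normalizeEvents(raw)
  } else {
    data.frame(time = numeric(), kind = character(), source = character(),
               sink = character(), new_size = numeric(),
               stringsAsFactors = FALSE)
  }
  if (nrow(pops) > 1 || nrow(events)) checkTopology(pops, events)

  migration <- list()
  if (!is.null(spec$migration)) {
    mg <- spec$migration
    rates <- matrix(0, nrow(pops), nrow(pops),
                    dimnames = list(pops$name, pops$name))
    if (!is.null(mg$rates)) {
      if (is.matrix(mg$rates)) {
        rates[rownames(mg$rates), colnames(mg$rates)] <- mg$rates
      } else {
        for (entry in mg$rates) {
          if (!entry$from %in% pops$name || !entry$to %in% pops$name)
            stop("migration references unknown deme")
          rates[entry$from, entry$to] <- as.numeric(entry$rate)
        }
      }
    }
    if (any(rates < 0 | rates > 1)) stop("migration fractions must be in [0, 1]")
    grp <- setNames(pops$island_group, pops$name)
    for (i in pops$name) for (j in pops$name)
      if (rates[i, j] > 0 && grp[i] != grp[j])
        stop(sprintf(
          "illegal migration between island groups ('%s' in %s -> '%s' in %s)",
          i, grp[i], j, grp[j]))
    t_end <- as.numeric(mg$t_end %||% 0)
    if (t_end < 0) stop("migration t_end must be non-negative")
    if (any(rates > 0)) migration <- list(t_end = t_end, rates = rates)
  }

  mu <- as.numeric(spec$mu %||% NA)
  if (!is.finite(mu) || mu <= 0) stop("mu must be a positive mutation rate")

  fp <- if (length(spec$free_params)) {
    do.call(rbind, lapply(spec$free_params, function(f)
      data.frame(name = as.character(f$name),
                 targets = as.character(f$targets),
                 lower = as.numeric(f$lower), upper = as.numeric(f$upper),
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(name = character(), targets = character(),
               lower = numeric(), upper = numeric(), stringsAsFactors = FALSE)
  }
  if (nrow(fp)) {
    if (any(!nzchar(fp$targets)))
      stop("every free parameter must be bound to at least one model slot")
    if (any(fp$lower <= 0 | fp$upper <= fp$lower))
      stop("free parameter bounds must satisfy 0 < lower < upper")
  }

  oc <- if (length(spec$order_constraints)) {
    do.call(rbind, lapply(spec$order_constraints, function(x)
      data.frame(earlier = as.integer(x$earlier), later = as.integer(x$later))))
  } else data.frame(earlier = integer(), later = integer())

  model <- new("DemographicModel",
               id = as.character(spec$id %||% "model"),
               populations = pops, events = events, migration = migration,
               mu = mu, freeParams = fp, orderConstraints = oc)
  # verify every free-parameter target resolves
  if (nrow(fp)) getModelParams(model)
  model
}

## ---- free-parameter plumbing ------------------------------------------------

parseTarget <- function(target) {
  parts <- strsplit(target, ":", fixed = TRUE)[[1]]
  list(kind = parts[1], a = parts[2], b = if (length(parts) > 2) parts[3])
}

#' Read current values of a model's free parameters
#'
#' @param model a [DemographicModel-class].
#' @return named numeric vector (value of the first target of each parameter).
#' @export
getModelParams <- function(model) {
  fp <- model@freeParams
  vals <- vapply(seq_len(nrow(fp)), function(i) {
    tg <- parseTarget(strsplit(fp$targets[i], ";", fixed = TRUE)[[1]][1])
    switch(tg$kind,
      time = model@events$time[as.integer(tg$a)],
      size = model@events$new_size[as.integer(tg$a)],
      N = model@populations$N_current[match(tg$a, model@populations$name)],
      mig = model@migration$rates[tg$a, tg$b],
      stop(sprintf("unknown target kind '%s'", tg$kind)))
  }, numeric(1))
  if (anyNA(vals)) stop("a free-parameter target did not resolve")
  setNames(vals, fp$name)
}

#' Write values into a model's free-parameter slots
#'
#' Events are re-sorted by time afterwards (target indices refer to the
#' pre-assignment event order; all targets are resolved before sorting).
#'
#' @param model a [DemographicModel-class].
#' @param values named numeric vector; names must match free-parameter names.
#' @param check validate topology afterwards (set `FALSE` inside optimizers
#'   that handle invalid proposals themselves).
#' @return the updated model.
#' @export
setModelParams <- function(model, values, check = TRUE) {
  fp <- model@freeParams
  bad <- setdiff(names(values), fp$name)
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  for (nm in names(values)) {
    i <- match(nm, fp$name)
    for (target in strsplit(fp$targets[i], ";", fixed = TRUE)[[1]]) {
      tg <- parseTarget(target)
      v <- as.numeric(values[[nm]])
      switch(tg$kind,
        time = { model@events$time[as.integer(tg$a)] <- v },
        size = { model@events$new_size[as.integer(tg$a)] <- v },
        N = { model@populations$N_current[
                match(tg$a, model@populations$name)] <- v },
        mig = { model@migration$rates[tg$a, tg$b] <- v },
        stop(sprintf("unknown target kind '%s'", tg$kind)))
    }
  }
  if (check && !modelParamsValid(model))
    stop("parameter values yield an invalid model (topology or ordering)")
  model
}

# TRUE iff the model's current parameter values give a legal history:
# topology replay succeeds and declared order constraints hold.
# (Event order targets are positional, so events are NOT resorted here;
# the engine sorts by time itself.)
modelParamsValid <- function(model) {
  oc <- model@orderConstraints
  if (nrow(oc) &&
      any(model@events$time[oc$earlier] > model@events$time[oc$later]))
    return(FALSE)
  isTRUE(checkTopology(model@populations, model@events, stopOnError = FALSE))
}

## ---- YAML serialization -----------------------------------------------------

#' Read or write a model config in YAML
#'
#' The YAML layout mirrors the list accepted by [buildModel()]; a written
#' file read back yields an identical model.  Migration is serialized as
#' forward-in-time fractions (`rates[i][j]` = fraction of deme j founded per
#' generation by migrants from deme i); the engine converts these to backward
#' lineage-movement probabilities internally (for this parameterization the
#' two coincide: the probability that a lineage in j had its parent in i is
#' exactly the founding fraction).
#'
#' @param path file path.
#' @return [readModelYAML()] returns a [DemographicModel-class].
#' @export
readModelYAML <- function(path) {
  buildModel(yaml::read_yaml(path))
}

#' @param model a [DemographicModel-class].
#' @rdname readModelYAML
#' @export
writeModelYAML <- function(model, path) {
  spec <- list(
    id = model@id,
    populations = lapply(seq_len(nrow(model@populations)), function(i)
      as.list(model@populations[i, ])),
    events = lapply(seq_len(nrow(model@events)), function(i) {
      e <- as.list(model@events[i, ])
      if (is.na(e$sink)) e$sink <- NULL
      if (is.na(e$new_size)) e$new_size <- NULL
      e
    }),
    mu = model@mu)
  if (length(model@migration)) {
    r <- model@migration$rates
    entries <- list()
    for (i in rownames(r)) for (j in colnames(r))
      if (r[i, j] > 0)
        entries[[length(entries) + 1L]] <-
          list(from = i, to = j, rate = r[i, j])
    spec$migration <- list(t_end = model@migration$t_end, rates = entries)
  }
  if (nrow(model@freeParams))
    spec$free_params <- lapply(seq_len(nrow(model@freeParams)), function(i)
      as.list(model@freeParams[i, ]))
  if (nrow(model@orderConstraints))
    spec$order_constraints <-
      lapply(seq_len(nrow(model@orderConstraints)), function(i)
        as.list(model@orderConstraints[i, ]))
  yaml::write_yaml(spec, path)
  invisible(path)
}

## ---- candidate enumeration --------------------------------------------------

#' Enumerate rooted divergence orderings of a taxon set
#'
#' A candidate is a backward-in-time sequence of merge events; each event
#' joins two or more extant lineages into one, and a single multi-lineage
#' merge models simultaneous divergence (a hard polytomy).  For three
#' unconstrained taxa this yields 4 candidates: the 3 strictly ordered rooted
#' histories plus the simultaneous trichotomy.
#'
#' Constraints are clades that must appear (winners of previous, smaller
#' analyses); constraints are intersected with `taxa` and those leaving fewer
#' than two taxa are ignored.  A constraint naming a taxon absent everywhere
#' is an error.
#'
#' @param taxa character vector of 2..6 labels.
#' @param constraints list of character vectors (required clades).
#' @param allTaxa the universe of known taxon labels (defaults to `taxa`);
#'   a stepwise driver passes the union over all steps so that constraints
#'   won at earlier steps may mention taxa outside the current subset.
#' @return list of candidates; each has `id` (stable identifier), `merges`
#'   (list of merged lineage-representative sets, most recent first) and
#'   `clades` (the taxon sets created by each merge).
#' @export
enumerateCandidates <- function(taxa, constraints = list(), allTaxa = taxa) {
  taxa <- as.character(taxa)
  if (length(taxa) < 2 || length(taxa) > 6)
    stop("between 2 and 6 taxa supported")
  for (cs in constraints) {
    unknown <- setdiff(cs, allTaxa)
    if (length(unknown))
      stop("constraint references unknown taxa: ",
           paste(unknown, collapse = ", "))
  }

  results <- list()
  recurse <- function(lineages, merges) {
    # lineages: named list rep -> taxon set
    if (length(lineages) == 1L) {
      reps <- lapply(merges, function(m) m$reps)
      clades <- lapply(merges, function(m) m$clade)
      id <- paste(vapply(reps, function(r) paste(sort(r), collapse = "+"),
                         character(1)), collapse = ";")
      results[[length(results) + 1L]] <<-
        list(id = id, merges = reps, clades = clades)
      return(invisible())
    }
    reps <- sort(names(lineages))
    n <- length(reps)
    for (k in 2:n) {
      for (sel in utils::combn(reps, k, simplify = FALSE)) {
        clade <- sort(unlist(lineages[sel], use.names = FALSE))
        keep <- lineages[setdiff(reps, sel)]
        keep[[min(sel)]] <- clade
        recurse(keep, c(merges, list(list(reps = sel, clade = clade))))
      }
    }
  }
  recurse(setNames(as.list(taxa), taxa), list())

  cons <- Filter(function(s) length(s) >= 2,
                 lapply(constraints, function(cs) sort(intersect(cs, taxa))))
  if (length(cons)) {
    ok <- vapply(results, function(cand) {
      all(vapply(cons, function(cl) {
        any(vapply(cand$clades, function(x) identical(x, cl), logical(1))) ||
          identical(cl, sort(taxa))
      }, logical(1)))
    }, logical(1))
    results <- results[ok]
  }
  results
}

#' Materialize a candidate divergence ordering as a demographic model
#'
#' Each merge event becomes one free divergence-time parameter; a
#' multi-lineage merge becomes tied divergence events sharing one time
#' parameter.  Event times of successive merges carry explicit ordering
#' constraints so the fitted history keeps the candidate's topology.
#'
#' @param candidate one element of [enumerateCandidates()].
#' @param populations data.frame as in [DemographicModel-class] (rows for the
#'   candidate's taxa are used).
#' @param mu mutation rate.
#' @param timeBounds length-2 search bounds (generations) for the divergence
#'   times (default `c(1e2, 1e5)`).
#' @param startTimes optional initial event times (one per merge, most recent
#'   first; defaults to a geometric ladder inside the bounds).
#' @return a [DemographicModel-class].
#' @export
candidateToModel <- function(candidate, populations, mu,
                             timeBounds = c(1e2, 1e5), startTimes = NULL) {
  merges <- candidate$merges
  nm <- length(merges)
  if (is.null(startTimes))
    startTimes <- exp(seq(log(timeBounds[1] * 4), log(timeBounds[2] / 4),
                          length.out = max(nm, 2)))[seq_len(nm)]
  events <- list()
  fp <- list()
  evOfMerge <- integer(nm)
  for (m in seq_len(nm)) {
    reps <- sort(merges[[m]])
    sink <- reps[1]
    for (src in reps[-1])
      events[[length(events) + 1L]] <-
        list(time = startTimes[m], kind = "divergence",
             source = src, sink = sink)
    first <- length(events) - (length(reps) - 2L)
    evOfMerge[m] <- first
    fp[[m]] <- list(name = sprintf("T_%d", m),
                    targets = paste(sprintf("time:%d", first:length(events)),
                                    collapse = ";"),
                    lower = timeBounds[1], upper = timeBounds[2])
  }
  oc <- if (nm > 1)
    lapply(seq_len(nm - 1), function(m)
      list(earlier = evOfMerge[m], later = evOfMerge[m + 1]))
  else list()
  taxa <- sort(unique(unlist(merges)))
  pops <- populations[populations$name %in% taxa, , drop = FALSE]
  buildModel(list(id = candidate$id,
                  populations = lapply(seq_len(nrow(pops)), function(i)
                    as.list(pops[i, ])),
                  events = events, mu = mu, free_params = fp,
                  order_constraints = oc))
}
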