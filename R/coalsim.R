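#' @include models.R
NULL

# Lower a DemographicModel to the flat representation the C++ engine takes.
# Events are sorted by time; migration is passed as the matrix of
# backward lineage-movement probabilities, which for the forward "founding
# fraction" parameterization equals the forward matrix itself.
lowerModel <- function(model) {
  pops <- model@populations
  ev <- model@events[order(model@events$time), , drop = FALSE]
  idx <- function(nm) match(nm, pops$name) - 1L
  out <- list(
    N = pops$N_current,
    evTime = ev$time,
    evKind = ifelse(ev$kind == "divergence", 0L, 1L),
    evA = idx(ev$source),
    evB = ifelse(ev$kind == "divergence", idx(ev$sink), 0L),
    evSize = ifelse(is.na(ev$new_size), 0, ev$new_size))
  if (length(model@migration)) {
    out$mig <- unname(model@migration$rates[pops$name, pops$name])
    out$migEnd <- model@migration$t_end
  } else {
    out$mig <- NULL
  }
  out
}

#' Simulate biallelic SNP genotypes under a demographic model
#'
#' Backward-in-time coalescent simulation with independent per-site
#' genealogies (no linkage, matching SFS-only inference).  Mutation is
#' infinite-sites with opportunity `mu * locusLength` per branch generation;
#' by default at most one SNP is retained per simulated locus (multi-hit loci
#' contribute their first mutation), matching one-SNP-per-locus RAD
#' conventions.  Loci with no mutation are emitted as monomorphic site
#' records (`is_variable = FALSE`).  Diploids are formed by pairing
#' consecutive haplotypes within each deme (Hardy-Weinberg implied).
#'
#' @param model a [DemographicModel-class]; sample sizes are the populations'
#'   `n_diploid`.
#' @param nSites number of independent loci to simulate.
#' @param locusLength mutation opportunity in bp per locus (default 51, a
#'   short single-end RAD read).
#' @param seed integer seed (same seed, same model gives a byte-identical
#'   result) or `NULL` to use the current RNG state.
#' @param oneSnpPerLocus retain at most the first mutation per locus
#'   (default); `FALSE` emits one site record per mutation.
#' @return a [GenotypeMatrix-class].
#' @export
simulateGenotypes <- function(model, nSites, locusLength = 51, seed = NULL,
                              oneSnpPerLocus = TRUE) {
  stopifnot(is(model, "DemographicModel"))
  if (nSites < 1) stop("nSites must be >= 1")
  pops <- model@populations
  if (!nrow(pops) || sum(pops$n_diploid) < 1)
    stop("model has zero sampled demes")
  theta <- model@mu * locusLength
  sampleN <- as.integer(2L * pops$n_diploid)
  sim <- withSeed(seed,
    .cpp_simulate_haplotypes(lowerModel(model), sampleN, as.integer(nSites),
                             theta, isTRUE(oneSnpPerLocus)))
  H <- sim$haplotypes
  # pair consecutive haplotypes within demes into diploid genotypes
  odd <- seq(1L, ncol(H), by = 2L)
  G <- H[, odd, drop = FALSE] + H[, odd + 1L, drop = FALSE]
  ids <- unlist(lapply(seq_len(nrow(pops)), function(i)
    sprintf("%s_%02d", pops$name[i], seq_len(pops$n_diploid[i]))))
  individuals <- data.frame(
    id = ids,
    population = rep(pops$name, pops$n_diploid),
    stringsAsFactors = FALSE)
  sites <- data.frame(
    chrom = sprintf("locus_%d", sim$locus),
    pos = 1L + (sequence(rle(sim$locus)$lengths) - 1L),
    ref = "A", alt = "T",
    is_variable = sim$is_variable == 1L,
    stringsAsFactors = FALSE)
  GenotypeMatrix(G, sites, individuals)
}

#' Expected folded SFS under a model, by Monte-Carlo simulation
#'
#' Estimates the per-site probability table over folded minor-allele SFS
#' cells (including the monomorphic cell) for one population pair, or the 1D
#' folded spectrum when a single population is named.  The estimator is
#' Rao-Blackwellized over mutation placement: each simulated genealogy
#' contributes `exp(-theta T)` to the monomorphic cell and
#' `(1 - exp(-theta T)) * L_c / T` to cell c, where `L_c` is the total branch
#' length subtending configuration c.  Entries therefore sum to 1 exactly,
#' and the table is folded exactly as [build2dMSFS()] folds observed data.
#'
#' @param model a [DemographicModel-class].
#' @param pair one or two population labels.
#' @param nSims number of simulated genealogies.
#' @param seed integer seed or `NULL`.
#' @param locusLength mutation opportunity in bp (default 51).
#' @return probability matrix, `(n1+1) x (n2+1)` (or `(n+1) x 1` for 1D).
#' @export
expectedSFS <- function(model, pair, nSims = 100000, seed = NULL,
                        locusLength = 51) {
  stopifnot(is(model, "DemographicModel"))
  pops <- model@populations
  unknown <- setdiff(pair, pops$name)
  if (length(unknown))
    stop("unknown deme(s): ", paste(unknown, collapse = ", "))
  if (!length(pair) %in% 1:2 || anyDuplicated(pair))
    stop("pair must name one or two distinct populations")
  sampleN <- integer(nrow(pops))
  sampleN[match(pair, pops$name)] <- 2L * pops$n_diploid[match(pair, pops$name)]
  pairIdx <- matrix(c(match(pair[1], pops$name) - 1L,
                      if (length(pair) == 2) match(pair[2], pops$name) - 1L
                      else -1L), nrow = 2)
  out <- withSeed(seed,
    .cpp_expected_sfs(lowerModel(model), sampleN, as.integer(nSims),
                      model@mu * locusLength, pairIdx))[[1]]
  dimnames(out) <- list(0:(nrow(out) - 1L), 0:(ncol(out) - 1L))
  out
}

#' Expected folded 2D spectra for many pairs from shared genealogies
#'
#' Samples every deme at its full haploid size once per simulation and
#' projects all requested pairwise spectra from the same genealogies — the
#' efficient evaluation mode used inside [ecmFit()].
#'
#' @param model a [DemographicModel-class].
#' @param pairs list of character(2) pairs; `NULL` means all unordered pairs.
#' @param nSims simulations.
#' @param seed integer seed or `NULL`.
#' @param locusLength mutation opportunity in bp.
#' @return named list (`"A|B"`) of probability matrices.
#' @export
expectedSFSAll <- function(model, pairs = NULL, nSims = 100000, seed = NULL,
                           locusLength = 51) {
  pops <- model@populations
  if (is.null(pairs))
    pairs <- utils::combn(pops$name, 2, simplify = FALSE)
  sampleN <- as.integer(2L * pops$n_diploid)
  pairIdx <- vapply(pairs, function(p) match(p, pops$name) - 1L, integer(2))
  if (anyNA(pairIdx)) stop("pair contains an unknown deme")
  out <- withSeed(seed,
    .cpp_expected_sfs(lowerModel(model), sampleN, as.integer(nSims),
                      model@mu * locusLength, pairIdx))
  out <- lapply(out, function(m) {
    dimnames(m) <- list(0:(nrow(m) - 1L), 0:(ncol(m) - 1L)); m
  })
  names(out) <- vapply(pairs, function(p) pairKey(p[1], p[2]), character(1))
  out
}

#' Set genotypes to missing at random
#'
#' Emulates RAD-style per-genotype missingness: each genotype call is
#' independently replaced by `NA` with the given probability.
#'
#' @param g a [GenotypeMatrix-class].
#' @param rate scalar missing probability, or a named vector giving one rate
#'   per population.
#' @param seed integer seed or `NULL`.
#' @return the thinned [GenotypeMatrix-class].
#' @export
applyMissingness <- function(g, rate, seed = NULL) {
  stopifnot(is(g, "GenotypeMatrix"))
  pop <- populations(g)
  rates <- if (length(rate) == 1L && is.null(names(rate)))
    rep(as.numeric(rate), ncol(g))
  else {
    if (!all(pop %in% names(rate)))
      stop("per-population rates must cover every population")
    as.numeric(rate[pop])
  }
  if (any(rates < 0 | rates > 1)) stop("rate must be in [0, 1]")
  G <- genotypes(g)
  drop <- withSeed(seed, {
    m <- matrix(runif(length(G)), nrow(G), ncol(G))
    sweep(m, 2, rates, `<`)
  })
  G[drop] <- NA_integer_
  out <- g
  SummarizedExperiment::assay(out, "GT") <- G
  out
}
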