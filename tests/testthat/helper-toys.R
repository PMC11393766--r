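# Small fixture builders and independent oracles shared across the suite.

MU <- 1.74e-8

singleDemeModel <- function(n_diploid = 3, N = 10000) {
  buildModel(list(
    id = "single",
    populations = list(list(name = "A", island_group = "X",
                            n_diploid = n_diploid, N_current = N)),
    events = list(), mu = MU))
}

twoDemeModel <- function(T_split = 2000, N = 5000, n_diploid = 5,
                         migRate = 0, migEnd = 0) {
  spec <- list(
    id = "two",
    populations = list(
      list(name = "A", island_group = "X", n_diploid = n_diploid, N_current = N),
      list(name = "B", island_group = "X", n_diploid = n_diploid, N_current = N)),
    events = list(list(time = T_split, kind = "divergence",
                       source = "B", sink = "A")),
    mu = MU,
    free_params = list(list(name = "T_split", targets = "time:1",
                            lower = 100, upper = 1e5)))
  if (migRate > 0)
    spec$migration <- list(t_end = migEnd, rates = list(
      list(from = "A", to = "B", rate = migRate),
      list(from = "B", to = "A", rate = migRate)))
  buildModel(spec)
}

threeTaxonModel <- function(tAB = 1500, tRoot = 6000, N = 5000, n_diploid = 3) {
  buildModel(list(
    id = "three",
    populations = list(
      list(name = "A", island_group = "X", n_diploid = n_diploid, N_current = N),
      list(name = "B", island_group = "X", n_diploid = n_diploid, N_current = N),
      list(name = "C", island_group = "X", n_diploid = n_diploid, N_current = N)),
    events = list(
      list(time = tAB, kind = "divergence", source = "B", sink = "A"),
      list(time = tRoot, kind = "divergence", source = "C", sink = "A")),
    mu = MU))
}

# random genotype fixture with two populations
randomGenotypeMatrix <- function(nSites = 20, nDip = c(A = 3, B = 3),
                                 missingRate = 0, seed = 42) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    n <- sum(nDip)
    G <- matrix(sample(0:2, nSites * n, replace = TRUE,
                       prob = c(0.6, 0.25, 0.15)), nSites, n)
    if (missingRate > 0)
      G[matrix(runif(length(G)) < missingRate, nSites, n)] <- NA_integer_
    GenotypeMatrix(
      G,
      sites = data.frame(chrom = sprintf("locus_%d", seq_len(nSites)),
                         pos = 1L, ref = "A", alt = "T",
                         is_variable = TRUE),
      individuals = data.frame(
        id = sprintf("%s_%d", rep(names(nDip), nDip),
                     unlist(lapply(nDip, seq_len))),
        population = rep(names(nDip), nDip)))
  })
}

# Brute-force per-site recount of the folded 2D-mSFS (complete data only):
# independent of the vectorized implementation.
bruteForce2dMSFS <- function(g, popA, popB) {
  G <- genotypes(g)
  pop <- populations(g)
  GA <- G[, pop == popA, drop = FALSE]
  GB <- G[, pop == popB, drop = FALSE]
  nA <- 2L * ncol(GA); nB <- 2L * ncol(GB)
  counts <- matrix(0L, nA + 1L, nB + 1L)
  for (s in seq_len(nrow(G))) {
    iA <- sum(GA[s, ]); iB <- sum(GB[s, ])
    if (2 * (iA + iB) > nA + nB) { iA <- nA - iA; iB <- nB - iB }
    counts[iA + 1L, iB + 1L] <- counts[iA + 1L, iB + 1L] + 1L
  }
  counts
}

# Independent count of rooted divergence orderings with simultaneous merges:
# a(1) = 1; a(n) = sum_{k=2..n} choose(n, k) * a(n - k + 1).
countOrderings <- function(n) {
  if (n == 1) return(1)
  sum(vapply(2:n, function(k) choose(n, k) * countOrderings(n - k + 1),
             numeric(1)))
}

# analytic folded neutral SFS proportions for a constant-size deme
analyticFolded <- function(n) {
  i <- seq_len(floor(n / 2))
  w <- (1 / i + 1 / (n - i)) / (1 + (i == n - i))
  w / sum(w)
}
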