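test_that("simulation is deterministic and the genotype contract holds", {
  m <- twoDemeModel()
  g1 <- simulateGenotypes(m, 200, seed = 7)
  g2 <- simulateGenotypes(m, 200, seed = 7)
  expect_identical(genotypes(g1), genotypes(g2))
  expect_identical(siteInfo(g1), siteInfo(g2))
  g3 <- simulateGenotypes(m, 200, seed = 8)
  expect_false(identical(genotypes(g1), genotypes(g3)))
  expect_true(all(genotypes(g1) %in% 0:2))
  expect_equal(populations(g1), rep(c("A", "B"), each = 5))
  # monomorphic loci are present and flagged
  expect_true(any(!siteInfo(g1)$is_variable))
  expect_true(all(rowSums(genotypes(g1)[!siteInfo(g1)$is_variable, ]) == 0))
})

test_that("mean segregating sites match Watterson's expectation", {
  # theta per locus = 6 so that E[S] = theta * (1 + 1/2 + 1/3) = 11 for n = 4
  m <- singleDemeModel(n_diploid = 2, N = 10000)
  L <- 6 / (4 * 10000 * MU)
  g <- simulateGenotypes(m, 200, locusLength = L, seed = 99,
                         oneSnpPerLocus = FALSE)
  S <- tapply(siteInfo(g)$is_variable, siteInfo(g)$chrom, sum)
  se <- sqrt((6 * sum(1 / (1:3)) + 36 * sum(1 / (1:3)^2)) / 200)
  expect_lt(abs(mean(S) - 11), 3 * se)
})

test_that("the expected folded SFS of a constant-size deme is neutral-analytic", {
  m <- singleDemeModel(n_diploid = 3, N = 10000)
  sfs <- expectedSFS(m, "A", nSims = 100000, seed = 5)
  expect_equal(sum(sfs), 1)
  poly <- sfs[2:4, 1] / sum(sfs[2:4, 1])
  expect_lt(max(abs(poly - analyticFolded(6))), 0.01)
})

test_that("expected spectra are normalized, symmetric and properly folded", {
  m <- twoDemeModel(T_split = 3000, migRate = 1e-4, migEnd = 1000)
  p <- expectedSFS(m, c("A", "B"), nSims = 30000, seed = 3)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # exchange symmetry of a fully symmetric two-deme model
  expect_lt(max(abs(p - t(p))), 4e-3)
  # all cells beyond the pooled-minor fold are structurally empty
  i <- row(p) - 1L; j <- col(p) - 1L
  expect_true(all(p[2 * (i + j) > 20] == 0))
  # monomorphic cell present
  expect_gt(p[1, 1], 0)
})

test_that("a divergence at time zero behaves as a single panmictic deme", {
  m0 <- twoDemeModel(T_split = 0, N = 8000, n_diploid = 3)
  p2 <- expectedSFS(m0, c("A", "B"), nSims = 80000, seed = 21)
  # project the pair spectrum onto pooled minor-allele counts
  pooled <- tapply(as.vector(p2), as.vector(row(p2) + col(p2) - 2L), sum)
  m1 <- singleDemeModel(n_diploid = 6, N = 8000)
  p1 <- expectedSFS(m1, "A", nSims = 80000, seed = 22)[, 1]
  expect_length(pooled, length(p1))
  expect_lt(max(abs(pooled - p1)), 4e-3)
})

test_that("older divergence shifts mass into fixed-difference cells", {
  sfsAt <- function(T_split)
    expectedSFS(twoDemeModel(T_split = T_split, n_diploid = 3),
                c("A", "B"), nSims = 30000, seed = 11)
  fixedMass <- function(p) p[7, 1] + p[1, 7]  # (6,0) and (0,6) cells
  expect_gt(fixedMass(sfsAt(20000)), fixedMass(sfsAt(2000)))
})

test_that("likelihood differences are smooth under common random numbers", {
  m <- twoDemeModel(T_split = 2000)
  obs <- simulateSFSData(m, 2000, seed = 31)
  ll <- function(T_split, seed) {
    m2 <- setModelParams(m, c(T_split = T_split))
    compositeLogLik(obs, expectedSFSAll(m2, nSims = 3000, seed = seed))
  }
  seeds <- 1:12
  a <- vapply(seeds, function(s) ll(2000, s), numeric(1))
  # paired (same-seed) likelihood differences vary much less than
  # independent-seed differences, and the pairing benefit grows as the
  # perturbation shrinks
  for (pert in c(2002, 2010)) {
    b <- vapply(seeds, function(s) ll(pert, s), numeric(1))
    b2 <- vapply(seeds, function(s) ll(pert, 100 + s), numeric(1))
    expect_lt(sd(a - b), 0.8 * sd(a - b2))
  }
})

test_that("missingness thinning is exact at the extremes and binomial between", {
  g <- simulateGenotypes(twoDemeModel(), 1000, seed = 13)
  expect_identical(genotypes(applyMissingness(g, 0, seed = 1)), genotypes(g))
  expect_true(all(is.na(genotypes(applyMissingness(g, 1, seed = 1)))))
  gm <- applyMissingness(g, 0.2, seed = 2)
  nMiss <- sum(is.na(genotypes(gm)))
  n <- length(genotypes(gm))
  expect_true(abs(nMiss - 0.2 * n) < 2.58 * sqrt(n * 0.2 * 0.8))
  # per-population rates
  gp <- applyMissingness(g, c(A = 0, B = 1), seed = 3)
  G <- genotypes(gp)
  expect_true(all(!is.na(G[, populations(gp) == "A"])))
  expect_true(all(is.na(G[, populations(gp) == "B"])))
  expect_error(applyMissingness(g, 1.5), "rate")
})

test_that("unknown demes and empty models are rejected", {
  m <- twoDemeModel()
  expect_error(expectedSFS(m, c("A", "Z"), nSims = 10), "unknown")
  expect_error(expectedSFS(m, c("A", "A"), nSims = 10), "distinct")
  expect_error(simulateGenotypes(m, 0), "nSites")
})
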