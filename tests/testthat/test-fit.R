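sfsFromCounts <- function(counts, pair = c("A", "B")) {
  SFS2D(pair, nrow(counts) - 1L, ncol(counts) - 1L, counts)
}

test_that("the composite log likelihood evaluates its closed form", {
  # two occupied cells, counts (2, 2), probabilities (1/2, 1/2)
  obs <- sfsFromCounts(matrix(c(2, 2, 0, 0), 2, 2))
  p <- matrix(c(0.5, 0.5, 0, 0), 2, 2)
  expect_equal(compositeLogLik(obs, p), 4 * log(0.5), tolerance = 1e-12)
  expect_equal(compositeLogLik(obs, p), -2.772589, tolerance = 1e-6)
  # zero simulated probability with a positive count: the floor applies
  obs2 <- sfsFromCounts(matrix(c(0, 3, 0, 0), 2, 2))
  p2 <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(compositeLogLik(obs2, p2, minProb = 1e-8), 3 * log(1e-8))
  # pairs combine by summation
  expect_equal(compositeLogLik(list(a = obs, b = obs), list(a = p, b = p)),
               8 * log(0.5))
  expect_error(compositeLogLik(obs, matrix(0.25, 3, 3)), "shape")
})

test_that("observed proportions maximize the likelihood (Gibbs inequality)", {
  set.seed(8)
  counts <- matrix(rpois(16, 5), 4, 4)
  counts[2 * (row(counts) + col(counts) - 2) > 6] <- 0
  obs <- sfsFromCounts(counts)
  pHat <- counts / sum(counts)
  llHat <- compositeLogLik(obs, pHat)
  for (r in 1:200) {
    q <- matrix(rexp(16), 4, 4)
    q <- q / sum(q)
    expect_gte(llHat, compositeLogLik(obs, q))
  }
})

test_that("AIC bookkeeping and best-model selection follow the stated rules", {
  fr <- function(id, lnL, k) new("FitResult", modelId = id,
                                 params = setNames(rep(1, k), paste0("p", seq_len(k))),
                                 lnL = lnL, k = as.integer(k),
                                 AIC = 2 * k - 2 * lnL, trace = lnL,
                                 converged = TRUE)
  expect_equal(fr("x", -100, 5)@AIC, 210)
  # AIC identity is enforced by the class validity
  expect_error(new("FitResult", modelId = "bad", params = c(a = 1),
                   lnL = -100, k = 1L, AIC = 1, trace = -100,
                   converged = TRUE), "AIC")
  sel <- selectBest(list(fr("m1", -100, 5), fr("m2", -102.5, 5)))
  expect_equal(sel$best@modelId, "m1")
  expect_equal(sel$table$dAIC, c(0, 5))
  # exact tie: fewer parameters wins; equal k: lexicographic id
  sel2 <- selectBest(list(fr("big", -99, 6), fr("small", -100, 5)))
  expect_equal(sel2$best@modelId, "small")
  sel3 <- selectBest(list(fr("zeta", -100, 5), fr("alpha", -100, 5)))
  expect_equal(sel3$best@modelId, "alpha")
  # invariant to input order
  fits <- list(fr("a", -101, 2), fr("b", -100, 2), fr("c", -99.5, 3))
  perm <- selectBest(rev(fits))
  expect_equal(perm$table, selectBest(fits)$table)
  expect_error(selectBest(list()), "no fits")
})

test_that("ECM is monotone under global common random numbers and deterministic", {
  m <- twoDemeModel(T_split = 2000)
  obs <- simulateSFSData(m, 1500, seed = 41)
  sch <- FitSchedule(nStarts = 1, nCycles = 6, nSims = 1500, seed = 5)
  fit <- ecmFit(m, obs, schedule = sch, crn = "global")
  expect_true(all(diff(fit@trace) >= 0))
  fit2 <- ecmFit(m, obs, schedule = sch, crn = "global")
  expect_identical(fittedParams(fit2), fittedParams(fit))
  expect_identical(fit2@trace, fit@trace)
  expect_equal(fit@AIC, 2 * fit@k - 2 * fit@lnL)
})

test_that("a model with no searched parameters returns an evaluation-only fit", {
  m <- twoDemeModel(T_split = 2000)
  obs <- simulateSFSData(m, 500, seed = 43)
  fit <- ecmFit(m, obs, schedule = FitSchedule(1, 1, 500, seed = 2),
                free = character(0))
  expect_equal(fit@k, 0L)
  expect_length(fittedParams(fit), 0L)
  expect_true(fit@converged)
  expect_equal(fit@AIC, -2 * fit@lnL)
})

test_that("the two-deme divergence time is recovered across seeded runs", {
  hits <- 0L
  for (s in 1:10) {
    m <- twoDemeModel(T_split = 2000)
    obs <- simulateSFSData(m, 4000, seed = 100 + s)
    fit <- ecmFit(m, obs,
                  schedule = FitSchedule(nStarts = 3, nCycles = 10,
                                         nSims = 5000, seed = 200 + s))
    if (abs(fittedParams(fit)[["T_split"]] - 2000) / 2000 < 0.15)
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("stepwise search recovers a known three-taxon divergence order", {
  pops <- data.frame(name = c("A", "B", "C"), island_group = "X",
                     n_diploid = 3, N_current = 5000)
  wins <- 0L
  for (s in 1:10) {
    truth <- threeTaxonModel(tAB = 1500, tRoot = 8000)
    obs <- simulateSFSData(truth, 4000, seed = 300 + s)
    sw <- stepwiseSearch(list(c("A", "B", "C")), obs,
                         schedule = FitSchedule(nStarts = 1, nCycles = 4,
                                                nSims = 1000, seed = 400 + s),
                         populations = pops, mu = MU)
    if (sw$path[[1]]$winner == "A+B;A+C") wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("stepwise bookkeeping: degenerate steps and path length", {
  pops <- data.frame(name = c("A", "B"), island_group = "X",
                     n_diploid = 3, N_current = 5000)
  truth <- twoDemeModel(T_split = 3000, n_diploid = 3)
  obs <- simulateSFSData(truth, 800, seed = 51)
  sw <- stepwiseSearch(list(c("A", "B")), obs,
                       schedule = FitSchedule(1, 2, 500, seed = 6),
                       populations = pops, mu = MU)
  expect_length(sw$path, 1L)
  expect_equal(nrow(sw$path[[1]]$table), 1L)
  expect_equal(sw$path[[1]]$winner, "A+B")
  expect_error(
    stepwiseSearch(list(c("A", "Z")), obs,
                   schedule = FitSchedule(1, 1, 100, seed = 1),
                   populations = pops, mu = MU),
    "absent")
})

test_that("parametric bootstrap returns percentile intervals and drops failures", {
  m <- twoDemeModel(T_split = 2000)
  obs <- simulateSFSData(m, 2000, seed = 61)
  fit <- ecmFit(m, obs, schedule = FitSchedule(1, 5, 1500, seed = 62))
  bt <- parametricBootstrap(fit, m, obs,
                            schedule = FitSchedule(1, 3, 1500, seed = 1),
                            nReps = 12, seed = 63)
  expect_lte(nrow(bt@replicates) + bt@failures, 12L)
  ci <- bootstrapCI(bt)
  expect_equal(ci$param, "T_split")
  expect_true(ci$lower <= ci$upper)
  expect_true(ci$lower < 2000 * 1.5 && ci$upper > 2000 * 0.5)
  # a fit with no free parameters yields an empty interval set
  fit0 <- ecmFit(m, obs, schedule = FitSchedule(1, 1, 300, seed = 3),
                 free = character(0))
  bt0 <- parametricBootstrap(fit0, m, obs,
                             schedule = FitSchedule(1, 1, 300, seed = 4),
                             nReps = 3, seed = 5)
  expect_equal(nrow(bootstrapCI(bt0)), 0L)
})

test_that("goodness-of-fit residuals follow the Pearson form and calibrate", {
  # 3x3 folded table: mass only in cells with pooled count <= (n1+n2)/2
  p <- matrix(0, 3, 3)
  p[1, 1] <- 0.4; p[2, 1] <- 0.3; p[1, 2] <- 0.2; p[2, 2] <- 0.1
  counts <- 1000 * p                      # observed equals expectation
  obs <- sfsFromCounts(counts)
  gr <- gofResiduals(obs, p)
  expect_true(all(gr$residuals == 0))
  expect_equal(gr$aggregate, 0)
  # single-cell excess of +k: residual k / sqrt(E)
  counts2 <- counts; counts2[1, 1] <- counts2[1, 1] + 30
  gr2 <- gofResiduals(sfsFromCounts(counts2), p)
  E <- sum(counts2) * p[1, 1]
  expect_equal(gr2$residuals[1, 1], (counts2[1, 1] - E) / sqrt(E))
  # data simulated from the fitted model: aggregate within its null range
  set.seed(71)
  draw <- function() matrix(rmultinom(1, 1000, as.vector(p)), 3, 3)
  nullStats <- replicate(200, gofResiduals(sfsFromCounts(draw()), p)$aggregate)
  stat <- gofResiduals(sfsFromCounts(draw()), p)$aggregate
  expect_gte(stat, quantile(nullStats, 0.005) - 1e-9)
  expect_lte(stat, quantile(nullStats, 0.995) + 1e-9)
})
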