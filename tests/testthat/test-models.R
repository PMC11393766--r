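test_that("generation/year conversions are exact, invertible and scale-linear", {
  expect_equal(generationsToYears(34140), 170700)   # 170.7 kya at 5 yr/gen
  expect_equal(generationsToYears(0), 0)
  expect_equal(generationsToYears(1000, TimeScale(25)), 25000)
  set.seed(1)
  x <- runif(1000, 0, 1e6)
  expect_equal(yearsToGenerations(generationsToYears(x)), x)
  k <- 3.7
  expect_equal(generationsToYears(k * x), k * generationsToYears(x))
  expect_error(generationsToYears(-1), "non-negative")
  expect_error(yearsToGenerations(10, TimeScale(5)), NA)
  expect_error(TimeScale(-5), "positive")
})

test_that("buildModel validates topology, migration legality and bindings", {
  # degenerate single-population model: fine, no divergence events
  expect_s4_class(singleDemeModel(), "DemographicModel")

  # a divergence referencing a deme already merged at a more recent time
  bad <- list(
    id = "bad",
    populations = list(
      list(name = "A", island_group = "X", n_diploid = 2, N_current = 1000),
      list(name = "B", island_group = "X", n_diploid = 2, N_current = 1000),
      list(name = "C", island_group = "X", n_diploid = 2, N_current = 1000)),
    events = list(
      list(time = 100, kind = "divergence", source = "B", sink = "A"),
      list(time = 200, kind = "divergence", source = "C", sink = "B")),
    mu = MU)
  expect_error(buildModel(bad), "already merged")

  # model that strands two ancestral lineages
  bad2 <- bad
  bad2$events <- bad$events[1]
  expect_error(buildModel(bad2), "exactly one ancestral lineage")

  # cross-island-group migration is illegal
  bad3 <- list(
    id = "bad3",
    populations = list(
      list(name = "A", island_group = "X", n_diploid = 2, N_current = 1000),
      list(name = "B", island_group = "Y", n_diploid = 2, N_current = 1000)),
    events = list(list(time = 100, kind = "divergence",
                       source = "B", sink = "A")),
    migration = list(t_end = 50, rates = list(
      list(from = "A", to = "B", rate = 1e-4))),
    mu = MU)
  expect_error(buildModel(bad3), "island group")

  # free parameter bound to a nonexistent slot
  bad4 <- twoDemeModel()
  spec <- list(
    id = "bad4",
    populations = list(list(name = "A", island_group = "X",
                            n_diploid = 2, N_current = 1000)),
    events = list(),
    mu = MU,
    free_params = list(list(name = "Q", targets = "N:ZZZ",
                            lower = 1, upper = 10)))
  expect_error(buildModel(spec))
})

test_that("the published model catalog is structurally faithful", {
  e1 <- modelE1()
  expect_equal(sum(modelEvents(e1)$kind == "divergence"), 5L)
  expect_equal(nrow(populations(e1)), 6L)
  # oldest divergence is the ST split at 34,140 generations = 170.7 kya
  div <- modelEvents(e1)[modelEvents(e1)$kind == "divergence", ]
  expect_equal(max(div$time), 34140)
  expect_equal(div$source[which.max(div$time)], "ST")
  # the radiation window spans the printed 72.9-76.9 kya
  window <- sort(div$time)[1:4]
  expect_true(all(window >= yearsToGenerations(72900) &
                  window <= yearsToGenerations(76900)))

  g2 <- modelG2()
  expect_equal(sum(modelEvents(g2)$kind == "divergence"), 4L)
  pg <- getModelParams(g2)
  expect_equal(unname(pg["T2"]), 16280)  # 81.4 kya
  expect_equal(unname(pg["T3"]), 16460)  # 82.3 kya
  expect_equal(unname(pg["T1"]), 33760)  # 168.8 kya
  expect_equal(unname(pg["T_red"]), 7420)  # 37.1 kya

  # all catalog migrant numbers sit inside the published 0.020-0.511 range
  for (m in list(e1, g2)) {
    M <- migrantNumbers(m)$migrants_per_generation
    expect_true(all(M >= 0.020 & M <= 0.511))
  }
})

test_that("parameter get/set round-trips and rejects illegal histories", {
  m <- modelG2()
  p <- getModelParams(m)
  m2 <- setModelParams(m, p)
  expect_equal(getModelParams(m2), p)
  # moving the STm->ST split older than the ST->S root is an illegal history
  p2 <- p; p2["T3"] <- p[["T1"]] + 1000
  m3 <- setModelParams(m, p2, check = FALSE)
  expect_false(coalSFS:::modelParamsValid(m3))
  expect_error(setModelParams(m, p2), "invalid")
})

test_that("YAML model configs round-trip exactly and ship the catalog", {
  for (build in list(modelE1, modelG2)) {
    m <- build()
    path <- tempfile(fileext = ".yaml")
    writeModelYAML(m, path)
    m2 <- readModelYAML(path)
    expect_equal(getModelParams(m2), getModelParams(m))
    expect_equal(modelEvents(m2), modelEvents(m))
    expect_equal(populations(m2), populations(m))
    expect_equal(m2@migration, m@migration)
  }
  e1 <- readModelYAML(system.file("extdata", "e1.yaml", package = "coalSFS"))
  expect_equal(getModelParams(e1), getModelParams(modelE1()))
  g2 <- readModelYAML(system.file("extdata", "g2.yaml", package = "coalSFS"))
  expect_equal(getModelParams(g2), getModelParams(modelG2()))
})

test_that("candidate enumeration matches the combinatorial oracle", {
  expect_length(enumerateCandidates(c("A", "B")), 1L)
  # 3 strictly ordered rooted histories + the simultaneous trichotomy
  expect_length(enumerateCandidates(c("A", "B", "C")), 4L)
  for (n in 4:5) {
    cands <- enumerateCandidates(LETTERS[1:n])
    expect_length(cands, countOrderings(n))
    ids <- vapply(cands, `[[`, character(1), "id")
    expect_false(anyDuplicated(ids) > 0)
    # deterministic
    ids2 <- vapply(enumerateCandidates(LETTERS[1:n]), `[[`,
                   character(1), "id")
    expect_identical(ids, ids2)
  }
  # constraining {A,B} as a clade strictly shrinks the 4-taxon set
  con <- enumerateCandidates(LETTERS[1:4], constraints = list(c("A", "B")))
  expect_lt(length(con), countOrderings(4))
  expect_true(all(vapply(con, function(cand)
    any(vapply(cand$clades, identical, logical(1), c("A", "B"))),
    logical(1))))
  expect_error(enumerateCandidates(c("A", "B"), constraints = list(c("A", "Z"))),
               "unknown")
})

test_that("candidate models enforce their divergence-time ordering", {
  cands <- enumerateCandidates(c("A", "B", "C"))
  pops <- data.frame(name = c("A", "B", "C"), island_group = "X",
                     n_diploid = 3, N_current = 5000)
  strict <- Filter(function(cand) length(cand$merges) == 2, cands)[[1]]
  m <- candidateToModel(strict, pops, MU)
  expect_equal(nrow(freeParams(m)), 2L)
  p <- getModelParams(m)
  flipped <- setNames(rev(unname(p)), names(p))
  expect_false(coalSFS:::modelParamsValid(
    setModelParams(m, flipped, check = FALSE)))
  # the trichotomy gets a single tied time parameter
  poly <- Filter(function(cand) length(cand$merges) == 1, cands)[[1]]
  mp <- candidateToModel(poly, pops, MU)
  expect_equal(nrow(freeParams(mp)), 1L)
  expect_equal(sum(modelEvents(mp)$kind == "divergence"), 2L)
})
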