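# hand-built 5-site fixture: two populations of 3 diploids, one site failing
# each filter rule and two passing (worked through by hand below)
fiveSiteFixture <- function() {
  G <- rbind(
    c(1, 1, 1, 1, 1, 1),     # s1: obs het 6/6 = 1.0   -> fails max_obs_het
    c(0, 0, 0, 0, 0, 0),     # s2: minor-allele count 0 -> fails min_mac 1
    c(0, 1, 0, NA, NA, 2),   # s3: pop B genotyped 1/3  -> fails -r 0.8
    c(0, 0, 1, 0, 0, 0),     # s4: passes all rules (mac 1, het 1/6)
    c(2, 1, 0, 0, 1, 0))     # s5: passes all rules (mac 4, het 2/6)
  GenotypeMatrix(
    G,
    sites = data.frame(chrom = sprintf("s%d", 1:5), pos = 1L,
                       ref = "A", alt = "T", is_variable = TRUE),
    individuals = data.frame(id = sprintf("i%d", 1:6),
                             population = rep(c("A", "B"), each = 3)))
}

test_that("site filters apply the four rules exactly as specified", {
  g <- fiveSiteFixture()
  cfg <- FilterConfig(r = 0.8, p = 2, min_mac = 1, max_obs_het = 0.5)
  kept <- filterSites(g, cfg)
  expect_equal(siteInfo(kept)$chrom, c("s4", "s5"))
  expect_equal(S4Vectors::metadata(kept)$filter$kept, 2L)

  # the monomorphic site comes back when min_mac = 0
  kept0 <- filterSites(g, FilterConfig(r = 0.8, p = 2, min_mac = 0,
                                       max_obs_het = 0.5))
  expect_true("s2" %in% siteInfo(kept0)$chrom)

  # overall genotyping-rate filter: s3 has 4/6 < 0.8
  keptO <- filterSites(g, FilterConfig(r = 0, p = 1, min_mac = 0,
                                       max_obs_het = 1, overall_rate = 0.8))
  expect_false("s3" %in% siteInfo(keptO)$chrom)
  expect_true("s1" %in% siteInfo(keptO)$chrom)

  expect_error(filterSites(g, FilterConfig(p = 3)), "populations")
})

test_that("filtering is idempotent and preserves order", {
  g <- randomGenotypeMatrix(nSites = 120, missingRate = 0.25, seed = 5)
  cfg <- FilterConfig(r = 0.6, p = 2, min_mac = 1, max_obs_het = 0.5)
  once <- filterSites(g, cfg)
  twice <- filterSites(once, cfg)
  expect_identical(genotypes(twice), genotypes(once))
  expect_identical(siteInfo(twice), siteInfo(once))
  # order preserved: kept chroms appear in original order
  expect_identical(siteInfo(once)$chrom,
                   intersect(siteInfo(g)$chrom, siteInfo(once)$chrom))
})

test_that("bootstrap completion keeps observed alleles and fills by frequency", {
  # no missing slots: identity (alleles of 0/1/2 are (0,0), (1,0), (1,1))
  expect_identical(fillMissingBootstrap(c(0L, 1L, 2L), 6L, seed = 1),
                   c(0L, 0L, 1L, 0L, 1L, 1L))
  # all-reference observations can only fill reference alleles
  expect_identical(fillMissingBootstrap(c(0L, 0L, NA), 6L, seed = 2),
                   rep(0L, 6L))
  expect_error(fillMissingBootstrap(c(NA_integer_, NA_integer_), 4L),
               "missing")
  # observed alleles {0,0,1,0}, two missing slots: each fill is the alternate
  # allele with the observed frequency 1/4
  fills <- vapply(1:4000, function(s)
    sum(fillMissingBootstrap(c(0L, 1L, NA), 6L, seed = s)) - 1L, integer(1))
  p <- mean(fills) / 2
  expect_lt(abs(p - 1 / 4), 2.58 * sqrt((1 / 4) * (3 / 4) / 8000))
  # genotype-level resampling: fills come in observed genotype pairs
  gfill <- fillMissingBootstrap(c(2L, 2L, NA), 6L, seed = 3,
                                unit = "genotype")
  expect_identical(gfill, rep(1L, 6L))
})

test_that("the 2D-mSFS counts, folds and transposes correctly", {
  # one site, 2+2 diploids, alt copies (1, 0): increments cell (1, 0)
  g <- GenotypeMatrix(
    matrix(c(1, 0, 0, 0), 1, 4),
    sites = data.frame(chrom = "s1", pos = 1L, ref = "A", alt = "T",
                       is_variable = TRUE),
    individuals = data.frame(id = sprintf("i%d", 1:4),
                             population = rep(c("A", "B"), each = 2)))
  s <- build2dMSFS(g, "A", "B")
  expect_equal(sfsCounts(s)["1", "0"], 1)
  expect_equal(sum(sfsCounts(s)), 1)

  # complete-data recount against the independent brute-force oracle
  g20 <- randomGenotypeMatrix(nSites = 20, seed = 9)
  s20 <- build2dMSFS(g20, "A", "B", seed = 1)
  expect_equal(unname(sfsCounts(s20)), bruteForce2dMSFS(g20, "A", "B"))

  # transpose / exchange symmetry at the same seed policy, with missing data
  gm <- randomGenotypeMatrix(nSites = 150, missingRate = 0.2, seed = 10)
  ab <- build2dMSFS(gm, "A", "B", seed = 77)
  ba <- build2dMSFS(gm, "B", "A", seed = 77)
  expect_identical(unname(sfsCounts(ba)), t(unname(sfsCounts(ab))))
})

test_that("count conservation holds, with exclusions logged", {
  gm <- randomGenotypeMatrix(nSites = 60, missingRate = 0.15, seed = 4)
  G <- genotypes(gm)
  G[5, populations(gm) == "A"] <- NA_integer_   # site 5: pop A fully missing
  gm2 <- GenotypeMatrix(G, siteInfo(gm),
                        data.frame(id = colnames(G),
                                   population = populations(gm)))
  s <- build2dMSFS(gm2, "A", "B", seed = 2)
  # independent recount of sites unusable for the pair
  G2 <- genotypes(gm2)
  unusable <- sum(rowSums(!is.na(G2[, populations(gm2) == "A"])) == 0 |
                  rowSums(!is.na(G2[, populations(gm2) == "B"])) == 0)
  expect_gte(unusable, 1L)
  expect_equal(s@excluded, unusable)
  expect_equal(sum(sfsCounts(s)) + s@excluded, 60)
})

test_that("bootstrap-completed spectra converge to the complete-data spectrum", {
  m <- twoDemeModel(T_split = 3000, n_diploid = 4)
  g <- simulateGenotypes(m, 3000, seed = 20)
  full <- sfsCounts(build2dMSFS(g, "A", "B", seed = 1))
  l1 <- vapply(c(0.2, 0.05), function(rate) {
    gm <- applyMissingness(g, rate, seed = 30)
    s <- build2dMSFS(gm, "A", "B", seed = 1)
    sum(abs(sfsCounts(s) - full)) + s@excluded
  }, numeric(1))
  expect_lt(l1[2], l1[1])
  gm0 <- applyMissingness(g, 0, seed = 30)
  expect_identical(sfsCounts(build2dMSFS(gm0, "A", "B", seed = 1)), full)
})

test_that("VCF output round-trips through the reader", {
  g <- simulateGenotypes(twoDemeModel(n_diploid = 3), 40, seed = 15)
  g <- applyMissingness(g, 0.1, seed = 16)
  vcf <- tempfile(fileext = ".vcf")
  pm <- tempfile(fileext = ".tsv")
  writeVCF(g, vcf)
  writePopmap(g, pm)
  g2 <- readVCF(vcf, pm)
  expect_identical(unname(genotypes(g2)), unname(genotypes(g)))
  expect_identical(populations(g2), populations(g))
  expect_identical(siteInfo(g2)$is_variable, siteInfo(g)$is_variable)
})

test_that("the VCF reader applies the stated dialect rules", {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "i1", "i2", sep = "\t"),
    paste("c1", 1, ".", "A", "T", ".", "PASS", ".", "GT", "0/0", "0/1", sep = "\t"),
    paste("c1", 2, ".", "A", "T,G", ".", "PASS", ".", "GT", "0/1", "1/2", sep = "\t"),
    paste("c1", 3, ".", "A", "T", ".", "PASS", ".", "GT", "./.", "1/1", sep = "\t"),
    paste("c1", 4, ".", "A", ".", ".", "PASS", ".", "GT", "0/0", "0/0", sep = "\t"))
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  popmap <- data.frame(id = c("i1", "i2"), population = c("A", "A"))
  expect_message(g <- readVCF(path, popmap), "multi-allelic")
  expect_equal(nrow(genotypes(g)), 3L)  # 1 of 4 skipped
  expect_equal(S4Vectors::metadata(g)$skipped_multiallelic, 1L)
  expect_identical(unname(genotypes(g)[2, ]), c(NA_integer_, 2L))  # "./."
  expect_false(siteInfo(g)$is_variable[3])  # ALT "." is monomorphic
})

test_that("SFS tables round-trip through TSV and export fsc layout", {
  s <- build2dMSFS(randomGenotypeMatrix(nSites = 30, seed = 2), "A", "B")
  path <- tempfile(fileext = ".tsv")
  writeSFS(s, path)
  s2 <- readSFS(path)
  expect_equal(unname(sfsCounts(s2)), unname(sfsCounts(s)))
  expect_equal(s2@pair, s@pair)
  fsc <- tempfile(fileext = ".obs")
  writeSFS(s, fsc, format = "fsc")
  expect_equal(readLines(fsc, n = 1), "1 observations")
  expect_length(readLines(fsc), 2 + s@n1 + 1)
})
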