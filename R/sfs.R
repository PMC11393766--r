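#' @include coalsim.R
NULL

# stable per-population stream index so pair order cannot change the fills
popStream <- function(pop) sum(utf8ToInt(pop)) %% 65521L

## ---- filtering --------------------------------------------------------------

#' Filter sites of a genotype matrix (Stacks `populations`-style rules)
#'
#' A site is retained iff (i) it is genotyped in at least fraction `r` of the
#' individuals of each of at least `p` populations; (ii) its minor-allele
#' count across genotyped individuals is at least `min_mac`; (iii) its
#' observed heterozygote fraction among genotyped individuals is at most
#' `max_obs_het`; and (iv), when set, its genotyping rate across all
#' individuals is at least `overall_rate`.  Site and individual order are
#' preserved; the operation is idempotent.
#'
#' @param g a [GenotypeMatrix-class].
#' @param cfg a [FilterConfig-class].
#' @return the filtered [GenotypeMatrix-class]; counts of sites failing each
#'   rule are stored in `metadata(x)$filter`.
#' @export
filterSites <- function(g, cfg = FilterConfig()) {
  stopifnot(is(g, "GenotypeMatrix"), is(cfg, "FilterConfig"))
  validObject(cfg)
  G <- genotypes(g)
  pop <- populations(g)
  popNames <- unique(pop)
  p <- if (is.na(cfg@p)) length(popNames) else as.integer(cfg@p)
  if (p > length(popNames))
    stop(sprintf("cfg requires %d populations but data has %d",
                 p, length(popNames)))

  genoByPop <- vapply(popNames, function(pn) {
    cols <- pop == pn
    rowSums(!is.na(G[, cols, drop = FALSE])) / sum(cols)
  }, numeric(nrow(G)))
  if (nrow(G) == 1L) genoByPop <- matrix(genoByPop, nrow = 1L)
  okPops <- rowSums(genoByPop >= cfg@r) >= p

  nGeno <- rowSums(!is.na(G))
  alt <- rowSums(G, na.rm = TRUE)
  tot <- 2L * nGeno
  mac <- ifelse(tot > 0, pmin(alt, tot - alt), 0)
  okMac <- mac >= cfg@min_mac

  nHet <- rowSums(G == 1L, na.rm = TRUE)
  het <- ifelse(nGeno > 0, nHet / nGeno, 0)
  okHet <- het <= cfg@max_obs_het

  okOverall <- if (is.na(cfg@overall_rate)) rep(TRUE, nrow(G))
               else nGeno / ncol(G) >= cfg@overall_rate

  keep <- okPops & okMac & okHet & okOverall
  out <- g[keep, ]
  out <- new("GenotypeMatrix", out)
  S4Vectors::metadata(out)$filter <- list(
    input = nrow(G), kept = sum(keep),
    failed_pop_rate = sum(!okPops), failed_mac = sum(!okMac),
    failed_het = sum(!okHet), failed_overall = sum(!okOverall))
  out
}

## ---- missing-data bootstrap -------------------------------------------------

#' Complete missing haplotypes by within-population bootstrap
#'
#' At one site in one population, the observed alleles are kept and each
#' missing haplotype slot is drawn i.i.d. with replacement from the
#' population's observed alleles (the default, haplotype-level resampling);
#' `unit = "genotype"` instead resamples whole observed genotypes (pairs of
#' alleles) for each missing individual.
#'
#' @param genotypes integer vector of diploid codes 0/1/2 with `NA` for
#'   missing, for the individuals of one population at one site.
#' @param targetHaploid haploid output size (typically twice the number of
#'   individuals).
#' @param seed integer seed or `NULL`.
#' @param unit `"haplotype"` (default) or `"genotype"`.
#' @return integer vector of `targetHaploid` alleles (observed first, then
#'   bootstrap fills).
#' @export
fillMissingBootstrap <- function(genotypes, targetHaploid, seed = NULL,
                                 unit = c("haplotype", "genotype")) {
  unit <- match.arg(unit)
  obsG <- genotypes[!is.na(genotypes)]
  if (!length(obsG))
    stop("all genotypes missing in the population at this site")
  obs <- unlist(lapply(obsG, function(x) c(as.integer(x >= 1), as.integer(x == 2))))
  nFill <- targetHaploid - length(obs)
  if (nFill < 0) stop("targetHaploid smaller than observed haplotypes")
  if (nFill == 0) return(obs)
  fill <- withSeed(seed, {
    if (unit == "haplotype") {
      sample(obs, nFill, replace = TRUE)
    } else {
      gs <- obsG[sample.int(length(obsG), ceiling(nFill / 2), replace = TRUE)]
      unlist(lapply(gs, function(x)
        c(as.integer(x >= 1), as.integer(x == 2))))[seq_len(nFill)]
    }
  })
  c(obs, fill)
}

## ---- 2D-mSFS construction ---------------------------------------------------

# fold a vector of pooled alt-copy pairs to minor orientation; exact 50:50
# pooled ties keep the ALT orientation (deterministic; same rule as the
# simulation engine)
foldPair <- function(iA, iB, nA, nB) {
  flip <- 2 * (iA + iB) > nA + nB
  list(i = ifelse(flip, nA - iA, iA), j = ifelse(flip, nB - iB, iB))
}

#' Build the folded 2D minor-allele SFS for a population pair
#'
#' Per site, missing genotypes are completed by within-population bootstrap
#' ([fillMissingBootstrap()]; haplotype-level fills are drawn as binomial
#' counts from the population's observed allele frequency, which is the same
#' distribution).  The minor allele is determined from the pooled pair after
#' completion and the cell (minor copies in A, minor copies in B) is
#' incremented; monomorphic sites land in cell (0, 0).  Sites where either
#' population is entirely missing are excluded for the pair and counted in
#' the result's `excluded` slot.
#'
#' @param g a (typically filtered) [GenotypeMatrix-class].
#' @param popA,popB two distinct population labels.
#' @param seed master seed for bootstrap completion; each population's fill
#'   stream is derived from the seed and a stable hash of the population
#'   name, so `build2dMSFS(g, B, A, seed)` is exactly the transpose of
#'   `build2dMSFS(g, A, B, seed)`.
#' @param unit passed to the completion step (`"haplotype"` or
#'   `"genotype"`).
#' @return an [SFS2D-class].
#' @export
build2dMSFS <- function(g, popA, popB, seed = NULL,
                        unit = c("haplotype", "genotype")) {
  stopifnot(is(g, "GenotypeMatrix"))
  unit <- match.arg(unit)
  if (identical(popA, popB)) stop("popA and popB must differ")
  pop <- populations(g)
  for (pn in c(popA, popB))
    if (!pn %in% pop) stop(sprintf("unknown population '%s'", pn))
  G <- genotypes(g)
  nA <- 2L * sum(pop == popA)
  nB <- 2L * sum(pop == popB)

  altCopies <- function(pn, stream) {
    Gp <- G[, pop == pn, drop = FALSE]
    nHap <- 2L * ncol(Gp)
    obsAlt <- rowSums(Gp, na.rm = TRUE)
    obsHap <- 2L * rowSums(!is.na(Gp))
    miss <- nHap - obsHap
    fill <- integer(nrow(Gp))
    todo <- which(miss > 0L & obsHap > 0L)
    if (length(todo)) {
      fill[todo] <- withSeed(deriveSeed(seed, stream), {
        if (unit == "haplotype") {
          rbinom(length(todo), miss[todo], obsAlt[todo] / obsHap[todo])
        } else {
          vapply(todo, function(s) {
            gobs <- Gp[s, !is.na(Gp[s, ])]
            sum(fillMissingBootstrap(gobs, nHap, seed = NULL,
                                     unit = "genotype")) - obsAlt[s]
          }, numeric(1))
        }
      })
    }
    list(alt = obsAlt + fill, usable = obsHap > 0L)
  }
  a <- altCopies(popA, popStream(popA))
  b <- altCopies(popB, popStream(popB))
  use <- a$usable & b$usable
  fo <- foldPair(a$alt[use], b$alt[use], nA, nB)
  idx <- fo$i * (nB + 1L) + fo$j + 1L
  counts <- matrix(tabulate(idx, nbins = (nA + 1L) * (nB + 1L)),
                   nrow = nA + 1L, byrow = TRUE)
  SFS2D(c(popA, popB), nA, nB, counts, excluded = sum(!use))
}

#' Build all pairwise folded 2D spectra
#'
#' @param g a [GenotypeMatrix-class].
#' @param seed master seed (see [build2dMSFS()]).
#' @param pairs list of character(2); default all unordered population pairs
#'   in data order.
#' @param unit completion unit.
#' @return named list (`"A|B"`) of [SFS2D-class] objects.
#' @export
buildPairwiseSFS <- function(g, seed = NULL, pairs = NULL,
                             unit = c("haplotype", "genotype")) {
  unit <- match.arg(unit)
  pops <- populationNames(g)
  if (is.null(pairs)) pairs <- utils::combn(pops, 2, simplify = FALSE)
  out <- lapply(pairs, function(p)
    build2dMSFS(g, p[1], p[2], seed = seed, unit = unit))
  names(out) <- vapply(pairs, function(p) pairKey(p[1], p[2]), character(1))
  out
}

## ---- VCF / popmap / SFS table I/O -------------------------------------------

#' Read a VCF 4.2 genotype matrix
#'
#' Reads diploid unphased biallelic genotypes (`0/0`, `0/1`, `1/1`, `./.`;
#' phased separators are tolerated).  Multi-allelic records are skipped with
#' a logged count.  Records with no ALT (or `ALT = "."`) are read as
#' monomorphic sites.
#'
#' @param path VCF file path (plain text or gzipped).
#' @param popmap a two-column data.frame (`id`, `population`) or the path of
#'   a two-column TSV.
#' @return a [GenotypeMatrix-class]; the number of skipped multi-allelic
#'   records is stored in `metadata(x)$skipped_multiallelic`.
#' @export
readVCF <- function(path, popmap) {
  if (is.character(popmap)) popmap <- readPopmap(popmap)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(v@gt)[-1]))
  multi <- grepl(",", fix$ALT %||% "", fixed = TRUE)
  nSkip <- sum(multi)
  if (nSkip) message(nSkip, " multi-allelic record(s) skipped")
  fix <- fix[!multi, , drop = FALSE]
  gt <- gt[!multi, , drop = FALSE]
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  g2 <- gsub("|", "/", gt, fixed = TRUE)
  code[g2 == "0/0"] <- 0L
  code[g2 %in% c("0/1", "1/0")] <- 1L
  code[g2 == "1/1"] <- 2L
  ids <- colnames(gt)
  if (!all(ids %in% popmap$id))
    stop("popmap does not cover all individuals: ",
         paste(setdiff(ids, popmap$id), collapse = ", "))
  individuals <- data.frame(
    id = ids,
    population = popmap$population[match(ids, popmap$id)],
    stringsAsFactors = FALSE)
  alt <- fix$ALT
  alt[is.na(alt)] <- "."
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = alt,
                      is_variable = alt != ".",
                      stringsAsFactors = FALSE)
  out <- GenotypeMatrix(code, sites, individuals)
  S4Vectors::metadata(out)$skipped_multiallelic <- nSkip
  out
}

#' Write a genotype matrix as plain-text VCF 4.2
#'
#' @param g a [GenotypeMatrix-class].
#' @param path output path.
#' @param monomorphicAlt how to emit monomorphic records: `"dot"` writes
#'   `ALT = "."`, `"invariant"` keeps the stored (unobserved) ALT symbol.
#' @param header extra `##`-header lines (e.g. a seed record).
#' @return the path, invisibly.
#' @export
writeVCF <- function(g, path, monomorphicAlt = c("dot", "invariant"),
                     header = character()) {
  stopifnot(is(g, "GenotypeMatrix"))
  monomorphicAlt <- match.arg(monomorphicAlt)
  si <- siteInfo(g)
  G <- genotypes(g)
  gtStr <- matrix("./.", nrow(G), ncol(G))
  gtStr[!is.na(G) & G == 0L] <- "0/0"
  gtStr[!is.na(G) & G == 1L] <- "0/1"
  gtStr[!is.na(G) & G == 2L] <- "1/1"
  alt <- si$alt
  if (monomorphicAlt == "dot") alt[!si$is_variable] <- "."
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=coalSFS %s", as.character(utils::packageVersion("coalSFS"))),
    header,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(G)), collapse = "\t"),
    paste(si$chrom, si$pos, ".", si$ref, alt, ".", "PASS", ".", "GT",
          apply(gtStr, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a two-column population map
#'
#' @param path TSV path (columns: individual id, population; no header).
#' @return data.frame with columns `id` and `population`.
#' @export
readPopmap <- function(path) {
  pm <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  setNames(pm[, 1:2], c("id", "population"))
}

#' @param g a [GenotypeMatrix-class].
#' @rdname readPopmap
#' @export
writePopmap <- function(g, path) {
  utils::write.table(
    data.frame(id = colnames(genotypes(g)), population = populations(g)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a 2D-mSFS as a labeled TSV matrix
#'
#' `format = "fsc"` additionally supports the fastsimcoal2 joint-MAF
#' observed-SFS text layout (`_jointMAFpop1_0.obs` style) for export.
#'
#' @param sfs an [SFS2D-class].
#' @param path output path.
#' @param format `"tsv"` (default, round-trips with [readSFS()]) or
#'   `"fsc"`.
#' @param header extra comment lines (prefixed `#`) embedded at the top of
#'   TSV output.
#' @export
writeSFS <- function(sfs, path, format = c("tsv", "fsc"),
                     header = character()) {
  stopifnot(is(sfs, "SFS2D"))
  format <- match.arg(format)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# pair\t%s\t%s", sfs@pair[1], sfs@pair[2]),
                 sprintf("# n\t%d\t%d", sfs@n1, sfs@n2),
                 sprintf("# excluded\t%d", sfs@excluded),
                 if (length(header)) paste0("# ", header)), con)
    utils::write.table(sfs@counts, con, sep = "\t", quote = FALSE,
                       col.names = NA)
  } else {
    rows <- apply(sfs@counts, 1, paste, collapse = "\t")
    writeLines(c("1 observations",
                 paste(c("", sprintf("d0_%d", 0:sfs@n2)), collapse = "\t"),
                 paste(sprintf("d1_%d", 0:sfs@n1), rows, sep = "\t")),
               path)
  }
  invisible(path)
}

#' @rdname writeSFS
#' @export
readSFS <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "# ")]
  meta <- strsplit(sub("^# ", "", hdr), "\t")
  getv <- function(key) {
    m <- Filter(function(x) x[1] == key, meta)
    if (length(m)) m[[1]][-1] else NULL
  }
  counts <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#",
                                        header = TRUE, row.names = 1,
                                        check.names = FALSE))
  pair <- getv("pair") %||% c("pop1", "pop2")
  SFS2D(pair, nrow(counts) - 1L, ncol(counts) - 1L, unname(counts),
        excluded = as.integer(getv("excluded") %||% 0L))
}
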