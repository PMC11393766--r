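#' @include utils.R
NULL

## ---- TimeScale --------------------------------------------------------------

#' Generation-time scale
#'
#' Converts between coalescent time (generations before present) and calendar
#' years.  The default of 5 years per generation reflects a woody perennial
#' that starts flowering within a few years of germination.
#'
#' @slot generationTimeYears positive number of years per generation.
#' @export
setClass("TimeScale", representation(generationTimeYears = "numeric"),
         prototype(generationTimeYears = 5))

setValidity("TimeScale", function(object) {
  g <- object@generationTimeYears
  if (length(g) != 1L || !is.finite(g) || g <= 0)
    return("generationTimeYears must be a single positive number")
  TRUE
})

#' @param generation_time_years years per generation (default 5).
#' @rdname TimeScale-class
#' @export
TimeScale <- function(generation_time_years = 5) {
  new("TimeScale", generationTimeYears = generation_time_years)
}

## ---- DemographicModel -------------------------------------------------------

#' Demographic model for a set of diploid populations
#'
#' A backward-in-time description of a multi-population history: present-day
#' demes with effective sizes, a list of divergence and size-change events
#' (times in generations before present), an optional recent-migration epoch,
#' a per-site per-generation mutation rate, and the set of free parameters
#' (with search bounds) bound to model slots.
#'
#' Free-parameter targets use a compact addressing syntax, semicolon-separated
#' when one parameter drives several slots:
#' \itemize{
#'   \item `time:<event row>` an event time,
#'   \item `size:<event row>` a size-change event's new size,
#'   \item `N:<population>` a present-day effective size,
#'   \item `mig:<from>:<to>` a forward migration fraction.
#' }
#'
#' @slot id model identifier.
#' @slot populations data.frame with columns `name`, `island_group`,
#'   `n_diploid`, `N_current`.
#' @slot events data.frame with columns `time`, `kind`
#'   (`"divergence"` or `"size_change"`), `source`, `sink`, `new_size`.
#' @slot migration list with `t_end` (generations) and `rates`
#'   (named square matrix of forward fractions, `rates[i, j]` = fraction of
#'   deme j founded per generation by migrants from deme i); empty list when
#'   the model has no migration.
#' @slot mu per-site per-generation mutation rate.
#' @slot freeParams data.frame with columns `name`, `targets`, `lower`,
#'   `upper`; all free parameters are positive and searched on log10 scale.
#' @slot orderConstraints data.frame with columns `earlier`, `later`
#'   (event row indices whose times must satisfy `time[earlier] <=
#'   time[later]`); used by tree-ordering candidate models.
#' @export
setClass("DemographicModel",
         representation(id = "character", populations = "data.frame",
                        events = "data.frame", migration = "list",
                        mu = "numeric", freeParams = "data.frame",
                        orderConstraints = "data.frame"))

## ---- GenotypeMatrix ---------------------------------------------------------

#' Biallelic genotype matrix (sites x diploid individuals)
#'
#' A `SummarizedExperiment` whose single assay `"GT"` holds alternate-allele
#' dosage codes (0, 1, 2, or `NA` for missing), with site records as row data
#' (`chrom`, `pos`, `ref`, `alt`, `is_variable`) and the population map as
#' column data (`population`).
#'
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  if (!"GT" %in% SummarizedExperiment::assayNames(object))
    return("assay 'GT' is required")
  g <- SummarizedExperiment::assay(object, "GT")
  bad <- g[!is.na(g)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    return("genotype codes must be 0, 1, 2 or NA")
  cd <- SummarizedExperiment::colData(object)
  if (!"population" %in% colnames(cd))
    return("colData must contain a 'population' column")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("chrom", "pos", "ref", "alt", "is_variable")
  if (!all(need %in% colnames(rd)))
    return(paste("rowData must contain:", paste(need, collapse = ", ")))
  if (nrow(rd) && any(rd$pos < 1L)) return("site positions must be >= 1")
  TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param genotypes integer matrix, sites x individuals, codes 0/1/2/NA.
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt`, `is_variable`.
#' @param individuals data.frame with `id` and `population`.
#' @return a [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(genotypes, sites, individuals) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  rownames(genotypes) <- NULL
  colnames(genotypes) <- individuals$id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(GT = genotypes),
    rowData = S4Vectors::DataFrame(sites),
    colData = S4Vectors::DataFrame(individuals, row.names = individuals$id))
  new("GenotypeMatrix", se)
}

## ---- SFS2D ------------------------------------------------------------------

#' Folded 2D minor-allele site frequency spectrum
#'
#' Counts of sites by minor-allele copy number jointly in two populations,
#' folded so the pooled minor-allele frequency is at most one half, including
#' the monomorphic cell (0, 0).  `n1` and `n2` are haploid sample sizes, so
#' `counts` is an (n1 + 1) x (n2 + 1) table.
#'
#' @slot pair character(2), the two population labels.
#' @slot n1,n2 haploid sample sizes.
#' @slot counts nonnegative numeric matrix of site counts.
#' @slot excluded number of sites dropped (e.g. a population entirely missing
#'   at the site).
#' @export
setClass("SFS2D",
         representation(pair = "character", n1 = "integer", n2 = "integer",
                        counts = "matrix", excluded = "integer"),
         prototype(excluded = 0L))

setValidity("SFS2D", function(object) {
  if (length(object@pair) != 2L) return("pair must have length 2")
  if (!all(dim(object@counts) == c(object@n1 + 1L, object@n2 + 1L)))
    return("counts must be (n1+1) x (n2+1)")
  if (any(object@counts < 0)) return("counts must be nonnegative")
  ## after folding, cells whose pooled count exceeds (n1+n2)/2 must be empty
  i <- row(object@counts) - 1L
  j <- col(object@counts) - 1L
  if (any(object@counts[2 * (i + j) > object@n1 + object@n2] > 0))
    return("counts contain unfolded cells (pooled count > (n1+n2)/2)")
  TRUE
})

#' @param pair,n1,n2,counts,excluded see slots.
#' @rdname SFS2D-class
#' @export
SFS2D <- function(pair, n1, n2, counts, excluded = 0L) {
  dimnames(counts) <- list(0:n1, 0:n2)
  new("SFS2D", pair = as.character(pair), n1 = as.integer(n1),
      n2 = as.integer(n2), counts = counts, excluded = as.integer(excluded))
}

## ---- FilterConfig -----------------------------------------------------------

#' Site-filter configuration (Stacks `populations`-style)
#'
#' @slot r per-population genotyping-rate minimum (default 0.8).
#' @slot p number of populations a site must be adequately genotyped in;
#'   `NA` means all populations present in the data.
#' @slot min_mac minimum minor-allele count across genotyped individuals
#'   (default 1).
#' @slot max_obs_het maximum observed heterozygote fraction among genotyped
#'   individuals (default 0.5).
#' @slot overall_rate optional across-all-individuals genotyping-rate
#'   minimum (`NA` disables; typical choices 0.3, 0.5, 0.8).
#' @export
setClass("FilterConfig",
         representation(r = "numeric", p = "numeric", min_mac = "numeric",
                        max_obs_het = "numeric", overall_rate = "numeric"),
         prototype(r = 0.8, p = NA_real_, min_mac = 1, max_obs_het = 0.5,
                   overall_rate = NA_real_))

setValidity("FilterConfig", function(object) {
  rr <- c(object@r, object@max_obs_het)
  if (any(!is.na(rr) & (rr < 0 | rr > 1))) return("rates must be in [0, 1]")
  if (!is.na(object@overall_rate) &&
      (object@overall_rate < 0 || object@overall_rate > 1))
    return("overall_rate must be in [0, 1]")
  if (object@min_mac < 0) return("min_mac must be >= 0")
  if (!is.na(object@p) && object@p < 1) return("p must be >= 1")
  TRUE
})

#' @param r,p,min_mac,max_obs_het,overall_rate see slots.
#' @rdname FilterConfig-class
#' @export
FilterConfig <- function(r = 0.8, p = NA, min_mac = 1, max_obs_het = 0.5,
                         overall_rate = NA) {
  new("FilterConfig", r = r, p = as.numeric(p), min_mac = min_mac,
      max_obs_het = max_obs_het, overall_rate = as.numeric(overall_rate))
}

## ---- FitSchedule ------------------------------------------------------------

#' ECM optimization schedule
#'
#' Defaults follow the full-scale analysis settings (50 random starts, 40 ECM
#' cycles, 100,000 coalescent simulations per likelihood evaluation); use
#' [deskSchedule()] for a scaled-down schedule suitable for experimentation.
#'
#' @slot nStarts number of random starting points.
#' @slot nCycles maximum ECM cycles per start.
#' @slot nSims coalescent simulations per likelihood evaluation.
#' @slot seed master seed for the fit.
#' @export
setClass("FitSchedule",
         representation(nStarts = "integer", nCycles = "integer",
                        nSims = "integer", seed = "integer"),
         prototype(nStarts = 50L, nCycles = 40L, nSims = 100000L, seed = 1L))

setValidity("FitSchedule", function(object) {
  v <- c(object@nStarts, object@nCycles, object@nSims)
  if (any(v < 1L)) return("nStarts, nCycles and nSims must all be positive")
  TRUE
})

#' @param nStarts,nCycles,nSims,seed see slots.
#' @rdname FitSchedule-class
#' @export
FitSchedule <- function(nStarts = 50, nCycles = 40, nSims = 100000, seed = 1) {
  new("FitSchedule", nStarts = as.integer(nStarts),
      nCycles = as.integer(nCycles), nSims = as.integer(nSims),
      seed = as.integer(seed))
}

#' Scaled-down ECM schedule for desk-scale experiments
#'
#' @param nStarts,nCycles,nSims,seed overrides of the desk defaults
#'   (3 starts, 10 cycles, 5000 simulations).
#' @return a [FitSchedule-class].
#' @export
deskSchedule <- function(nStarts = 3, nCycles = 10, nSims = 5000, seed = 1) {
  FitSchedule(nStarts = nStarts, nCycles = nCycles, nSims = nSims, seed = seed)
}

## ---- FitResult --------------------------------------------------------------

#' Result of a composite-likelihood model fit
#'
#' @slot modelId identifier of the fitted model.
#' @slot params named vector of parameter estimates (natural scale).
#' @slot lnL natural-log composite likelihood at the estimates.
#' @slot k number of free parameters.
#' @slot AIC Akaike information criterion, `2k - 2 lnL`.
#' @slot trace per-cycle lnL of the best start.
#' @slot converged logical convergence flag.
#' @export
setClass("FitResult",
         representation(modelId = "character", params = "numeric",
                        lnL = "numeric", k = "integer", AIC = "numeric",
                        trace = "numeric", converged = "logical"))

setValidity("FitResult", function(object) {
  if (is.finite(object@lnL) &&
      abs(object@AIC - (2 * object@k - 2 * object@lnL)) > 1e-8)
    return("AIC must equal 2k - 2 lnL")
  TRUE
})

## ---- BootstrapResult --------------------------------------------------------

#' Parametric-bootstrap result
#'
#' @slot replicates data.frame of refitted parameter values, one row per
#'   successful replicate.
#' @slot ci data.frame with columns `param`, `lower`, `upper` (2.5% and
#'   97.5% percentile bounds).
#' @slot failures number of replicate refits that failed and were dropped.
#' @export
setClass("BootstrapResult",
         representation(replicates = "data.frame", ci = "data.frame",
                        failures = "integer"),
         prototype(failures = 0L))

setValidity("BootstrapResult", function(object) {
  ci <- object@ci
  if (nrow(ci) && any(ci$lower > ci$upper)) return("ci lower must be <= upper")
  TRUE
})

## ---- AllometricModel --------------------------------------------------------

#' Allometric seed-dispersal model
#'
#' Dispersal distance is the product of flight speed and gut retention time,
#' each a power law of body mass: `speed = a_s * mass^b_s` (km/h, mass in g)
#' and `retention = a_r * mass^b_r` (minutes, mass in g), so
#' `distance = speed * retention / 60` km.
#'
#' @slot retention list with `intercept`, `exponent` (minutes vs g).
#' @slot speed list with `intercept`, `exponent` (km/h vs g).
#' @slot provenance citation note for the coefficient sources.
#' @export
setClass("AllometricModel",
         representation(retention = "list", speed = "list",
                        provenance = "character"),
         prototype(provenance = ""))

setValidity("AllometricModel", function(object) {
  for (part in c("retention", "speed")) {
    co <- slot(object, part)
    if (!all(c("intercept", "exponent") %in% names(co)))
      return(sprintf("%s must provide intercept and exponent", part))
    v <- unlist(co[c("intercept", "exponent")])
    if (any(!is.finite(v))) return(sprintf("%s coefficients must be finite", part))
  }
  TRUE
})

#' @param retention,speed lists with `intercept` and `exponent`.
#' @param provenance citation note.
#' @rdname AllometricModel-class
#' @export
allometricModel <- function(retention, speed, provenance = "") {
  if (is.null(retention$intercept) || is.null(retention$exponent) ||
      is.null(speed$intercept) || is.null(speed$exponent))
    stop("allometric coefficients are required (no silent defaults): ",
         "retention and speed each need intercept and exponent")
  new("AllometricModel", retention = retention, speed = speed,
      provenance = provenance)
}
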