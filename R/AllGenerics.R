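#' @include AllClasses.R
NULL

#' Accessors for coalSFS classes
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname accessors
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x)
  SummarizedExperiment::assay(x, "GT"))

#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname accessors
#' @export
setMethod("populations", "GenotypeMatrix", function(x)
  as.character(SummarizedExperiment::colData(x)$population))

#' @rdname accessors
#' @export
setMethod("populations", "DemographicModel", function(x) x@populations)

#' @rdname accessors
#' @export
setGeneric("populationNames", function(x) standardGeneric("populationNames"))

#' @rdname accessors
#' @export
setMethod("populationNames", "GenotypeMatrix", function(x)
  unique(populations(x)))

#' @rdname accessors
#' @export
setMethod("populationNames", "DemographicModel", function(x)
  x@populations$name)

#' @rdname accessors
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @rdname accessors
#' @export
setMethod("siteInfo", "GenotypeMatrix", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname accessors
#' @export
setGeneric("sfsCounts", function(x) standardGeneric("sfsCounts"))

#' @rdname accessors
#' @export
setMethod("sfsCounts", "SFS2D", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("modelEvents", function(x) standardGeneric("modelEvents"))

#' @rdname accessors
#' @export
setMethod("modelEvents", "DemographicModel", function(x) x@events)

#' @rdname accessors
#' @export
setGeneric("freeParams", function(x) standardGeneric("freeParams"))

#' @rdname accessors
#' @export
setMethod("freeParams", "DemographicModel", function(x) x@freeParams)

#' @rdname accessors
#' @export
setGeneric("fittedParams", function(x) standardGeneric("fittedParams"))

#' @rdname accessors
#' @export
setMethod("fittedParams", "FitResult", function(x) x@params)

#' @rdname accessors
#' @export
setGeneric("logLik2", function(x) standardGeneric("logLik2"))

#' @rdname accessors
#' @export
setMethod("logLik2", "FitResult", function(x) x@lnL)

#' @rdname accessors
#' @export
setGeneric("aic", function(x) standardGeneric("aic"))

#' @rdname accessors
#' @export
setMethod("aic", "FitResult", function(x) x@AIC)

#' @rdname accessors
#' @export
setGeneric("bootstrapCI", function(x) standardGeneric("bootstrapCI"))

#' @rdname accessors
#' @export
setMethod("bootstrapCI", "BootstrapResult", function(x) x@ci)

## ---- show methods -----------------------------------------------------------

setMethod("show", "DemographicModel", function(object) {
  cat("DemographicModel '", object@id, "': ", nrow(object@populations),
      " demes, ", sum(object@events$kind == "divergence"),
      " divergence and ", sum(object@events$kind == "size_change"),
      " size-change events\n", sep = "")
  cat("  demes:", paste(object@populations$name, collapse = ", "), "\n")
  if (length(object@migration))
    cat("  recent migration until t =", object@migration$t_end, "generations\n")
  cat("  mu =", object@mu, "; free parameters:",
      if (nrow(object@freeParams)) paste(object@freeParams$name, collapse = ", ")
      else "(none)", "\n")
})

setMethod("show", "SFS2D", function(object) {
  cat("SFS2D ", pairKey(object@pair[1], object@pair[2]),
      " (n1 = ", object@n1, ", n2 = ", object@n2, " haploids): ",
      format(sum(object@counts), big.mark = ","), " sites (",
      object@excluded, " excluded)\n", sep = "")
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult '", object@modelId, "': lnL = ", format(object@lnL),
      ", k = ", object@k, ", AIC = ", format(object@AIC),
      if (object@converged) " (converged)\n" else "\n", sep = "")
  if (length(object@params)) {
    cat("  estimates:\n")
    print(signif(object@params, 4))
  }
})

setMethod("show", "BootstrapResult", function(object) {
  cat("BootstrapResult:", nrow(object@replicates), "replicates,",
      object@failures, "failures\n")
  if (nrow(object@ci)) print(object@ci)
})

setMethod("show", "AllometricModel", function(object) {
  cat("AllometricModel: speed = ", object@speed$intercept, " * m^",
      object@speed$exponent, " km/h; retention = ",
      object@retention$intercept, " * m^", object@retention$exponent,
      " min (mass in g)\n", sep = "")
  if (nzchar(object@provenance)) cat("  provenance:", object@provenance, "\n")
})
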