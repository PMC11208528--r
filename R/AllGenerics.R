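#' Accessors for mbGWAS data classes
#'
#' `dosage()` returns the samples x variants dosage matrix of a
#' [GenotypeMatrix-class]; `variantInfo()` its per-variant metadata;
#' `nSamples()`/`nVariants()` its dimensions. `taxonomy()` returns the
#' lineage table of a [TaxaCounts-class]; `sampleTotals()` its
#' per-sample total sequence counts. `gowerValues()` returns the
#' centered matrix inside a [GowerMatrix-class] and `nPartialled()`
#' the number of covariate columns projected out of it.
#' `selectedFeatures()` returns the representative features chosen
#' from a [FeatureSet-class].
#'
#' @param x a package data object.
#' @return See details per accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname accessors
#' @export
setMethod("dosage", "GenotypeMatrix", function(x) x@dosage)

#' @rdname accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname accessors
#' @export
setMethod("variantInfo", "GenotypeMatrix", function(x) x@variants)

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setMethod("nSamples", "GenotypeMatrix", function(x) nrow(x@dosage))

#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname accessors
#' @export
setMethod("nVariants", "GenotypeMatrix", function(x) ncol(x@dosage))

#' @rdname accessors
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @rdname accessors
#' @export
setMethod("taxonomy", "TaxaCounts", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname accessors
#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "TaxaCounts", function(object)
  SummarizedExperiment::assay(object, "counts"))

#' @rdname accessors
#' @export
setGeneric("sampleTotals", function(x) standardGeneric("sampleTotals"))

#' @rdname accessors
#' @export
setMethod("sampleTotals", "TaxaCounts", function(x) colSums(counts(x)))

#' @rdname accessors
#' @export
setGeneric("gowerValues", function(x) standardGeneric("gowerValues"))

#' @rdname accessors
#' @export
setMethod("gowerValues", "GowerMatrix", function(x) x@mat)

#' @rdname accessors
#' @export
setGeneric("nPartialled", function(x) standardGeneric("nPartialled"))

#' @rdname accessors
#' @export
setMethod("nPartialled", "GowerMatrix", function(x) x@q)

#' @rdname accessors
#' @export
setGeneric("selectedFeatures",
           function(x) standardGeneric("selectedFeatures"))

#' @rdname accessors
#' @export
setMethod("selectedFeatures", "FeatureSet", function(x) {
  cl <- x@clusters
  if (!nrow(cl) || !"selected" %in% colnames(cl))
    return(x@candidates[0, , drop = FALSE])
  ids <- cl$feature_id[cl$selected]
  out <- x@candidates[match(ids, x@candidates$feature_id), , drop = FALSE]
  out$cluster <- cl$cluster[cl$selected]
  rownames(out) <- NULL
  out
})

#' @rdname accessors
#' @export
setGeneric("clusterAssignments",
           function(x) standardGeneric("clusterAssignments"))

#' @rdname accessors
#' @export
setMethod("clusterAssignments", "FeatureSet", function(x) x@clusters)

#' @rdname accessors
#' @export
setGeneric("filterLog", function(x) standardGeneric("filterLog"))

#' @rdname accessors
#' @export
setMethod("filterLog", "FeatureSet", function(x) x@log)
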