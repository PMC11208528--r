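#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#'   assayNames rowData
NULL

TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family",
               "genus", "species")

#' GenotypeMatrix: allele dosages for a cohort
#'
#' Holds hard-called alternative-allele dosages (0 = homozygous
#' reference, 1 = heterozygous, 2 = homozygous alternative, `NA` =
#' missing call) for samples (rows) by biallelic SNPs (columns),
#' together with per-variant metadata: chromosome, 1-based position,
#' identifier, reference/alternative alleles and, when available, the
#' imputation quality R2.
#'
#' @slot dosage numeric matrix, samples x variants, values in
#'   \{0, 1, 2, NA\}; dimnames are sample and variant identifiers.
#' @slot variants [S4Vectors::DataFrame] with columns `chrom`, `pos`,
#'   `id`, `ref`, `alt` and optionally `impR2` (in \[0, 1\]).
#' @seealso [readGenotypes()], [simulateGenotypes()], [variantQC()]
#' @export
setClass("GenotypeMatrix",
  representation(dosage = "matrix", variants = "DataFrame"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosage
  v <- object@variants
  msg <- character()
  if (nrow(v) != ncol(d))
    msg <- c(msg, "variant metadata rows must match dosage columns")
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% colnames(v)))
    msg <- c(msg, paste("variants must have columns:",
                        paste(need, collapse = ", ")))
  bad <- d[!is.na(d)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(rownames(d)))
    msg <- c(msg, "sample ids must be unique")
  if (all(need %in% colnames(v))) {
    if (anyDuplicated(paste(v$chrom, v$pos, v$alt)))
      msg <- c(msg, "(chrom, pos, alt) must be unique across variants")
  }
  if ("impR2" %in% colnames(v)) {
    r2 <- v$impR2[!is.na(v$impR2)]
    if (length(r2) && (any(r2 < 0) || any(r2 > 1)))
      msg <- c(msg, "impR2 must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage samples x variants numeric matrix of alt-allele
#'   dosages in \{0, 1, 2, NA\}, with sample ids as rownames.
#' @param variants data.frame or DataFrame of variant metadata with
#'   columns `chrom`, `pos`, `id`, `ref`, `alt` and optional `impR2`.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' g <- GenotypeMatrix(
#'   matrix(c(0, 1, 2, 0), 2, 2,
#'          dimnames = list(c("s1", "s2"), c("v1", "v2"))),
#'   data.frame(chrom = "1", pos = c(100L, 200L), id = c("v1", "v2"),
#'              ref = "A", alt = "G"))
#' nVariants(g)
#' @export
GenotypeMatrix <- function(dosage, variants) {
  variants <- as(as.data.frame(variants), "DataFrame")
  if (is.null(colnames(dosage))) colnames(dosage) <- variants$id
  rownames(variants) <- variants$id
  new("GenotypeMatrix", dosage = dosage, variants = variants)
}

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosage
  nm <- sum(is.na(d))
  cat("GenotypeMatrix:", nrow(d), "samples x", ncol(d), "variants\n")
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nm,
              100 * nm / max(1, length(d))))
  if ("impR2" %in% colnames(object@variants))
    cat("  imputation R2 available\n")
})

#' TaxaCounts: a taxon count table with lineages
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding non-negative
#' integer sequence counts (assay `"counts"`, features x samples) whose
#' `rowData` carries the seven-rank lineage (kingdom..species) plus the
#' rank label of each feature (`"asv"` for unaggregated amplicon
#' sequence variants).
#'
#' @seealso [TaxaCounts()], [aggregateTaxa()], [rarefyCounts()]
#' @export
setClass("TaxaCounts", contains = "SummarizedExperiment")

setValidity("TaxaCounts", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    msg <- c(msg, "counts must be non-negative integers")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c(TAX_RANKS, "rank") %in% colnames(rd)))
    msg <- c(msg, paste("rowData needs columns:",
                        paste(c(TAX_RANKS, "rank"), collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "feature ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a TaxaCounts object
#'
#' @param counts features x samples matrix of non-negative integer
#'   counts; rownames are feature (e.g. ASV) ids, colnames sample ids.
#' @param taxonomy data.frame with one row per feature (matched by
#'   rownames or a first `feature_id` column) and the seven rank
#'   columns kingdom, phylum, class, order, family, genus, species
#'   (`NA` where unassigned); an optional `rank` column labels the
#'   taxonomic level of each feature (default `"asv"`).
#' @return A [TaxaCounts-class] object.
#' @export
TaxaCounts <- function(counts, taxonomy) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  taxonomy <- as.data.frame(taxonomy)
  if ("feature_id" %in% colnames(taxonomy)) {
    rownames(taxonomy) <- taxonomy$feature_id
    taxonomy$feature_id <- NULL
  }
  if (is.null(rownames(counts)))
    stop("count matrix must have feature rownames")
  missing_tax <- setdiff(rownames(counts), rownames(taxonomy))
  if (length(missing_tax))
    stop("features missing from taxonomy: ",
         paste(missing_tax, collapse = ", "))
  taxonomy <- taxonomy[rownames(counts), , drop = FALSE]
  if (!"rank" %in% colnames(taxonomy)) taxonomy$rank <- "asv"
  miss <- setdiff(TAX_RANKS, colnames(taxonomy))
  for (r in miss) taxonomy[[r]] <- NA_character_
  extra <- setdiff(colnames(taxonomy), c(TAX_RANKS, "rank"))
  taxonomy <- taxonomy[, c(TAX_RANKS, "rank", extra), drop = FALSE]
  new("TaxaCounts", SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = as(taxonomy, "DataFrame")))
}

#' FeatureSet: the univariate feature-construction state
#'
#' Records the candidate bacterial features (ASVs plus agglomerated
#' taxa), which passed the prevalence/abundance filters, their
#' correlation-cluster assignment, and the representative selected
#' from each cluster.
#'
#' @slot candidates data.frame: feature id, rank, lineage, prevalence,
#'   median count over present samples, total count, kept flag.
#' @slot clusters data.frame: per kept feature its cluster id and
#'   whether it is the selected representative.
#' @slot log data.frame: per feature a status and reason string.
#' @seealso [filterFeatures()], [clusterFeatures()],
#'   [selectRepresentatives()]
#' @export
setClass("FeatureSet",
  representation(candidates = "data.frame", clusters = "data.frame",
                 log = "data.frame"))

setValidity("FeatureSet", function(object) {
  cl <- object@clusters
  if (nrow(cl) && any(!cl$feature_id %in% object@candidates$feature_id))
    return("cluster rows must refer to candidate features")
  TRUE
})

setMethod("show", "FeatureSet", function(object) {
  cat("FeatureSet:", nrow(object@candidates), "candidates,",
      sum(object@candidates$kept), "passed filters\n")
  cl <- object@clusters
  if (nrow(cl)) {
    cat("  clusters:", length(unique(cl$cluster)), "\n")
    sel <- selectedFeatures(object)
    if (nrow(sel)) {
      cat("  selected representatives by rank:\n")
      print(table(sel$rank))
    }
  }
})

#' GowerMatrix: a double-centered inner-product matrix
#'
#' The Gower-centered form `G = J A J` of a squared dissimilarity
#' matrix (`A = -D^2/2`, `J = I - 11'/n`), optionally with covariates
#' projected out (`G_res = R G R`). This is the object the
#' distance-based F-test operates on.
#'
#' @slot mat the n x n symmetric, doubly centered matrix.
#' @slot q integer, number of covariate columns (excluding the
#'   intercept) already partialled out of the matrix.
#' @seealso [gowerCenter()], [partialOutCovariates()], [dbfTest()]
#' @export
setClass("GowerMatrix",
  representation(mat = "matrix", q = "integer"))

setValidity("GowerMatrix", function(object) {
  m <- object@mat
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  else {
    if (max(abs(m - t(m))) > 1e-8) msg <- c(msg, "matrix must be symmetric")
    if (max(abs(rowSums(m))) > 1e-6)
      msg <- c(msg, "rows must sum to zero (double centering)")
  }
  if (object@q < 0) msg <- c(msg, "q must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GowerMatrix", function(object) {
  cat("GowerMatrix:", nrow(object@mat), "samples, trace",
      format(sum(diag(object@mat)), digits = 6), "\n")
  if (object@q > 0)
    cat("  covariates partialled out:", object@q, "columns\n")
})
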