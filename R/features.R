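# Feature construction for the univariate scans: taxonomic
# agglomeration, prevalence/abundance filtering, Spearman-correlation
# clustering and representative selection.

RANK_DEPTH <- c(phylum = 1, class = 2, order = 3, family = 4,
                genus = 5, species = 6, asv = 7)

#' Agglomerate counts to a taxonomic rank
#'
#' Features sharing the full lineage prefix down to `rank` are summed
#' per sample. Features unassigned at `rank` are grouped under their
#' longest assigned prefix and flagged (`unresolved = TRUE` in the
#' rowData), so per-sample totals are conserved exactly.
#'
#' @param tc a [TaxaCounts-class] (typically at ASV level).
#' @param rank one of phylum, class, order, family, genus, species.
#' @return A [TaxaCounts-class] at the requested rank; feature ids
#'   are `rank:lineage` strings.
#' @examples
#' # two ASVs of one genus with counts 3 and 4 sum to a genus count 7
#' @export
aggregateTaxa <- function(tc, rank) {
  ranks_to <- TAX_RANKS[2:7]  # phylum..species
  if (!rank %in% ranks_to)
    stop("unknown rank: ", rank, " (expected one of ",
         paste(ranks_to, collapse = ", "), ")")
  tax <- taxonomy(tc)
  upto <- TAX_RANKS[seq_len(match(rank, TAX_RANKS))]
  lin <- tax[, upto, drop = FALSE]
  # longest assigned prefix: truncate at the first NA in the lineage
  key <- apply(as.matrix(lin), 1, function(r) {
    na1 <- which(is.na(r) | r == "")
    if (length(na1)) r <- r[seq_len(min(na1) - 1)]
    paste(r, collapse = ";")
  })
  unresolved <- is.na(lin[[rank]]) | lin[[rank]] == ""
  m <- counts(tc)
  agg <- rowsum(m, group = key, reorder = TRUE)
  ids <- paste0(rank, ":", rownames(agg))
  first <- match(rownames(agg), key)
  newtax <- tax[first, TAX_RANKS, drop = FALSE]
  ri <- match(rank, TAX_RANKS)
  if (ri < 7) newtax[, TAX_RANKS[(ri + 1):7]] <- NA_character_
  # unresolved groups keep only the assigned prefix of their lineage
  flag <- unresolved[first]
  depth_of <- lengths(strsplit(rownames(agg), ";", fixed = TRUE))
  for (i in which(flag))
    if (depth_of[i] < ri)
      newtax[i, TAX_RANKS[(depth_of[i] + 1):ri]] <- NA_character_
  newtax$rank <- rank
  newtax$unresolved <- flag
  rownames(agg) <- ids
  rownames(newtax) <- ids
  out <- TaxaCounts(agg, newtax)
  out
}

#' Build the candidate feature table across ranks
#'
#' Concatenates the ASV-level features with their agglomerations at
#' genus, family, order, class and phylum into one [TaxaCounts-class]
#' of candidates for filtering.
#'
#' @param tc ASV-level [TaxaCounts-class].
#' @param ranks ranks to agglomerate to (default genus up to phylum).
#' @return A [TaxaCounts-class] stacking all candidate features.
#' @export
candidateFeatures <- function(tc,
                              ranks = c("genus", "family", "order",
                                        "class", "phylum")) {
  pieces <- lapply(ranks, function(r) aggregateTaxa(tc, r))
  tax0 <- taxonomy(tc)
  tax0$unresolved <- FALSE
  mats <- c(list(counts(tc)), lapply(pieces, counts))
  taxs <- c(list(tax0), lapply(pieces, taxonomy))
  m <- do.call(rbind, mats)
  tax <- do.call(rbind, taxs)
  TaxaCounts(m, tax)
}

lineageString <- function(tax) {
  apply(as.matrix(tax[, TAX_RANKS, drop = FALSE]), 1, function(r) {
    r <- r[!is.na(r) & r != ""]
    paste(r, collapse = ";")
  })
}

#' Prevalence and abundance filtering of candidate features
#'
#' A feature is kept iff it is present (count > 0) in strictly more
#' than `min_prevalence` samples AND the median of its counts over
#' the samples where it is present is strictly above `min_median`.
#' Every dropped feature is logged with the failed rule.
#'
#' @param tc candidate [TaxaCounts-class] (see [candidateFeatures()]).
#' @param min_prevalence,min_median strict lower bounds (defaults
#'   100 samples and median count 50).
#' @return A [FeatureSet-class] with the candidate table and filter
#'   log; clusters are assigned by [clusterFeatures()].
#' @export
filterFeatures <- function(tc, min_prevalence = 100, min_median = 50) {
  m <- counts(tc)
  tax <- taxonomy(tc)
  prevalence <- rowSums(m > 0)
  med_present <- apply(m, 1, function(x) {
    x <- x[x > 0]
    if (length(x)) median(x) else 0
  })
  keep <- prevalence > min_prevalence & med_present > min_median
  reason <- rep("ok", nrow(m))
  reason[prevalence <= min_prevalence] <- "low_prevalence"
  reason[prevalence > min_prevalence &
           med_present <= min_median] <- "low_median"
  cand <- data.frame(
    feature_id = rownames(m),
    rank = tax$rank,
    lineage = lineageString(tax),
    prevalence = prevalence,
    median_present = med_present,
    total = rowSums(m),
    kept = keep,
    row.names = NULL, stringsAsFactors = FALSE)
  lg <- data.frame(feature_id = rownames(m),
                   status = ifelse(keep, "kept", "dropped"),
                   reason = reason, row.names = NULL,
                   stringsAsFactors = FALSE)
  new("FeatureSet", candidates = cand,
      clusters = data.frame(feature_id = character(),
                            cluster = integer(),
                            selected = logical()),
      log = lg)
}

# Complete-linkage clustering of a correlation matrix at 1 - cutoff;
# guarantees every within-cluster pair has rho >= cutoff.
clusterFromCorrelation <- function(rho, cutoff) {
  k <- nrow(rho)
  if (k == 1) return(stats::setNames(1L, rownames(rho)))
  d <- 1 - rho
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  cl <- stats::cutree(hc, h = 1 - cutoff)
  cl
}

#' Cluster filtered features by Spearman correlation
#'
#' Pairwise Spearman correlations (average-rank ties) of the kept
#' features across samples are converted to the distance 1 - rho and
#' clustered by complete linkage; the tree is cut at 1 - `rho_cutoff`
#' so that every within-cluster pair correlates at least
#' `rho_cutoff`. Zero-variance features cannot be ranked against
#' anything and become logged singleton clusters.
#'
#' @param fs a [FeatureSet-class] from [filterFeatures()].
#' @param tc the candidate [TaxaCounts-class] the filters ran on.
#' @param rho_cutoff signed Spearman cutoff (default 0.985).
#' @return The [FeatureSet-class] with cluster assignments.
#' @export
clusterFeatures <- function(fs, tc, rho_cutoff = 0.985) {
  kept <- fs@candidates$feature_id[fs@candidates$kept]
  if (!length(kept)) stop("no features passed the filters")
  m <- counts(tc)[kept, , drop = FALSE]
  vars <- apply(m, 1, var)
  lg <- fs@log
  const <- vars == 0
  if (any(const)) {
    lg <- rbind(lg, data.frame(
      feature_id = kept[const], status = "singleton",
      reason = "zero_variance", stringsAsFactors = FALSE))
  }
  varying <- kept[!const]
  cl <- integer(0)
  if (length(varying) > 1) {
    rho <- cor(t(m[varying, , drop = FALSE]), method = "spearman")
    cl <- clusterFromCorrelation(rho, rho_cutoff)
  } else if (length(varying) == 1) {
    cl <- stats::setNames(1L, varying)
  }
  n_cl <- if (length(cl)) max(cl) else 0L
  assign <- c(cl, stats::setNames(n_cl + seq_len(sum(const)),
                                  kept[const]))
  clusters <- data.frame(feature_id = names(assign),
                         cluster = as.integer(assign),
                         selected = FALSE,
                         row.names = NULL, stringsAsFactors = FALSE)
  new("FeatureSet", candidates = fs@candidates, clusters = clusters,
      log = lg)
}

#' Select one representative per cluster
#'
#' Within each cluster the feature of the lowest (most specific)
#' taxonomic rank is selected — ASV below species below genus ... —
#' with ties at the same rank broken by the highest total count and
#' then lexicographic feature id.
#'
#' @param fs a clustered [FeatureSet-class].
#' @return The [FeatureSet-class] with `selected` marked; retrieve
#'   the final set with [selectedFeatures()].
#' @export
selectRepresentatives <- function(fs) {
  cl <- fs@clusters
  if (!nrow(cl)) stop("no clusters assigned; run clusterFeatures()")
  cand <- fs@candidates
  idx <- match(cl$feature_id, cand$feature_id)
  depth <- RANK_DEPTH[cand$rank[idx]]
  total <- cand$total[idx]
  cl$selected <- FALSE
  for (g in unique(cl$cluster)) {
    rows <- which(cl$cluster == g)
    ord <- rows[order(-depth[rows], -total[rows],
                      cl$feature_id[rows])]
    cl$selected[ord[1]] <- TRUE
  }
  new("FeatureSet", candidates = fs@candidates, clusters = cl,
      log = fs@log)
}

#' Plan of association scans
#'
#' One univariate abundance scan per feature cluster (its selected
#' representative) plus one beta-diversity scan: the accounting that
#' defines the number of GWAS performed (and hence the study-wide
#' multiplicity correction).
#'
#' @param fs a [FeatureSet-class] with representatives selected.
#' @return data.frame with columns `scan`, `type`
#'   (`"abundance"`/`"beta_diversity"`) and `feature_id`.
#' @export
scanPlan <- function(fs) {
  sel <- selectedFeatures(fs)
  rbind(
    data.frame(scan = paste0("abundance:", sel$feature_id),
               type = "abundance", feature_id = sel$feature_id,
               stringsAsFactors = FALSE),
    data.frame(scan = "beta_diversity", type = "beta_diversity",
               feature_id = NA_character_,
               stringsAsFactors = FALSE))
}

#' Run the full feature-construction pipeline
#'
#' Agglomerates, filters, clusters and selects representatives in one
#' call.
#'
#' @param tc ASV-level [TaxaCounts-class].
#' @param min_prevalence,min_median,rho_cutoff see the step
#'   functions.
#' @return list with the final [FeatureSet-class] (`features`) and
#'   the candidate [TaxaCounts-class] (`candidates`) whose rows the
#'   univariate scans model.
#' @export
buildFeatureSet <- function(tc, min_prevalence = 100, min_median = 50,
                            rho_cutoff = 0.985) {
  cand_tc <- candidateFeatures(tc)
  fs <- filterFeatures(cand_tc, min_prevalence, min_median)
  fs <- clusterFeatures(fs, cand_tc, rho_cutoff)
  fs <- selectRepresentatives(fs)
  list(features = fs, candidates = cand_tc)
}
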