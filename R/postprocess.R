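# Significance calling, locus grouping, LD, nearest-gene annotation
# and genome-wide diagnostics.

#' Flag genome-wide and study-wide significant associations
#'
#' Genome-wide significance is `p <= alpha_gw` (default 5e-8);
#' study-wide significance divides the genome-wide level by the
#' number of scans performed, unless an explicit `alpha_sw` is given
#' (the study default 1.19e-9).
#'
#' @param assoc association data.frame with a `p` column.
#' @param alpha_gw genome-wide threshold.
#' @param n_tests number of association scans performed.
#' @param alpha_sw explicit study-wide threshold overriding
#'   `alpha_gw / n_tests`.
#' @return `assoc` with logical columns `genome_wide` and
#'   `study_wide`.
#' @export
applyThresholds <- function(assoc, alpha_gw = 5e-8, n_tests = NULL,
                            alpha_sw = NULL) {
  if (is.null(alpha_sw)) {
    if (is.null(n_tests) || n_tests < 1)
      stop("give n_tests or an explicit alpha_sw")
    alpha_sw <- alpha_gw / n_tests
  }
  assoc$genome_wide <- !is.na(assoc$p) & assoc$p <= alpha_gw
  assoc$study_wide <- !is.na(assoc$p) & assoc$p <= alpha_sw
  attr(assoc, "alpha_gw") <- alpha_gw
  attr(assoc, "alpha_sw") <- alpha_sw
  assoc
}

#' Group significant variants into loci
#'
#' Greedy clumping: the unassigned significant variant with the
#' smallest p becomes a lead, and all unassigned significant variants
#' on the same chromosome within half the window of it join its
#' locus; repeat until none remain. Ties on p break by position, then
#' id. With the default 1 Mb window, members lie within +/- 500 kb of
#' their lead.
#'
#' @param sig data.frame of significant variants with columns `id`,
#'   `chrom`, `pos`, `p` (and optionally `beta`, `a1`, `a2`,
#'   `feature_name`, `feature_rank`).
#' @param window_bp total window span (default 1e6).
#' @param genes optional `GRanges` from [readGenesBed()] for
#'   nearest-gene naming.
#' @return data.frame, one row per locus: chrom, window start/end,
#'   lead id/p, members (comma-joined ids), n_members, nearest gene
#'   and distance when `genes` given, plus any feature columns of the
#'   lead.
#' @export
groupLoci <- function(sig, window_bp = 1e6, genes = NULL) {
  if (!nrow(sig)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), lead_id = character(),
                      lead_p = numeric(), members = character(),
                      n_members = integer())
    return(out)
  }
  sig <- sig[order(sig$p, sig$pos, sig$id), , drop = FALSE]
  half <- window_bp / 2
  assigned <- rep(FALSE, nrow(sig))
  loci <- list()
  while (!all(assigned)) {
    lead <- which(!assigned)[1]
    in_win <- !assigned & sig$chrom == sig$chrom[lead] &
      abs(sig$pos - sig$pos[lead]) <= half
    members <- sig[in_win, , drop = FALSE]
    assigned[in_win] <- TRUE
    row <- data.frame(
      chrom = sig$chrom[lead],
      start = sig$pos[lead] - half, end = sig$pos[lead] + half,
      lead_id = sig$id[lead], lead_p = sig$p[lead],
      members = paste(members$id, collapse = ","),
      n_members = nrow(members), stringsAsFactors = FALSE)
    for (cc in intersect(c("beta", "a1", "a2", "feature_name",
                           "feature_rank"), colnames(sig)))
      row[[paste0("lead_", cc)]] <- sig[[cc]][lead]
    if (!is.null(genes)) {
      ng <- nearestGene(sig$chrom[lead], sig$pos[lead], genes)
      row$gene <- ng$gene
      row$gene_distance <- ng$distance
    }
    loci[[length(loci) + 1]] <- row
  }
  out <- do.call(rbind, loci)
  rownames(out) <- NULL
  out
}

#' Squared LD correlation between two dosage vectors
#'
#' Squared Pearson correlation over pairwise-complete samples; `NA`
#' when either vector is constant on the shared calls.
#'
#' @param g1,g2 dosage vectors of equal length.
#' @return r-squared in \[0, 1\] or `NA`.
#' @export
ldR2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Genomic inflation factor
#'
#' lambda_GC = median of the 1-df chi-square quantiles of the
#' p-values, divided by the null median 0.4549364. Values near 1
#' indicate calibrated tests.
#'
#' @param pvals p-values in (0, 1].
#' @return lambda_GC.
#' @examples
#' genomicInflation(runif(1e4))
#' @export
genomicInflation <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (!length(pvals)) stop("no p-values")
  stopifnot(all(pvals > 0), all(pvals <= 1))
  chi <- qchisq(pvals, df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1)
}

#' Nearest gene to a genomic position
#'
#' Distance 0 when the position falls inside a gene; otherwise the
#' minimal gap to an interval end on the same chromosome. Ties break
#' by the smaller gene start.
#'
#' @param chrom chromosome label.
#' @param pos 1-based position.
#' @param genes `GRanges` with a `name` column ([readGenesBed()]).
#' @return list with `gene` (name or `NA`) and `distance` (bp).
#' @export
nearestGene <- function(chrom, pos, genes) {
  on_chr <- genes[as.character(GenomicRanges::seqnames(genes)) ==
                    as.character(chrom)]
  if (!length(on_chr)) {
    warning("no genes on chromosome ", chrom)
    return(list(gene = NA_character_, distance = NA_real_))
  }
  st <- GenomicRanges::start(on_chr)
  en <- GenomicRanges::end(on_chr)
  dist <- ifelse(pos >= st & pos <= en, 0,
                 pmin(abs(pos - st), abs(pos - en)))
  ord <- order(dist, st)
  list(gene = on_chr$name[ord[1]], distance = dist[ord[1]])
}

#' Manhattan- and QQ-plot data tables
#'
#' Pure data transforms for plotting: `manhattanData` returns one row
#' per variant (chrom, pos, p, feature); `qqData` the sorted expected
#' vs observed -log10 p.
#'
#' @param assoc association data.frame with `chrom`, `pos`, `p` (and
#'   optionally `feature_name`).
#' @return data.frame ready for plotting.
#' @export
manhattanData <- function(assoc) {
  data.frame(chrom = assoc$chrom, pos = assoc$pos, p = assoc$p,
             feature = if ("feature_name" %in% colnames(assoc))
               assoc$feature_name else NA_character_,
             stringsAsFactors = FALSE)
}

#' @rdname manhattanData
#' @export
qqData <- function(assoc) {
  p <- sort(assoc$p[!is.na(assoc$p)])
  n <- length(p)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n),
             observed = -log10(p))
}
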