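# PheWAS-style lookups: allele-aligned Z scores of lead variants in
# external GWAS summary statistics, with FDR-controlled flags.

#' Align an external effect estimate to the counted allele
#'
#' Z = beta/se when the external record's effect allele equals the
#' query's counted (A2) allele; the sign flips when the alleles are
#' swapped; allele sets that differ give a missing Z with reason
#' `"allele_mismatch"`. Palindromic pairs (A/T, C/G) are aligned by
#' label but flagged `"ambiguous"` — no strand flipping is attempted.
#'
#' @param a1,a2 the query variant's non-counted and counted alleles.
#' @param effect_allele,other_allele,beta,se the external record.
#' @return list: `z` (or `NA`), `flag` (`""`, `"ambiguous"`,
#'   `"allele_mismatch"`).
#' @examples
#' alignZ("T", "C", effect_allele = "C", other_allele = "T",
#'        beta = 0.2, se = 0.1)  # z = 2
#' @export
alignZ <- function(a1, a2, effect_allele, other_allele, beta, se) {
  if (!is.finite(se) || se <= 0) stop("standard error must be > 0")
  up <- toupper
  a1 <- up(a1); a2 <- up(a2)
  ea <- up(effect_allele); oa <- up(other_allele)
  flag <- ""
  pal <- function(x, y) (x == "A" && y == "T") ||
    (x == "T" && y == "A") || (x == "C" && y == "G") ||
    (x == "G" && y == "C")
  if (pal(a1, a2)) flag <- "ambiguous"
  if (ea == a2 && oa == a1) {
    z <- beta / se
  } else if (ea == a1 && oa == a2) {
    z <- -beta / se
  } else {
    return(list(z = NA_real_, flag = "allele_mismatch"))
  }
  list(z = z, flag = flag)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment, preserving input
#' order: q(i) = min over j with p(j) >= p(i) of m * p(j) / rank(j).
#'
#' @param pvals p-values in (0, 1].
#' @return adjusted p-values in input order.
#' @examples
#' fdrBH(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdrBH <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Look lead variants up in external trait summary statistics
#'
#' For every (lead variant, trait) pair with a record in the trait's
#' summary statistics, the allele-aligned Z score and its two-sided
#' normal p are computed; p < 0.05 is flagged suggestive and
#' FDR-adjusted p < 0.05 significant, with the FDR family spanning
#' the whole available variant-by-trait grid. Variants absent from a
#' trait's table get `available = FALSE` and no flags.
#'
#' External tables use a normalized schema with columns `id`,
#' `effect_allele`, `other_allele`, `beta`, `se` (and optionally
#' `p`).
#'
#' @param leads data.frame of lead variants with columns `id`, `a1`,
#'   `a2` (a2 = counted allele).
#' @param traits named list of external summary-statistic
#'   data.frames, one per trait.
#' @return data.frame, one row per (variant, trait): `id`, `trait`,
#'   `available`, `z`, `p`, `suggestive`, `significant`, `flag`.
#' @export
traitLookup <- function(leads, traits) {
  stopifnot(all(c("id", "a1", "a2") %in% colnames(leads)),
            length(names(traits)) == length(traits))
  rows <- list()
  for (tr in names(traits)) {
    tab <- traits[[tr]]
    for (i in seq_len(nrow(leads))) {
      rec <- tab[tab$id == leads$id[i], , drop = FALSE]
      if (!nrow(rec)) {
        rows[[length(rows) + 1]] <- data.frame(
          id = leads$id[i], trait = tr, available = FALSE,
          z = NA_real_, p = NA_real_, suggestive = NA,
          significant = NA, flag = "unavailable",
          stringsAsFactors = FALSE)
        next
      }
      al <- alignZ(leads$a1[i], leads$a2[i],
                   rec$effect_allele[1], rec$other_allele[1],
                   rec$beta[1], rec$se[1])
      p <- if (is.na(al$z)) NA_real_ else
        2 * pnorm(abs(al$z), lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        id = leads$id[i], trait = tr, available = !is.na(al$z),
        z = al$z, p = p, suggestive = NA, significant = NA,
        flag = al$flag, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  ok <- out$available & !is.na(out$p)
  if (any(ok)) {
    out$suggestive[ok] <- out$p[ok] < 0.05
    out$significant[ok] <- fdrBH(out$p[ok]) < 0.05
  }
  out
}
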