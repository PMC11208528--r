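# Beta-diversity GWAS: rarefaction, Bray-Curtis dissimilarity, Gower
# centering, covariate partialling, and the per-variant
# distance-based F-test (DBF-test) with a Pearson type III
# approximation to the permutation null.

#' Rarefy a count table to even depth
#'
#' Each sample is subsampled to exactly `depth` reads without
#' replacement from the multinomial of its counts; samples with fewer
#' than `depth` total reads are dropped and recorded in the
#' `"dropped_samples"` attribute. Deterministic given `seed`.
#'
#' @param tc a [TaxaCounts-class].
#' @param depth target reads per sample (default 5000).
#' @param seed integer seed.
#' @return A rarefied [TaxaCounts-class].
#' @export
rarefyCounts <- function(tc, depth = 5000, seed = 1) {
  if (depth <= 0) stop("depth must be positive")
  m <- counts(tc)
  totals <- colSums(m)
  keep <- totals >= depth
  dropped <- colnames(m)[!keep]
  if (!any(keep)) stop("no sample reaches the rarefaction depth")
  sub <- t(m[, keep, drop = FALSE])
  rar <- withr::with_seed(as.integer(seed), withCallingHandlers(
    vegan::rrarefy(sub, sample = depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  out <- TaxaCounts(t(rar), taxonomy(tc))
  attr(out, "dropped_samples") <- dropped
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(u, v) = sum_j |u_j - v_j| / sum_j (u_j + v_j) over the feature
#' counts of each sample pair; 0 for identical samples, 1 for
#' disjoint support.
#'
#' @param tc a [TaxaCounts-class] (typically rarefied).
#' @return symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
brayCurtis <- function(tc) {
  m <- t(counts(tc))
  if (nrow(m) < 2) stop("need at least two samples")
  zero <- rowSums(m) == 0
  if (any(zero))
    stop("all-zero sample(s): ",
         paste(rownames(m)[zero], collapse = ", "))
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Gower-center a dissimilarity matrix
#'
#' Forms G = J A J with A = -D^2/2 elementwise and J = I - 11'/n, the
#' doubly centered inner-product matrix underlying principal
#' coordinates analysis and the distance-based F-test. For a
#' Euclidean D this is the centered Gram matrix of the points.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @return A [GowerMatrix-class] with `q = 0`.
#' @examples
#' gowerCenter(matrix(c(0, 1, 1, 0), 2, 2))
#' @export
gowerCenter <- function(D) {
  D <- as.matrix(D)
  stopifnot(nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-12) stop("D must be symmetric")
  A <- -0.5 * D * D
  n <- nrow(A)
  G <- A - matrix(rowMeans(A), n, n) -
    matrix(colMeans(A), n, n, byrow = TRUE) + mean(A)
  G <- (G + t(G)) / 2
  dimnames(G) <- dimnames(D)
  new("GowerMatrix", mat = G, q = 0L)
}

#' Partial covariates out of a Gower matrix
#'
#' Projects the Gower matrix onto the residual space of the covariate
#' design: G_res = R G R with R = I - X (X'X)^-1 X' and X the
#' intercept-plus-covariates design. This is the distance-based
#' redundancy "Condition()" step: the residual structure the DBF-test
#' then interrogates.
#'
#' @param Gm a [GowerMatrix-class].
#' @param covariates covariate data.frame aligned to the rows of
#'   `Gm` (same sample ids), or a pre-built design matrix with
#'   intercept.
#' @return A [GowerMatrix-class] with `q` = number of non-intercept
#'   design columns.
#' @export
partialOutCovariates <- function(Gm, covariates) {
  G <- gowerValues(Gm)
  X <- if (is.matrix(covariates)) covariates
       else buildDesign(covariates[rownames(G), , drop = FALSE])
  stopifnot(nrow(X) == nrow(G))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  G1 <- qr.resid(qrX, G)
  G2 <- t(qr.resid(qrX, t(G1)))
  G2 <- (G2 + t(G2)) / 2
  dimnames(G2) <- dimnames(G)
  new("GowerMatrix", mat = G2, q = ncol(X) - 1L)
}

# Re-center a subsetted Gower matrix (centering must match the tested
# sample set for the trace identities to hold).
recenterGower <- function(M) {
  n <- nrow(M)
  G <- M - matrix(rowMeans(M), n, n) -
    matrix(colMeans(M), n, n, byrow = TRUE) + mean(M)
  (G + t(G)) / 2
}

# Exact permutation mean and variance of Q = x' G x for a doubly
# centered symmetric G and a centered x under uniform relabeling.
# Derived from the permutation moments of quadratic forms using the
# zero row-sum structure (sum_j G_ij = 0, sum_i x_i = 0); verified
# against full enumeration at small n.
permMomentsQuad <- function(G, x) {
  n <- length(x)
  S2 <- sum(x^2); S4 <- sum(x^4)
  Tg <- sum(diag(G))
  Sd2 <- sum(diag(G)^2)
  F2 <- sum(G^2) - Sd2
  m <- Tg * S2 / (n - 1)
  EB2 <- Sd2 * S4 / n + (Tg^2 - Sd2) * (S2^2 - S4) / (n * (n - 1))
  EAB <- 2 * Sd2 * S4 / (n * (n - 1)) +
    (2 * Sd2 - Tg^2) * (2 * S4 - S2^2) / (n * (n - 1) * (n - 2))
  EA2 <- 2 * F2 * (S2^2 - S4) / (n * (n - 1)) +
    4 * (Sd2 - F2) * (2 * S4 - S2^2) / (n * (n - 1) * (n - 2)) +
    (Tg^2 - 4 * Sd2 + 2 * F2) * (3 * S2^2 - 6 * S4) /
      (n * (n - 1) * (n - 2) * (n - 3))
  v <- EA2 + 2 * EAB + EB2 - m^2
  list(mean = m, var = max(v, 0))
}

# Upper-tail p of a Pearson type III distribution matched to the
# moments (m, s, skewness g1) of the permutation null, evaluated at x.
pearson3Tail <- function(x, m, s, g1) {
  z <- (x - m) / s
  if (!is.finite(g1) || abs(g1) < 1e-8)
    return(pnorm(z, lower.tail = FALSE))
  a <- 4 / g1^2
  if (g1 > 0)
    pgamma(a + sqrt(a) * z, shape = a, lower.tail = FALSE)
  else
    pgamma(a - sqrt(a) * z, shape = a, lower.tail = TRUE)
}

#' Distance-based F-test of a genotype against a Gower matrix
#'
#' Tests association between a single (genotype dosage) vector and
#' the community structure in a covariate-partialled Gower matrix,
#' without ordination. With x the centered genotype and
#' H = xx'/(x'x) its hat matrix, the statistic is
#'
#'   pseudo-F = tr(H G H) / \[ tr((I-H) G (I-H)) / (n - q - 2) \]
#'
#' where q covariate columns were already projected out of G. The
#' analytic p-value fits a Pearson type III distribution to the mean,
#' variance and skewness of the permutation distribution of the
#' numerator tr(H G H) (label permutations of x; the denominator is
#' tr(G) minus the numerator, so the numerator is pivotal). A direct
#' permutation p-value `(1 + #\{F_perm >= F_obs\}) / (1 + n_perm)` is
#' returned when `n_perm > 0`.
#'
#' @param Gm a [GowerMatrix-class] (rows/cols must match `g`).
#' @param g genotype (or any single-predictor) vector, non-constant.
#' @param n_perm permutations for the direct p (0 = analytic only).
#' @param n_moment_perm permutations used to estimate the Pearson III
#'   moments (>= 1000 recommended).
#' @param method `"pearson3"` (default) or `"permutation"` (use the
#'   permutation p as primary).
#' @param seed integer seed for the permutation draws.
#' @return list of class `DBFResult`: `pseudo_F`, `p_analytic`,
#'   `p_perm` (or `NA`), `n_perm`, `df_denom`, `method`.
#' @export
dbfTest <- function(Gm, g, n_perm = 0, n_moment_perm = 1000,
                    method = c("pearson3", "permutation"), seed = 1) {
  method <- match.arg(method)
  G <- gowerValues(Gm)
  q <- nPartialled(Gm)
  stopifnot(length(g) == nrow(G))
  miss <- is.na(g)
  if (any(miss)) {
    g <- g[!miss]
    G <- recenterGower(G[!miss, !miss, drop = FALSE])
  }
  n <- length(g)
  if (n - q - 2 <= 0) stop("not enough samples: n - q - 2 <= 0")
  if (var(g) == 0) stop("monomorphic predictor")
  x <- g - mean(g)
  cxx <- sum(x^2)
  trG <- sum(diag(G))
  Gx <- G %*% x
  s_obs <- sum(x * Gx) / cxx          # tr(H G H)
  denom <- (trG - s_obs) / (n - q - 2)
  pseudo_F <- s_obs / denom
  B <- as.integer(max(n_moment_perm, n_perm))
  perms <- withr::with_seed(as.integer(seed), {
    idx <- replicate(B, sample.int(n))
    P <- matrix(x[idx], n, B)
    colSums(P * (G %*% P)) / cxx
  })
  # mean and variance of the numerator under relabeling are exact
  # trace identities; only the skewness is estimated by Monte Carlo
  if (n >= 5) {
    mom <- permMomentsQuad(G, x)
    m1 <- mom$mean / cxx
    sdev <- sqrt(mom$var) / cxx
  } else {  # too few samples for the n-3 identity
    m1 <- mean(perms)
    sdev <- sd(perms)
  }
  # skewness from every permutation drawn (n_moment_perm at least)
  g1 <- mean((perms - m1)^3) / sdev^3
  p_analytic <- pearson3Tail(s_obs, m1, sdev, g1)
  p_analytic <- min(max(p_analytic, .Machine$double.xmin), 1)
  p_perm <- NA_real_
  if (n_perm > 0) {
    s_perm <- perms[seq_len(n_perm)]
    p_perm <- (1 + sum(s_perm >= s_obs - 1e-12)) / (1 + n_perm)
  }
  structure(list(
    pseudo_F = pseudo_F,
    p_analytic = p_analytic,
    p_perm = p_perm,
    n_perm = as.integer(n_perm),
    df_denom = n - q - 2,
    stat = s_obs,
    method = if (method == "pearson3") "pearson3-moment"
             else "permutation"), class = "DBFResult")
}

#' @export
print.DBFResult <- function(x, ...) {
  cat(sprintf("DBF-test: pseudo-F = %.4g (df2 = %d), p = %.3g [%s]\n",
              x$pseudo_F, x$df_denom, x$p_analytic, x$method))
  if (!is.na(x$p_perm))
    cat(sprintf("  permutation p = %.3g (%d permutations)\n",
                x$p_perm, x$n_perm))
  invisible(x)
}

#' Beta-diversity scan over genotype variants
#'
#' Runs the DBF-test per QC-passing variant. For variants with
#' missing calls the Gower matrix is subset to the called samples and
#' re-centered before testing.
#'
#' @param Gm a (covariate-partialled) [GowerMatrix-class].
#' @param G a [GenotypeMatrix-class].
#' @param keep logical QC mask (use [variantQC()] with
#'   `r2_min = 0.6` for this arm); default all.
#' @param n_moment_perm moment permutations per variant.
#' @param seed integer seed.
#' @return data.frame: id, chrom, pos, a1, a2, pseudo_F, p, n, flag.
#' @export
snpScanBeta <- function(Gm, G, keep = NULL, n_moment_perm = 1000,
                        seed = 1) {
  Gmat <- gowerValues(Gm)
  d <- dosage(G)
  v <- as.data.frame(variantInfo(G))
  shared <- intersect(rownames(Gmat), rownames(d))
  if (!length(shared)) stop("no shared samples")
  if (!identical(rownames(Gmat), shared)) {
    Gmat <- recenterGower(Gmat[shared, shared, drop = FALSE])
    Gm <- new("GowerMatrix", mat = Gmat, q = nPartialled(Gm))
  }
  d <- d[shared, , drop = FALSE]
  if (is.null(keep)) keep <- rep(TRUE, ncol(d))
  if (is.null(names(keep))) names(keep) <- colnames(d)
  cols <- which(keep[colnames(d)])
  out <- data.frame(
    id = v$id[cols], chrom = v$chrom[cols], pos = v$pos[cols],
    a1 = v$ref[cols], a2 = v$alt[cols],
    pseudo_F = NA_real_, p = NA_real_, n = NA_integer_,
    flag = "", stringsAsFactors = FALSE)
  for (k in seq_along(cols)) {
    g <- d[, cols[k]]
    res <- tryCatch(
      dbfTest(Gm, g, n_moment_perm = n_moment_perm,
              seed = seed + k),
      error = function(e) e)
    out$n[k] <- sum(!is.na(g))
    if (inherits(res, "error")) {
      out$flag[k] <- conditionMessage(res)
      next
    }
    out$pseudo_F[k] <- res$pseudo_F
    out$p[k] <- res$p_analytic
  }
  out
}

#' Run the beta-diversity GWAS
#'
#' Rarefies the ASV counts to even depth, computes Bray-Curtis
#' dissimilarities, Gower-centers them, partials out the covariates,
#' and scans the QC-passing variants (imputation R2 filter active in
#' this arm) with the DBF-test.
#'
#' @param asv_counts ASV-level [TaxaCounts-class].
#' @param G a [GenotypeMatrix-class].
#' @param covariates covariate data.frame.
#' @param depth rarefaction depth (default 5000).
#' @param r2_min imputation-quality threshold (default 0.6).
#' @param n_moment_perm moment permutations per variant.
#' @param seed integer seed (rarefaction and permutations).
#' @return list with `assoc` (scan table), `qc`, `gower` (the
#'   partialled [GowerMatrix-class]) and `dropped_samples`.
#' @export
runBetaGwas <- function(asv_counts, G, covariates, depth = 5000,
                        r2_min = 0.6, n_moment_perm = 1000,
                        seed = 1) {
  rar <- rarefyCounts(asv_counts, depth = depth, seed = seed)
  D <- brayCurtis(rar)
  Gm <- gowerCenter(D)
  covs <- covariates[rownames(gowerValues(Gm)), , drop = FALSE]
  Gm <- partialOutCovariates(Gm, covs)
  qc <- variantQC(G, r2_min = r2_min)
  assoc <- snpScanBeta(Gm, G, qc$keep,
                       n_moment_perm = n_moment_perm,
                       seed = seed + 1000L)
  list(assoc = assoc, qc = qc, gower = Gm,
       dropped_samples = attr(rar, "dropped_samples"))
}
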