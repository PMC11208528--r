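# Univariate abundance GWAS: Hardy-Weinberg exact test, variant QC,
# the covariate-adjusted negative-binomial fit with offset,
# randomized-quantile (Dunn-Smyth) residuals, and the per-variant
# linear scan of residuals on allele dosage.

#' Hardy-Weinberg exact test
#'
#' Exact two-sided p-value for departure from Hardy-Weinberg genotype
#' proportions: conditioning on the observed allele counts, the
#' probabilities of all possible heterozygote counts are enumerated
#' and those no more probable than the observed configuration are
#' summed.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return p-value in (0, 1].
#' @examples
#' hweExactP(1, 0, 1)  # 1/3
#' @export
hweExactP <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("no genotype calls")
  n_a <- 2 * n_hom_ref + n_het   # reference-allele count
  n_b <- 2 * n_hom_alt + n_het
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)  # feasible het counts
  # P(het = h | allele counts) up to a constant:
  # n! / (nAA! nAa! naa!) * 2^h ; work in logs
  logp <- vapply(hets, function(h) {
    haa <- (rare - h) / 2
    hbb <- n - h - haa
    lgamma(n + 1) - lgamma(haa + 1) - lgamma(h + 1) -
      lgamma(hbb + 1) + h * log(2)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  sum(p[p <= obs + 1e-12])
}

#' Variant quality control
#'
#' Per variant: MAF computed over non-missing calls as
#' `min(f_alt, 1 - f_alt)`, call rate, and the Hardy-Weinberg exact
#' p-value. A variant is kept iff MAF > `maf_min` (strict), call rate
#' > `callrate_min` (strict), HWE p >= `hwe_alpha`, and — when
#' `r2_min` is given (the beta-diversity arm) — imputation R2 >
#' `r2_min`. Variants with no calls are dropped with reason
#' `"no_calls"`.
#'
#' @param G a [GenotypeMatrix-class].
#' @param maf_min,callrate_min,hwe_alpha,r2_min thresholds (defaults
#'   0.05, 0.95, 0.005; `r2_min = NULL` skips the imputation filter).
#' @return list with `keep` (named logical), `report` (per-variant
#'   metrics and first failed rule) and `drop_counts` (per rule).
#' @export
variantQC <- function(G, maf_min = 0.05, callrate_min = 0.95,
                      hwe_alpha = 0.005, r2_min = NULL) {
  d <- dosage(G)
  v <- as.data.frame(variantInfo(G))
  n <- nrow(d)
  ncall <- colSums(!is.na(d))
  callrate <- ncall / n
  falt <- colSums(d, na.rm = TRUE) / (2 * pmax(ncall, 1))
  maf <- pmin(falt, 1 - falt)
  hwe <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    hweExactP(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  reason <- rep("pass", ncol(d))
  if (!is.null(r2_min)) {
    r2 <- if ("impR2" %in% colnames(v)) v$impR2 else
      rep(NA_real_, ncol(d))
    reason[is.na(r2) | r2 <= r2_min] <- "low_imputation_r2"
  }
  reason[!is.na(hwe) & hwe < hwe_alpha] <- "hwe_fail"
  reason[callrate <= callrate_min] <- "low_callrate"
  reason[maf <= maf_min] <- "low_maf"
  reason[ncall == 0] <- "no_calls"
  keep <- reason == "pass"
  names(keep) <- colnames(d)
  report <- data.frame(
    id = colnames(d), maf = maf, callrate = callrate, hwe_p = hwe,
    impR2 = if ("impR2" %in% colnames(v)) v$impR2 else NA_real_,
    keep = keep, reason = reason,
    row.names = NULL, stringsAsFactors = FALSE)
  drop_counts <- table(factor(reason[!keep],
    levels = c("low_maf", "low_callrate", "hwe_fail",
               "low_imputation_r2", "no_calls")))
  list(keep = keep, report = report, drop_counts = drop_counts)
}

#' Fit the covariate-adjusted negative-binomial abundance model
#'
#' The zero-truncated, non-rarefied counts of one taxon (samples with
#' a positive count and complete covariates) are fit by a
#' negative-binomial GLM with log link, the full covariate design
#' (sex, age, BMI, smoking, alcohol, glycemic state, sequencing run,
#' ten genetic PCs) and the log of each sample's total sequence count
#' as offset. Variance parameterization Var = mu + mu^2/theta; beta
#' and theta are estimated by alternating IRLS and univariate score
#' iterations ([MASS::glm.nb]).
#'
#' @param y named integer vector of taxon counts per sample.
#' @param covariates covariate data.frame (rownames = sample ids);
#'   `NULL` fits an intercept-only model.
#' @param offset named numeric vector, log total sequence counts per
#'   sample (default 0).
#' @return An object of class `NBFit`: coefficients, `theta`, fitted
#'   `mu`, `offset`, `converged`, `n_used`, `samples` used.
#' @export
fitNbGlm <- function(y, covariates = NULL, offset = NULL) {
  if (is.null(names(y))) names(y) <- paste0("s", seq_along(y))
  if (is.null(offset)) offset <- setNames(rep(0, length(y)), names(y))
  keep <- names(y)[y[names(y)] > 0]
  if (!is.null(covariates))
    keep <- intersect(keep, completeCovariateSamples(covariates))
  yk <- y[keep]
  ok <- offset[keep]
  if (is.null(covariates)) {
    dat <- data.frame(y = as.numeric(yk), off = as.numeric(ok))
    form <- y ~ 1 + offset(off)
    p <- 1
  } else {
    X <- covariates[keep, , drop = FALSE]
    dat <- cbind(data.frame(y = as.numeric(yk), off = as.numeric(ok)),
                 X)
    form <- stats::as.formula(paste(
      "y ~", paste(COVARIATE_COLS, collapse = " + "), "+ offset(off)"))
    p <- ncol(buildDesign(X))
  }
  if (length(yk) <= p)
    stop("not enough positive-count samples (", length(yk),
         ") for ", p, " model columns")
  converged <- TRUE
  fit <- withCallingHandlers(
    tryCatch(MASS::glm.nb(form, data = dat),
             error = function(e) e),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error"))
    stop("negative-binomial fit failed: ", conditionMessage(fit))
  if (!isTRUE(fit$converged)) converged <- FALSE
  structure(list(
    coefficients = stats::coef(fit),
    theta = fit$theta,
    mu = setNames(stats::fitted(fit), keep),
    offset = ok,
    converged = converged,
    n_used = length(keep),
    samples = keep,
    glm = fit), class = "NBFit")
}

#' @export
print.NBFit <- function(x, ...) {
  cat("Negative-binomial abundance fit:", x$n_used, "samples,",
      "theta =", format(x$theta, digits = 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Randomized-quantile (Dunn-Smyth) residuals
#'
#' For each retained sample, a uniform draw between the fitted NB CDF
#' at y-1 and at y is transformed by the standard-normal quantile
#' function. Under a correctly specified model these residuals are
#' standard normal. The draw is deterministic given `seed`; uniforms
#' are clipped to [1e-12, 1 - 1e-12].
#'
#' @param fit an `NBFit` from [fitNbGlm()].
#' @param y the full count vector the model was fit to.
#' @param seed integer seed.
#' @return named numeric vector of residuals (class
#'   `ResidualVector`), one per sample used in the fit.
#' @export
dunnSmythResiduals <- function(fit, y, seed = 1) {
  if (!fit$converged)
    warning("residuals from a non-converged fit")
  yk <- y[fit$samples]
  lo <- pnbinom(yk - 1, mu = fit$mu, size = fit$theta)
  hi <- pnbinom(yk, mu = fit$mu, size = fit$theta)
  u <- withr::with_seed(as.integer(seed),
                        runif(length(yk), min = lo, max = hi))
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  r <- qnorm(u)
  names(r) <- fit$samples
  structure(r, residual_type = "dunn-smyth", seed = as.integer(seed))
}

#' Pearson residuals of an NB fit
#'
#' (y - mu) / sqrt(mu + mu^2/theta); offered as a configurable
#' alternative to the randomized-quantile default.
#'
#' @inheritParams dunnSmythResiduals
#' @return named numeric vector.
#' @export
pearsonResiduals <- function(fit, y) {
  yk <- y[fit$samples]
  r <- (yk - fit$mu) / sqrt(fit$mu + fit$mu^2 / fit$theta)
  structure(r, residual_type = "pearson")
}

#' Scan residuals over genotype variants
#'
#' For every QC-passing variant, the taxon residuals are regressed on
#' the alt-allele dosage by simple linear regression on the samples
#' with a non-missing call at that variant: beta =
#' sum((g - gbar)(r - rbar)) / sum((g - gbar)^2), se from the
#' residual variance with n - 2 df, p the two-sided t tail. The
#' effect is reported for the alternative (A2) allele. Variants
#' monomorphic in the analysis subset get a missing p with a reason;
#' a perfect fit (zero residual sum of squares) is flagged
#' `degenerate_fit` with p reported as the 0 limit.
#'
#' @param r residual vector (named by sample).
#' @param G a [GenotypeMatrix-class].
#' @param keep logical mask of QC-passing variants (default all).
#' @return data.frame: id, chrom, pos, a1 (ref), a2 (alt), beta, se,
#'   t, p, n, flag.
#' @export
snpScanUnivariate <- function(r, G, keep = NULL) {
  d <- dosage(G)
  v <- as.data.frame(variantInfo(G))
  if (is.null(keep)) keep <- rep(TRUE, ncol(d))
  if (is.null(names(keep))) names(keep) <- colnames(d)
  use_samples <- intersect(names(r), rownames(d))
  d <- d[use_samples, , drop = FALSE]
  r <- r[use_samples]
  cols <- which(keep[colnames(d)])
  out <- data.frame(
    id = v$id[cols], chrom = v$chrom[cols], pos = v$pos[cols],
    a1 = v$ref[cols], a2 = v$alt[cols],
    beta = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
    n = NA_integer_, flag = "", stringsAsFactors = FALSE)
  for (k in seq_along(cols)) {
    g <- d[, cols[k]]
    ok <- !is.na(g)
    gk <- g[ok]; rk <- r[ok]
    n <- length(gk)
    out$n[k] <- n
    sxx <- sum((gk - mean(gk))^2)
    if (n < 3 || sxx == 0) {
      out$flag[k] <- "monomorphic"
      next
    }
    beta <- sum((gk - mean(gk)) * (rk - mean(rk))) / sxx
    rss <- sum((rk - mean(rk) - beta * (gk - mean(gk)))^2)
    if (rss < 1e-12 * max(1, sum(rk^2))) {
      out$beta[k] <- beta
      out$p[k] <- 0
      out$flag[k] <- "degenerate_fit"
      next
    }
    s2 <- rss / (n - 2)
    se <- sqrt(s2 / sxx)
    tval <- beta / se
    out$beta[k] <- beta; out$se[k] <- se; out$t[k] <- tval
    out$p[k] <- 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  out
}

#' Run the abundance GWAS for the selected features
#'
#' For each selected representative feature: fit the NB model on its
#' zero-truncated counts with the log total sequence counts (from the
#' ASV-level table) as offset, draw Dunn-Smyth residuals, and scan
#' them over the QC-passing variants.
#'
#' @param features result of [buildFeatureSet()] (list with
#'   `features` and `candidates`).
#' @param asv_counts the ASV-level [TaxaCounts-class] (source of the
#'   per-sample total sequence counts used as offset).
#' @param G a [GenotypeMatrix-class].
#' @param covariates covariate data.frame.
#' @param qc result of [variantQC()]; computed with defaults when
#'   `NULL`.
#' @param seed integer seed for the residual draws.
#' @return list with `assoc` (one association data.frame per feature,
#'   with feature name/rank columns), `fits`, `qc` and `skipped`
#'   (features whose fit did not converge).
#' @export
runAbundanceGwas <- function(features, asv_counts, G, covariates,
                             qc = NULL, seed = 1) {
  if (is.null(qc)) qc <- variantQC(G)
  sel <- selectedFeatures(features$features)
  cand <- features$candidates
  totals <- sampleTotals(asv_counts)
  off <- log(totals)
  assoc <- list(); fits <- list(); skipped <- character()
  for (i in seq_len(nrow(sel))) {
    fid <- sel$feature_id[i]
    y <- counts(cand)[fid, ]
    fit <- tryCatch(fitNbGlm(y, covariates, off),
                    error = function(e) e)
    if (inherits(fit, "error") || !fit$converged) {
      skipped <- c(skipped, fid)
      next
    }
    r <- dunnSmythResiduals(fit, y, seed = seed + i)
    tab <- snpScanUnivariate(r, G, qc$keep)
    tab$feature_name <- sel$lineage[i]
    tab$feature_rank <- sel$rank[i]
    assoc[[fid]] <- tab
    fits[[fid]] <- fit
  }
  list(assoc = assoc, fits = fits, qc = qc, skipped = skipped)
}
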