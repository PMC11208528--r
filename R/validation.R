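# Calibration and power studies on synthetic cohorts: the package's
# own evidence that the two association arms are valid. These run
# the full pipeline on generated data and summarize operating
# characteristics.

#' Type-I error of the abundance arm on a null cohort
#'
#' Simulates a cohort with no genotype effects (all covariates
#' active), runs the full two-stage abundance pipeline on one taxon
#' (NB fit with offset, Dunn-Smyth residuals, per-variant scan of the
#' QC-passing variants) and summarizes the null p-value distribution.
#'
#' @param n_samples,n_variants cohort size (defaults 600 x 2000).
#' @param theta NB dispersion (default 2).
#' @param seed integer seed.
#' @return list: `p` (per-variant p-values), `type1`
#'   (fraction p < 0.05), `lambda_gc`, `n_variants_tested`.
#' @export
abundanceNullStudy <- function(n_samples = 600, n_variants = 2000,
                               theta = 2, seed = 1) {
  seed <- as.integer(seed)
  cfg <- simConfig(n_samples = n_samples, n_variants = n_variants,
                   n_asv = 5, dispersion_theta = theta,
                   maf_range = c(0.1, 0.5), missing_rate = 0.01)
  coh <- simulateCohort(cfg, seed = seed)
  qc <- variantQC(coh$genotypes)
  y <- counts(coh$counts)[1, ]
  fit <- fitNbGlm(y, coh$covariates, log(sampleTotals(coh$counts)))
  r <- dunnSmythResiduals(fit, y, seed = seed + 3L)
  sc <- snpScanUnivariate(r, coh$genotypes, qc$keep)
  p <- sc$p[!is.na(sc$p)]
  list(p = p, type1 = mean(p < 0.05),
       lambda_gc = genomicInflation(p),
       n_variants_tested = length(p))
}

#' Planted-effect recovery of the abundance arm
#'
#' Plants a per-allele effect on one common variant (the simulated
#' variant with minor allele frequency closest to `maf`) for one
#' taxon, runs the two-stage pipeline, and reports whether the
#' planted variant attains the minimum p of the scan with the
#' correct effect sign.
#'
#' @param seed integer seed.
#' @param n_samples,n_variants cohort size.
#' @param beta planted per-allele effect on the log-mean scale.
#' @param maf target minor allele frequency of the planted variant.
#' @param theta NB dispersion.
#' @return list: `planted_id`, `min_p_id`, `recovered` (planted
#'   variant is the scan minimum), `sign_match`, `p_planted`.
#' @export
plantedRecoveryRun <- function(seed, n_samples = 600,
                               n_variants = 2000, beta = 0.5,
                               maf = 0.3, theta = 2) {
  seed <- as.integer(seed)
  cfg <- simConfig(n_samples = n_samples, n_variants = n_variants,
                   n_asv = 5, dispersion_theta = theta,
                   maf_range = c(0.1, 0.5), missing_rate = 0.01)
  G <- simulateGenotypes(cfg, seed = seed)
  d <- dosage(G)
  obs_maf <- pmin(colMeans(d, na.rm = TRUE) / 2,
                  1 - colMeans(d, na.rm = TRUE) / 2)
  planted_id <- colnames(d)[which.min(abs(obs_maf - maf))]
  cfg$snp_effects <- data.frame(variant = planted_id, taxon = 1,
                                beta = beta)
  covariates <- simulateCovariates(n_samples, seed = seed + 1L)
  rownames(covariates) <- rownames(d)
  sim <- simulateCounts(G, covariates, cfg, seed = seed + 2L)
  qc <- variantQC(G)
  y <- counts(sim$counts)[1, ]
  fit <- fitNbGlm(y, covariates, log(sampleTotals(sim$counts)))
  r <- dunnSmythResiduals(fit, y, seed = seed + 3L)
  sc <- snpScanUnivariate(r, G, qc$keep)
  ok <- !is.na(sc$p)
  min_p_id <- sc$id[ok][which.min(sc$p[ok])]
  row <- sc[sc$id == planted_id, ]
  list(planted_id = planted_id, min_p_id = min_p_id,
       recovered = identical(min_p_id, planted_id),
       sign_match = nrow(row) == 1 && !is.na(row$beta) &&
         sign(row$beta) == sign(beta),
       p_planted = if (nrow(row)) row$p else NA_real_)
}

#' Null calibration of the DBF-test
#'
#' Fixes one simulated community dissimilarity structure and tests
#' `n_reps` independent random genotype vectors against it; under
#' this null the analytic p-values should be uniform.
#'
#' @param n_reps replicates (default 500).
#' @param n_samples samples (default 100).
#' @param n_moment_perm moment permutations per test.
#' @param seed integer seed.
#' @return numeric vector of analytic p-values.
#' @export
dbfNullStudy <- function(n_reps = 500, n_samples = 100,
                         n_moment_perm = 1000, seed = 1) {
  seed <- as.integer(seed)
  cfg <- simConfig(n_samples = n_samples, n_variants = 2,
                   n_asv = 15, missing_rate = 0)
  coh <- simulateCohort(cfg, seed = seed)
  Gm <- gowerCenter(brayCurtis(coh$counts))
  gs <- withr::with_seed(seed + 1L,
    matrix(rbinom(n_samples * n_reps, 2, 0.3), n_samples, n_reps))
  vapply(seq_len(n_reps), function(i)
    dbfTest(Gm, gs[, i], n_moment_perm = n_moment_perm,
            seed = seed + 1L + i)$p_analytic, numeric(1))
}

#' Agreement of analytic and permutation DBF p-values
#'
#' Generates synthetic instances with graded association strength and
#' compares the Pearson type III p-value against a long permutation
#' p-value on each.
#'
#' @param n_instances instances (default 20).
#' @param n_samples samples per instance (default 100).
#' @param n_perm permutations for the reference p (default 1e4).
#' @param seed integer seed.
#' @return data.frame with `p_analytic`, `p_perm`, `abs_diff`.
#' @export
dbfAgreementStudy <- function(n_instances = 20, n_samples = 100,
                              n_perm = 10000, seed = 1) {
  seed <- as.integer(seed)
  out <- withr::with_seed(seed, {
    res <- vector("list", n_instances)
    for (i in seq_len(n_instances)) {
      Y <- matrix(rnorm(n_samples * 5), n_samples, 5)
      g <- rbinom(n_samples, 2, 0.3)
      Y[, 1] <- Y[, 1] + 0.04 * i * g  # graded signal
      D <- as.matrix(dist(Y))
      r <- dbfTest(gowerCenter(D), g, n_perm = n_perm,
                   n_moment_perm = 1000, seed = seed + 100L + i)
      res[[i]] <- data.frame(p_analytic = r$p_analytic,
                             p_perm = r$p_perm)
    }
    do.call(rbind, res)
  })
  out$abs_diff <- abs(out$p_analytic - out$p_perm)
  out
}
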