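# Internal helpers shared across modules.

#' @importFrom stats model.matrix median complete.cases qnorm pnorm
#'   runif rnorm rbinom rnbinom rlnorm qchisq pchisq pgamma pt sd cor
#'   var setNames quantile
#' @importFrom utils read.table write.table
NULL

COVARIATE_COLS <- c("sex", "age", "bmi", "smoking", "alcohol",
                    "glycemic_state", "seq_run", paste0("pc", 1:10))

# Build the fixed-covariate design matrix (intercept + one-hot with
# first level as reference). Factors are re-leveled from character.
buildDesign <- function(covariates) {
  covariates <- as.data.frame(covariates)
  miss <- setdiff(COVARIATE_COLS, colnames(covariates))
  if (length(miss))
    stop("covariate table missing columns: ", paste(miss, collapse = ", "))
  x <- covariates[, COVARIATE_COLS, drop = FALSE]
  for (j in seq_along(x))
    if (is.character(x[[j]])) x[[j]] <- factor(x[[j]])
  model.matrix(~ ., data = x)
}

# Samples with any missing covariate are excluded from model fits.
completeCovariateSamples <- function(covariates) {
  keep <- complete.cases(covariates[, intersect(COVARIATE_COLS,
                                                colnames(covariates)),
                                    drop = FALSE])
  rownames(covariates)[keep]
}

#' Default analysis configuration
#'
#' All thresholds used by the pipeline, with the study defaults:
#' prevalence filter (feature present in more than `min_prevalence`
#' samples), median filter (median count over present samples above
#' `min_median`), Spearman clustering cutoff, variant QC (MAF, call
#' rate, Hardy-Weinberg alpha, imputation R2 for the beta-diversity
#' arm), rarefaction depth, genome-wide and study-wide significance
#' thresholds, locus window, and the DBF-test settings.
#'
#' The study-wide threshold is an explicit value (1.19e-9, the
#' genome-wide level divided by the number of scans), overridable;
#' when `NULL` it is recomputed as `alpha_genomewide / n_tests`.
#'
#' @param ... named overrides of any default.
#' @return A named list of configuration values.
#' @examples
#' cfg <- mbgwasConfig(rho_cutoff = 0.99)
#' cfg$rho_cutoff
#' @export
mbgwasConfig <- function(...) {
  cfg <- list(
    min_prevalence = 100,
    min_median = 50,
    rho_cutoff = 0.985,
    maf_min = 0.05,
    callrate_min = 0.95,
    hwe_alpha = 0.005,
    r2_min = 0.6,
    rarefaction_depth = 5000,
    rarefaction_seed = 1L,
    alpha_genomewide = 5e-8,
    alpha_studywide = 1.19e-9,
    locus_window_bp = 1e6,
    dbf_n_moment_perm = 1000L,
    dbf_n_perm = 0L,
    residual_type = "dunn-smyth",
    info_key = "R2"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read / write a configuration file
#'
#' Configurations are stored as YAML; unknown keys are rejected so a
#' typo cannot silently fall back to a default.
#'
#' @param path file path.
#' @param cfg for `writeConfig`, a list as returned by [mbgwasConfig()].
#' @return `readConfig` returns the merged configuration list.
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(mbgwasConfig, vals)
}

#' @rdname readConfig
#' @export
writeConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
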