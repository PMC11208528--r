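# Synthetic-cohort generator: HWE genotypes with block LD and
# missingness, covariates matching the cohort's structure, and
# negative-binomial taxon counts with log-link covariate and
# per-allele SNP effects plus per-sample sequencing depth.

#' Simulation configuration
#'
#' Defines the synthetic cohort. Genotypes: `n_variants` biallelic
#' SNPs for `n_samples` individuals, per-variant minor allele
#' frequency drawn uniformly from `maf_range`, Hardy-Weinberg
#' genotypes, optional LD through a haplotype-copy chain within
#' blocks of `ld_block_size` variants (each successive variant copies
#' the previous variant's allele per haplotype with probability
#' `ld_rho`), and entries set missing at `missing_rate`. Counts: per
#' sample a sequencing depth LogNormal(`depth_meanlog`,
#' `depth_sdlog`); per taxon j a negative-binomial count with
#' log mu_ij = alpha_j + x_i' gamma_j + beta_vj g_iv + log N_i and
#' variance mu + mu^2/theta. `snp_effects` is a data.frame
#' (variant, taxon, beta) of planted per-allele effects.
#'
#' @param n_samples,n_variants cohort dimensions.
#' @param maf_range length-2 numeric in (0, 0.5].
#' @param missing_rate fraction of dosage entries set missing.
#' @param ld_block_size,ld_rho LD block length and copy probability.
#' @param imp_r2_range range of simulated imputation R2 values.
#' @param n_asv number of amplicon sequence variants.
#' @param taxonomy_spec named integer vector giving the number of
#'   distinct groups at each rank, e.g. `c(phylum = 2, class = 3,
#'   order = 4, family = 6, genus = 10)`; ASVs are nested into them.
#' @param depth_meanlog,depth_sdlog log-normal sequencing depth.
#' @param dispersion_theta NB size parameter(s), recycled over taxa.
#' @param covariate_sd standard deviation of the random covariate
#'   coefficients applied on the standardized design scale.
#' @param snp_effects data.frame with columns `variant` (index or
#'   id), `taxon` (index or id) and `beta` (per-allele log effect);
#'   `NULL` for a null cohort.
#' @param baseline_logit_sd spread of baseline log relative
#'   abundances across ASVs.
#' @return A validated list of class `simConfig`.
#' @examples
#' cfg <- simConfig(n_samples = 100, n_variants = 50, n_asv = 10)
#' @export
simConfig <- function(n_samples = 600, n_variants = 2000,
                      maf_range = c(0.05, 0.5), missing_rate = 0.01,
                      ld_block_size = 1, ld_rho = 0,
                      imp_r2_range = c(0.7, 1),
                      n_asv = 40,
                      taxonomy_spec = c(phylum = 2, class = 3,
                                        order = 4, family = 6,
                                        genus = 10),
                      depth_meanlog = log(20000), depth_sdlog = 0.35,
                      dispersion_theta = 2,
                      covariate_sd = 0.1,
                      snp_effects = NULL,
                      baseline_logit_sd = 1) {
  cfg <- list(n_samples = n_samples, n_variants = n_variants,
              maf_range = maf_range, missing_rate = missing_rate,
              ld_block_size = ld_block_size, ld_rho = ld_rho,
              imp_r2_range = imp_r2_range, n_asv = n_asv,
              taxonomy_spec = taxonomy_spec,
              depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
              dispersion_theta = dispersion_theta,
              covariate_sd = covariate_sd, snp_effects = snp_effects,
              baseline_logit_sd = baseline_logit_sd)
  stopifnot(n_samples >= 1, n_variants >= 1, n_asv >= 1,
            length(maf_range) == 2, maf_range[1] > 0,
            maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
            missing_rate >= 0, missing_rate < 1,
            ld_block_size >= 1, ld_rho >= 0, ld_rho <= 1,
            all(dispersion_theta > 0))
  class(cfg) <- "simConfig"
  cfg
}

#' Simulate a genotype matrix
#'
#' Per variant, the alternative-allele frequency is drawn uniformly
#' from `maf_range` and two haplotypes per individual are drawn
#' Bernoulli(p) (Hardy-Weinberg). Within an LD block each successive
#' variant copies the previous variant's allele on the same haplotype
#' with probability `ld_rho`, otherwise redraws Bernoulli(p) — so the
#' marginal frequency is exact and genotypes always valid. Missing
#' calls are planted uniformly at `missing_rate`.
#'
#' @param cfg a [simConfig()].
#' @param seed integer seed; the generator is deterministic given it.
#' @return A [GenotypeMatrix-class] with `impR2` metadata.
#' @export
simulateGenotypes <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "simConfig"))
  withr::with_seed(as.integer(seed), {
    n <- cfg$n_samples; m <- cfg$n_variants
    p <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
    h1 <- matrix(0L, n, m); h2 <- matrix(0L, n, m)
    block_start <- (seq_len(m) - 1) %% cfg$ld_block_size == 0
    for (j in seq_len(m)) {
      if (block_start[j] || cfg$ld_rho == 0) {
        h1[, j] <- rbinom(n, 1, p[j]); h2[, j] <- rbinom(n, 1, p[j])
      } else {
        copy1 <- runif(n) < cfg$ld_rho
        copy2 <- runif(n) < cfg$ld_rho
        f1 <- rbinom(n, 1, p[j]); f2 <- rbinom(n, 1, p[j])
        h1[, j] <- ifelse(copy1, h1[, j - 1], f1)
        h2[, j] <- ifelse(copy2, h2[, j - 1], f2)
      }
    }
    d <- h1 + h2
    storage.mode(d) <- "double"
    if (cfg$missing_rate > 0)
      d[matrix(runif(n * m) < cfg$missing_rate, n, m)] <- NA_real_
    samples <- sprintf("S%04d", seq_len(n))
    ids <- sprintf("var%05d", seq_len(m))
    dimnames(d) <- list(samples, ids)
    variants <- data.frame(
      chrom = as.character(1 + (seq_len(m) - 1) %/% ceiling(m / 22)),
      pos = 10000L + 5000L * ((seq_len(m) - 1) %% ceiling(m / 22)),
      id = ids, ref = "A", alt = "G",
      impR2 = runif(m, cfg$imp_r2_range[1], cfg$imp_r2_range[2]),
      stringsAsFactors = FALSE)
    GenotypeMatrix(d, variants)
  })
}

#' Simulate the covariate table
#'
#' Sex is Bernoulli with the cohort's observed proportion of women
#' (0.454); age ~ Normal(67.6, 6.0) years and BMI ~ Normal(26.9, 4.2)
#' kg/m^2 match the cohort's summary moments; smoking (smoker /
#' ex-smoker / non-smoker) and glycemic state (NGT, IFG, IGT,
#' IFG&IGT, screen-detected T2D, T2D) are drawn uniformly over their
#' levels; weekly alcohol intake is log-normal; sequencing run is a
#' balanced two-level batch; the ten genetic PCs are standard normal.
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @return data.frame with rownames `S0001`.. and the covariate
#'   columns used by [buildDesign()].
#' @export
simulateCovariates <- function(n, seed = 1) {
  withr::with_seed(as.integer(seed), {
    x <- data.frame(
      sex = ifelse(rbinom(n, 1, 0.454) == 1, "female", "male"),
      age = rnorm(n, 67.6, 6.0),
      bmi = rnorm(n, 26.9, 4.2),
      smoking = sample(c("non-smoker", "ex-smoker", "smoker"), n,
                       replace = TRUE),
      alcohol = rlnorm(n, log(5), 0.8),
      glycemic_state = sample(c("NGT", "IFG", "IGT", "IFG_IGT",
                                "sdT2D", "T2D"), n, replace = TRUE),
      seq_run = sample(c("R1", "R2"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    pcs <- matrix(rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("pc", 1:10)))
    x <- cbind(x, as.data.frame(pcs))
    rownames(x) <- sprintf("S%04d", seq_len(n))
    x
  })
}

# Nested taxonomy for n ASVs given the groups-per-rank spec.
makeTaxonomy <- function(n_asv, spec) {
  ranks <- c("phylum", "class", "order", "family", "genus")
  for (r in ranks) if (!r %in% names(spec)) spec[r] <- 1
  spec <- pmin(spec[ranks], n_asv)
  genus_of <- sort(rep_len(seq_len(spec["genus"]), n_asv))
  nest <- function(n_child, n_parent) sort(rep_len(seq_len(n_parent), n_child))
  family_of_genus <- nest(spec["genus"], spec["family"])
  order_of_family <- nest(spec["family"], spec["order"])
  class_of_order <- nest(spec["order"], spec["class"])
  phylum_of_class <- nest(spec["class"], spec["phylum"])
  g <- genus_of
  f <- family_of_genus[g]
  o <- order_of_family[f]
  cl <- class_of_order[o]
  ph <- phylum_of_class[cl]
  data.frame(
    feature_id = sprintf("ASV%04d", seq_len(n_asv)),
    kingdom = "Bacteria",
    phylum = sprintf("Phylum_%02d", ph),
    class = sprintf("Class_%02d", cl),
    order = sprintf("Order_%02d", o),
    family = sprintf("Family_%02d", f),
    genus = sprintf("Genus_%02d", g),
    species = sprintf("Species_%04d", seq_len(n_asv)),
    rank = "asv", stringsAsFactors = FALSE)
}

#' Simulate taxon counts with planted genotype effects
#'
#' Per sample i a sequencing depth N_i ~ LogNormal is drawn; per ASV
#' j the count is negative binomial with
#' log mu_ij = alpha_j + x_i' gamma_j + sum_v beta_vj g_iv + log N_i
#' and Var = mu + mu^2/theta_j. Baseline log relative abundances
#' alpha_j are a normalized log-normal profile; gamma_j are random
#' coefficients on the standardized covariate design; planted
#' per-allele effects come from `cfg$snp_effects`. Missing genotypes
#' at a planted variant contribute the variant's mean dosage (so no
#' sample is dropped at generation time).
#'
#' @param G a [GenotypeMatrix-class].
#' @param covariates covariate data.frame aligned to `G`'s samples.
#' @param cfg a [simConfig()].
#' @param seed integer seed.
#' @return list with `counts` (a [TaxaCounts-class]) and `truth`
#'   (data.frame of planted (variant, taxon, beta) triples plus the
#'   null-variant ids).
#' @export
simulateCounts <- function(G, covariates, cfg, seed = 1) {
  stopifnot(inherits(cfg, "simConfig"))
  d <- dosage(G)
  stopifnot(nrow(d) == nrow(covariates))
  n <- nrow(d); J <- cfg$n_asv
  tax <- makeTaxonomy(J, cfg$taxonomy_spec)
  theta <- rep_len(cfg$dispersion_theta, J)
  planted <- cfg$snp_effects
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    stopifnot(all(c("variant", "taxon", "beta") %in% colnames(planted)))
    if (is.numeric(planted$variant))
      planted$variant <- colnames(d)[planted$variant]
    if (is.numeric(planted$taxon))
      planted$taxon <- tax$feature_id[planted$taxon]
    stopifnot(all(planted$variant %in% colnames(d)),
              all(planted$taxon %in% tax$feature_id))
    for (vid in unique(planted$variant)) {
      gv <- d[, vid]
      if (var(gv, na.rm = TRUE) == 0 || all(is.na(gv)))
        stop("planted variant ", vid, " is monomorphic")
    }
  }
  withr::with_seed(as.integer(seed), {
    X <- buildDesign(covariates)
    Xs <- scale(X[, -1, drop = FALSE])  # standardized, no intercept
    Xs[is.nan(Xs)] <- 0
    alpha <- rnorm(J, 0, cfg$baseline_logit_sd)
    alpha <- log(exp(alpha) / sum(exp(alpha)))
    gamma <- matrix(rnorm(ncol(Xs) * J, 0, cfg$covariate_sd),
                    ncol(Xs), J)
    depth <- rlnorm(n, cfg$depth_meanlog, cfg$depth_sdlog)
    eta <- matrix(alpha, n, J, byrow = TRUE) + Xs %*% gamma +
      log(depth)
    if (!is.null(planted)) {
      for (k in seq_len(nrow(planted))) {
        gv <- d[, planted$variant[k]]
        gv[is.na(gv)] <- mean(gv, na.rm = TRUE)
        jj <- match(planted$taxon[k], tax$feature_id)
        eta[, jj] <- eta[, jj] + planted$beta[k] * gv
      }
    }
    y <- matrix(rnbinom(n * J, mu = exp(eta),
                        size = rep(theta, each = n)), n, J)
    dimnames(y) <- list(rownames(d), tax$feature_id)
    tc <- TaxaCounts(t(y), tax)
    truth <- list(
      planted = if (is.null(planted))
        data.frame(variant = character(), taxon = character(),
                   beta = numeric()) else planted,
      null_variants = setdiff(colnames(d),
                              if (is.null(planted)) character()
                              else planted$variant))
    list(counts = tc, truth = truth)
  })
}

#' Simulate a full cohort
#'
#' Convenience wrapper drawing genotypes, covariates and counts with
#' seeds derived from one master seed.
#'
#' @param cfg a [simConfig()].
#' @param seed master integer seed.
#' @return list with `genotypes`, `covariates`, `counts`, `truth`.
#' @export
simulateCohort <- function(cfg, seed = 1) {
  seed <- as.integer(seed)
  G <- simulateGenotypes(cfg, seed = seed)
  covariates <- simulateCovariates(cfg$n_samples, seed = seed + 1L)
  rownames(covariates) <- rownames(dosage(G))
  sim <- simulateCounts(G, covariates, cfg, seed = seed + 2L)
  list(genotypes = G, covariates = covariates,
       counts = sim$counts, truth = sim$truth)
}
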