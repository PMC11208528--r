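# Shared fixture builders; everything is generated in code.

# Small deterministic count table: 3 samples x 2 ASVs sharing a genus.
toyTaxaCounts <- function() {
  m <- matrix(c(3, 1, 0,
                4, 2, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("ASV1", "ASV2"),
                              c("s1", "s2", "s3")))
  tax <- data.frame(
    feature_id = c("ASV1", "ASV2"),
    kingdom = "Bacteria", phylum = "P1", class = "C1", order = "O1",
    family = "F1", genus = "G1",
    species = c("sp1", "sp2"), stringsAsFactors = FALSE)
  TaxaCounts(m, tax)
}

# Random ASV table with full taxonomy, Poisson counts.
randomTaxaCounts <- function(n_samples = 50, n_asv = 10, seed = 1,
                             lambda = 20) {
  withr::with_seed(seed, {
    tax <- mbGWAS:::makeTaxonomy(n_asv, c(phylum = 2, class = 2,
                                          order = 3, family = 3,
                                          genus = 4))
    m <- matrix(rpois(n_asv * n_samples, lambda), n_asv, n_samples,
                dimnames = list(tax$feature_id,
                                sprintf("s%03d", 1:n_samples)))
    TaxaCounts(m, tax)
  })
}

# Genotype matrix from an explicit dosage matrix.
toyGenotypes <- function(d, chrom = NULL, pos = NULL, impR2 = NULL) {
  m <- ncol(d)
  if (is.null(colnames(d))) colnames(d) <- sprintf("v%02d", 1:m)
  if (is.null(rownames(d))) rownames(d) <- sprintf("s%03d", 1:nrow(d))
  v <- data.frame(chrom = if (is.null(chrom)) rep("1", m) else chrom,
                  pos = if (is.null(pos)) 1000L * (1:m) else pos,
                  id = colnames(d), ref = "A", alt = "G",
                  stringsAsFactors = FALSE)
  if (!is.null(impR2)) v$impR2 <- impR2
  GenotypeMatrix(d, v)
}

# Independent brute-force HWE enumeration (oracle for hweExactP):
# enumerate every heterozygote count compatible with the allele
# counts, with multinomial weight n! / (nAA! nAa! naa!) * 2^nAa.
hweEnumOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  na <- 2 * nAA + nAa
  nb <- 2 * naa + nAa
  rare <- min(na, nb)
  hets <- seq(rare %% 2, rare, by = 2)
  w <- sapply(hets, function(h) {
    aa <- (rare - h) / 2
    bb <- n - h - aa
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) -
          lfactorial(bb)) * 2^h
  })
  pr <- w / sum(w)
  sum(pr[pr <= pr[hets == nAa] * (1 + 1e-12)])
}

# Randomized (uniformized) exact HWE p: subtracts a uniform share of
# the observed configuration's probability mass, making the p-value
# exactly Uniform(0,1) when genotypes follow the HWE-conditional
# distribution (the plain exact p is discrete and conservative).
hweRandomizedP <- function(nAA, nAa, naa, u) {
  n <- nAA + nAa + naa
  na <- 2 * nAA + nAa
  rare <- min(na, 2 * naa + nAa)
  hets <- seq(rare %% 2, rare, by = 2)
  w <- sapply(hets, function(h) {
    aa <- (rare - h) / 2
    bb <- n - h - aa
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) -
          lfactorial(bb) + h * log(2))
  })
  pr <- w / sum(w)
  p_obs <- pr[hets == nAa]
  sum(pr[pr <= p_obs * (1 + 1e-12)]) - u * p_obs
}

# Brute-force Benjamini-Hochberg (oracle for fdrBH).
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
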