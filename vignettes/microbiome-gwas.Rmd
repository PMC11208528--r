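---
title: "Methods: microbiome GWAS with negative-binomial residuals and the distance-based F-test"
author: "mbGWAS"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: microbiome GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbGWAS)
```

# Scope and model

`mbGWAS` associates host genotypes with two kinds of microbiome
traits from a 16S amplicon cohort: the abundance of individual
bacterial features, and overall community composition (beta
diversity). Both arms adjust for the same host covariates — sex, age,
BMI, smoking, alcohol, glycemic state, sequencing run and ten genetic
principal components — and both consume hard-called alternative-allele
dosages (0/1/2) from a VCF.

## The abundance arm

Counts are overdispersed and depth-confounded, so each feature is
modeled on its zero-truncated, non-rarefied counts by a
negative-binomial GLM with log link and the log of the sample's total
sequence count as offset:

$$\log \mu_{ij} = \alpha_j + x_i^\top \gamma_j + \log N_i, \qquad
\mathrm{Var}(y_{ij}) = \mu_{ij} + \mu_{ij}^2/\theta_j .$$

"Zero-truncated" is implemented as exclusion of zero-count samples
before a standard NB fit, not as a truncated-NB likelihood: presence
and abundance are treated as separate phenomena, and the model only
claims to describe abundance where the taxon is observed. A
truncated likelihood would change the fitted means near zero; we
consider the exclusion reading the natural one for a
presence-conditional abundance trait, and the residual diagnostics
below are computed under the same convention, so the two stages are
consistent.

The genotype is deliberately kept out of this model. Instead,
randomized-quantile (Dunn–Smyth) residuals

$$r_i = \Phi^{-1}(u_i), \qquad u_i \sim \mathrm{U}\big(F(y_i - 1;
\hat\mu_i, \hat\theta), \; F(y_i; \hat\mu_i, \hat\theta)\big)$$

are extracted once per feature and regressed on each variant's dosage
by simple linear regression (slope, t statistic, two-sided p with
n − 2 df). Under a correctly specified fit the residuals are exactly
standard normal, which the test suite verifies by a
Kolmogorov–Smirnov check at n = 5000. The residuals are stochastic by
construction; the draw is controlled by a logged seed, and Pearson
residuals are available as a deterministic alternative
(`pearsonResiduals()`), though the randomized-quantile form is the
default because it is the one whose null distribution is exactly
normal for discrete data. The two-stage design means each feature's
NB model is fitted once, not once per variant — the property that
makes a genome-wide scan affordable — at the price of not re-adjusting
covariates per variant; the calibration study below shows the type-I
error is nonetheless nominal.

Samples with a missing genotype at variant v are dropped for that
variant only (residuals are per-feature, not per-variant). A variant
monomorphic in the analysis subset yields a record with missing p and
a reason; a perfect fit (zero residual sum of squares) is flagged
`degenerate_fit` with p reported as the 0 limit.

## The beta-diversity arm

Counts are rarefied to an even depth of 5000 reads per sample
(samples below depth are dropped and logged; the subsampling seed is
a first-class argument). Bray–Curtis dissimilarities are
Gower-centered, $G = J(-\tfrac12 D \circ D)J$, and the covariate
design is projected out, $G_\mathrm{res} = RGR$ with
$R = I - X(X^\top X)^{-1}X^\top$ — the same operation a distance-based
redundancy analysis performs with conditioned covariates. Negative
eigenvalues of the Bray–Curtis Gower matrix (the metric is
non-Euclidean) are retained; no Lingoes/Cailliez correction is
applied, matching how distance-based redundancy models treat raw
dissimilarity input.

Each variant is then tested with the distance-based F-test: with
$H = xx^\top/(x^\top x)$ for the centered dosage $x$,

$$F = \frac{\mathrm{tr}(H G_\mathrm{res} H)}
{\mathrm{tr}\big((I-H) G_\mathrm{res} (I-H)\big)/(n - q - 2)} .$$

The denominator df $n - q - 2$ charges the $q$ partialled covariate
columns, which keeps the Euclidean, no-covariate special case equal
to the classical regression F (verified to 1e-8 in the tests). For
variants with missing calls the matrix is subset to called samples
and re-centered, because the trace identities only hold when the
centering matches the tested sample set.

### The analytic null

Because $H$ is a rank-one projection,
$\mathrm{tr}(HG_\mathrm{res}H) = x^\top G_\mathrm{res}\,x /(x^\top x)$
and the denominator equals $\mathrm{tr}(G_\mathrm{res})$ minus the
numerator — so the numerator is pivotal for the permutation null, and
its null distribution under label permutations of $x$ is what we
approximate. A Pearson type III (shifted gamma) distribution is
matched to three moments: the mean and variance are computed by exact
trace identities for quadratic forms under permutation (derived for
the doubly centered $G$, zero row sums, and centered $x$; verified in
the tests against full enumeration of all permutations at small n),
while the skewness is estimated from Monte-Carlo label permutations —
1000 by default, and every permutation drawn for a requested
permutation p-value is reused for it. The exact first two moments
remove most of the Monte-Carlo error; what remains is the skewness
noise, which moves mid-range p-values by well under 0.02 (the
agreement study below measures it at about 0.01 against a
10^4-permutation reference). The direct permutation p-value
$(1 + \#\{F_\pi \ge F\})/(1 + B)$ is always available as the
assumption-free fallback.

# The synthetic cohort generator

The generator produces data with exactly the structure the analysis
assumes, plus a truth table of planted effects, and is first-class,
tested code:

* **Genotypes** — per variant an allele frequency uniform in
  `maf_range`, two Bernoulli haplotypes per individual
  (Hardy–Weinberg by construction), optional LD by a haplotype-copy
  chain (each variant in a block copies the previous variant's allele
  with probability `ld_rho`, which preserves the marginal frequency
  exactly and always yields valid genotypes — the reason this was
  chosen over a thresholded Gaussian model), missing calls planted
  uniformly.
* **Covariates** — age ~ N(67.6, 6.0) years and BMI ~ N(26.9, 4.2)
  kg/m², matching the cohort summary moments the pipeline was
  designed around; sex Bernoulli(0.454); smoking and glycemic state
  uniform over their clinical levels; log-normal weekly alcohol;
  a balanced two-level sequencing run; standard-normal PCs.
* **Counts** — per sample a log-normal sequencing depth (default
  meanlog log 20000, sdlog 0.35, a typical amplicon depth profile);
  per taxon NB counts with
  $\log \mu = \alpha_j + x^\top\gamma_j + \beta_{vj} g_v + \log N_i$
  and Var = mu + mu²/theta. The NB parameterization is fixed to the
  same convention the fitting uses, so parameter recovery is
  well-posed. Default planted effects in the validation studies are
  0.2–0.7 per allele, the magnitude range typical of reported
  microbiome effect sizes; this is a calibration choice, not an
  estimate.

What the generator does **not** emulate: population structure and
kinship (the cohort is unrelated by construction, so the PCs carry no
real ancestry signal), zero inflation beyond what the NB produces,
compositional closure effects, phylogenetic correlation between taxa,
and realistic recombination maps. Passing tests therefore demonstrate
statistical correctness of the machinery under the stated model, not
robustness to those real-data features.

# Feature construction choices

* Candidates are the ASVs plus their agglomerations at genus, family,
  order, class and phylum; agglomeration sums counts over the full
  lineage prefix and conserves per-sample totals exactly. Features
  unassigned at the target rank are grouped under their longest
  assigned prefix and flagged rather than dropped.
* The prevalence filter (present in **more than** 100 samples) and
  the abundance filter (median count **above** 50) are both strict
  inequalities. The median is taken over the samples where the
  feature is present: over all samples, a median above 50 would
  already force presence in more than half the cohort and make the
  prevalence filter redundant, so the present-only reading is the one
  under which both filters do work.
* Redundancy clustering uses Spearman correlation (average-rank ties)
  on raw counts — the downstream model consumes raw counts with an
  offset, so ranking raw counts matches what the scans will see — and
  complete-linkage clustering cut at 1 − 0.985, the one linkage under
  which the cutoff provably holds for **every** within-cluster pair.
  The signed correlation is compared to the cutoff; redundancy
  between nested taxa is positive by construction. Zero-variance
  features cannot be ranked and become logged singletons.
* Per cluster the lowest (most specific) taxonomic rank is selected;
  ties at the same rank break by the higher total count, then
  lexicographic id — the count tie-break prefers the better-measured
  feature, and the lexicographic one makes the choice deterministic.

# Variant QC and significance

MAF and call rate are strict inequalities (MAF > 0.05, call rate >
0.95); the Hardy–Weinberg exact test keeps variants with p ≥ 0.005
(the exact two-sided p enumerates all heterozygote configurations
conditional on allele counts and sums those no more probable than the
observed one); the imputation-quality filter (R2 > 0.6) is active
only in the beta-diversity arm, whose input is dosage-derived.
Filters report per-rule drop counts; a variant failing several rules
is attributed to the most basic one (missingness before MAF before
call rate before HWE before imputation quality).

Genome-wide significance is p ≤ 5e-8. The study-wide threshold is a
configurable explicit value, default 1.19e-9, rather than hard-coded
`5e-8 / n_scans`: dividing by the 44 scans of the motivating design
gives 1.136e-9, so an explicit threshold is the only way to reproduce
analyses that round or fix this number; when no explicit value is
given the code computes `alpha / n_tests`. Locus grouping reads "1 Mb
regions" as a ±500 kb window around each lead (greedy by ascending
p), the common clumping convention; the window is a parameter.

# Numerical and degenerate-input conventions

* Dosages from DS fields are rounded to the nearest integer: the
  association models code genotypes 0/1/2.
* Samples with any missing covariate are excluded from all model
  fits, with a logged count; no imputation is attempted.
* Dunn–Smyth uniforms are clipped to [1e-12, 1 − 1e-12] before the
  normal quantile transform.
* The NB fit flags non-convergence; non-converged features are
  excluded from scans with a log entry.
* An all-zero sample makes Bray–Curtis undefined and is an error
  naming the sample; pairs of identical samples give distance 0.
* Rank-deficient covariate designs are refused with the collinear
  columns named.
* The analytic DBF p-value is floored at the smallest positive
  double and capped at 1.

# Validation studies and problem sizes

The shipped studies (also driven by `scripts/acceptance.R`) use
cohorts of 600 samples by 2000 variants for the abundance arm — large
enough for stable tail behavior while keeping a full two-stage run in
seconds — and 100-sample instances for the DBF-test studies, where
each analytic p-value is backed by 10^4 permutations:

* null type-I error of the full abundance pipeline at 0.05 and its
  genomic inflation factor;
* recovery of a planted 0.5 per-allele effect (MAF 0.3) as the scan
  minimum with the correct sign across 20 cohorts;
* DBF-test exactness on Euclidean data, agreement of the Pearson III
  p with the permutation p, and null uniformity over 500 replicates.

# Known limitations

The pipeline performs no kinship or mixed-model correction, no
conditional analysis or fine-mapping, and no strand flipping in trait
lookups (palindromic variants are flagged, not resolved). The
beta-diversity arm tests one variant at a time with a single-df
dosage coding. External summary statistics must be supplied in the
package's normalized schema; the FDR family for trait lookups is the
whole variant-by-trait grid of available tests, a single family — per
trait or per variant families would give different flags.
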