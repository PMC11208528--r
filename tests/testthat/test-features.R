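test_that("agglomeration sums lineage groups and conserves totals", {
  tc <- toyTaxaCounts()
  gen <- aggregateTaxa(tc, "genus")
  expect_equal(nrow(counts(gen)), 1)
  expect_equal(unname(counts(gen)[1, "s1"]), 7)  # 3 + 4
  expect_equal(colSums(counts(gen)), colSums(counts(tc)))

  tc2 <- randomTaxaCounts(n_samples = 30, n_asv = 12, seed = 4)
  for (r in c("genus", "family", "order", "class", "phylum"))
    expect_equal(colSums(counts(aggregateTaxa(tc2, r))),
                 colSums(counts(tc2)))
  expect_error(aggregateTaxa(tc, "tribe"), "unknown rank")
})

test_that("features unassigned at the target rank group under their prefix", {
  m <- matrix(c(5, 2, 1, 7), 2, 2,
              dimnames = list(c("ASVa", "ASVb"), c("s1", "s2")))
  tax <- data.frame(
    feature_id = c("ASVa", "ASVb"), kingdom = "Bacteria",
    phylum = "P1", class = "C1", order = "O1", family = "F1",
    genus = c("G1", NA), species = NA_character_,
    stringsAsFactors = FALSE)
  tc <- TaxaCounts(m, tax)
  gen <- aggregateTaxa(tc, "genus")
  tx <- taxonomy(gen)
  expect_equal(nrow(tx), 2)
  flagged <- tx[tx$unresolved, , drop = FALSE]
  expect_equal(nrow(flagged), 1)
  expect_true(is.na(flagged$genus))
  expect_equal(flagged$family, "F1")  # grouped by the family prefix
  expect_equal(colSums(counts(gen)), colSums(counts(tc)))
})

test_that("prevalence and median filters are strict inequalities", {
  n <- 120
  mk <- function(prev, med) {
    x <- numeric(n); x[seq_len(prev)] <- med
    x
  }
  m <- rbind(kept = mk(101, 51), prev_boundary = mk(100, 51),
             med_boundary = mk(101, 50))
  colnames(m) <- sprintf("s%03d", 1:n)
  tax <- data.frame(feature_id = rownames(m), kingdom = "Bacteria",
                    phylum = "P", genus = rownames(m),
                    stringsAsFactors = FALSE)
  fs <- filterFeatures(TaxaCounts(m, tax))
  cand <- fs@candidates
  expect_true(cand$kept[cand$feature_id == "kept"])
  expect_false(cand$kept[cand$feature_id == "prev_boundary"])
  expect_false(cand$kept[cand$feature_id == "med_boundary"])
  lg <- filterLog(fs)
  expect_equal(lg$reason[lg$feature_id == "prev_boundary"],
               "low_prevalence")
  expect_equal(lg$reason[lg$feature_id == "med_boundary"],
               "low_median")
})

test_that("complete-linkage cut reproduces the hand-worked clustering", {
  rho <- matrix(c(1, 0.99, 0.99,
                  0.99, 1, 0.97,
                  0.99, 0.97, 1), 3, 3,
                dimnames = list(c("f1", "f2", "f3"),
                                c("f1", "f2", "f3")))
  cl <- mbGWAS:::clusterFromCorrelation(rho, 0.985)
  # complete linkage at cutoff 0.985: {f1,f2} merge at d=0.01, f3
  # cannot join (d(f3, {f1,f2}) = 0.03 > 0.015)
  expect_equal(cl[["f1"]], cl[["f2"]])
  expect_false(cl[["f3"]] == cl[["f1"]])
})

test_that("clustering groups duplicates and separates noise", {
  withr::with_seed(8, {
    base <- rpois(80, 40)
    m <- rbind(a = base, a_dup = base,            # rho = 1
               b = rpois(80, 40), c = rpois(80, 40))
  })
  colnames(m) <- sprintf("s%03d", 1:80)
  tax <- data.frame(feature_id = rownames(m), kingdom = "Bacteria",
                    genus = rownames(m), stringsAsFactors = FALSE)
  tc <- TaxaCounts(m, tax)
  fs <- filterFeatures(tc, min_prevalence = 10, min_median = 5)
  fs <- clusterFeatures(fs, tc)
  cl <- clusterAssignments(fs)
  cla <- cl$cluster[cl$feature_id == "a"]
  expect_equal(cl$cluster[cl$feature_id == "a_dup"], cla)
  expect_false(cl$cluster[cl$feature_id == "b"] == cla)
  expect_false(cl$cluster[cl$feature_id == "b"] ==
                 cl$cluster[cl$feature_id == "c"])
})

test_that("zero-variance features become logged singleton clusters", {
  m <- rbind(flat = rep(60, 40),
             varying = rpois(40, 60))
  colnames(m) <- sprintf("s%02d", 1:40)
  tax <- data.frame(feature_id = rownames(m), kingdom = "Bacteria",
                    genus = rownames(m), stringsAsFactors = FALSE)
  tc <- TaxaCounts(m, tax)
  fs <- filterFeatures(tc, min_prevalence = 10, min_median = 5)
  fs <- clusterFeatures(fs, tc)
  cl <- clusterAssignments(fs)
  expect_equal(length(unique(cl$cluster)), 2)
  lg <- filterLog(fs)
  expect_true(any(lg$feature_id == "flat" &
                    lg$reason == "zero_variance"))
})

test_that("within every output cluster min pairwise Spearman >= cutoff", {
  withr::with_seed(15, {
    n <- 150
    base1 <- rpois(n, 200)
    base2 <- rpois(n, 150)
    m <- rbind(
      g1a = base1, g1b = base1 + rbinom(n, 2, 0.5),
      g2a = base2, g2b = base2,
      noise1 = rpois(n, 180), noise2 = rpois(n, 120))
  })
  colnames(m) <- sprintf("s%03d", 1:n)
  tax <- data.frame(feature_id = rownames(m), kingdom = "Bacteria",
                    genus = rownames(m), stringsAsFactors = FALSE)
  tc <- TaxaCounts(m, tax)
  fs <- filterFeatures(tc, min_prevalence = 10, min_median = 5)
  fs <- clusterFeatures(fs, tc, rho_cutoff = 0.985)
  cl <- clusterAssignments(fs)
  rho <- cor(t(m), method = "spearman")
  for (g in unique(cl$cluster)) {
    ids <- cl$feature_id[cl$cluster == g]
    if (length(ids) > 1)
      expect_gte(min(rho[ids, ids]), 0.985)
  }
})

test_that("representatives are the most specific rank, ties by total", {
  cand <- data.frame(
    feature_id = c("order:O1", "genus:G1", "sp_low", "sp_high"),
    rank = c("order", "genus", "species", "species"),
    lineage = c("O1", "O1;G1", "S1", "S2"),
    prevalence = 50, median_present = 10,
    total = c(5000, 2000, 900, 1000),
    kept = TRUE, stringsAsFactors = FALSE)
  clusters <- data.frame(
    feature_id = cand$feature_id,
    cluster = c(1L, 1L, 2L, 2L), selected = FALSE,
    stringsAsFactors = FALSE)
  fs <- new("FeatureSet", candidates = cand, clusters = clusters,
            log = data.frame())
  fs <- selectRepresentatives(fs)
  sel <- selectedFeatures(fs)
  expect_setequal(sel$feature_id, c("genus:G1", "sp_high"))
})

test_that("feature construction is deterministic and plans scans", {
  tc <- randomTaxaCounts(n_samples = 60, n_asv = 15, seed = 12,
                         lambda = 30)
  b1 <- buildFeatureSet(tc, min_prevalence = 10, min_median = 5)
  b2 <- buildFeatureSet(tc, min_prevalence = 10, min_median = 5)
  expect_identical(selectedFeatures(b1$features),
                   selectedFeatures(b2$features))
  plan <- scanPlan(b1$features)
  n_clusters <- length(unique(clusterAssignments(b1$features)$cluster))
  expect_equal(nrow(plan), n_clusters + 1)
  expect_equal(sum(plan$type == "beta_diversity"), 1)
})
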