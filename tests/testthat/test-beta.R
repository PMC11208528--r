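test_that("rarefaction hits the exact depth and drops shallow samples", {
  tc <- randomTaxaCounts(n_samples = 20, n_asv = 8, seed = 5,
                         lambda = 100)
  m <- counts(tc)
  m[, 1] <- 0; m[1, 1] <- 499  # sample below depth
  tc <- TaxaCounts(m, taxonomy(tc))
  rar <- rarefyCounts(tc, depth = 500, seed = 3)
  expect_true(all(colSums(counts(rar)) == 500))
  expect_equal(attr(rar, "dropped_samples"), colnames(m)[1])
  rar2 <- rarefyCounts(tc, depth = 500, seed = 3)
  expect_identical(counts(rar), counts(rar2))
  expect_error(rarefyCounts(tc, depth = 0), "positive")
})

test_that("Bray-Curtis matches hand values and bounds", {
  m <- cbind(u = c(5, 5, 0), v = c(0, 5, 5), w = c(5, 5, 0),
             x = c(9, 0, 0))
  rownames(m) <- c("t1", "t2", "t3")
  tc <- TaxaCounts(m, data.frame(feature_id = rownames(m),
                                 kingdom = "B"))
  D <- brayCurtis(tc)
  expect_equal(D["u", "v"], 0.5)       # 10/20
  expect_equal(D["u", "w"], 0)         # identical
  expect_equal(D["v", "x"], 1)         # disjoint support
  expect_true(all(D >= 0 & D <= 1))

  m2 <- cbind(a = c(1, 2), b = c(0, 0))
  rownames(m2) <- c("t1", "t2")
  tc2 <- TaxaCounts(m2, data.frame(feature_id = rownames(m2),
                                   kingdom = "B"))
  expect_error(brayCurtis(tc2), "b")
})

test_that("Gower centering matches hand algebra and the Gram matrix", {
  G2 <- gowerCenter(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(gowerValues(G2),
               matrix(c(0.25, -0.25, -0.25, 0.25), 2, 2),
               tolerance = 1e-12)

  withr::with_seed(11, {
    Y <- matrix(rnorm(20 * 3), 20, 3)
  })
  D <- as.matrix(dist(Y))
  G <- gowerValues(gowerCenter(D))
  expect_lt(max(abs(rowSums(G))), 1e-8)
  Yc <- scale(Y, scale = FALSE)
  expect_equal(G, Yc %*% t(Yc), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("covariate partialling is a projection with the right nulls", {
  withr::with_seed(21, {
    n <- 40
    Y <- matrix(rnorm(n * 4), n, 4)
    z <- rnorm(n)
  })
  D <- as.matrix(dist(Y))
  dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
  Gm <- gowerCenter(D)

  # intercept only: no change (G already centered)
  X0 <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  expect_equal(gowerValues(partialOutCovariates(Gm, X0)),
               gowerValues(Gm), tolerance = 1e-10)

  # partialling the tested variable annihilates the pseudo-F
  Xz <- cbind("(Intercept)" = 1, z = z)
  Gres <- partialOutCovariates(Gm, Xz)
  res <- dbfTest(Gres, z, n_moment_perm = 100, seed = 1)
  expect_lt(res$pseudo_F, 1e-8)

  # equals the Gram matrix of covariate-residualized coordinates
  R <- qr.resid(qr(Xz), scale(Y, scale = FALSE))
  expect_equal(gowerValues(Gres), R %*% t(R), tolerance = 1e-6,
               ignore_attr = TRUE)

  # rank-deficient design is refused with the offending column named
  Xbad <- cbind(Xz, z2 = z)
  expect_error(partialOutCovariates(Gm, Xbad), "z2")
})

test_that("pseudo-F equals the classical regression F on Euclidean data", {
  withr::with_seed(33, {
    n <- 30
    g <- rbinom(n, 2, 0.4)
    y <- 0.5 * g + rnorm(n)
  })
  D <- as.matrix(dist(y))
  Gm <- gowerCenter(D)
  res <- dbfTest(Gm, g, n_moment_perm = 100, seed = 2)
  f_classic <- summary(lm(y ~ g))$fstatistic[["value"]]
  expect_equal(res$pseudo_F, f_classic, tolerance = 1e-8)
  expect_equal(res$df_denom, n - 2)
})

test_that("pseudo-F agrees with the PERMANOVA F of an independent package", {
  tc <- randomTaxaCounts(n_samples = 35, n_asv = 12, seed = 44,
                         lambda = 50)
  D <- brayCurtis(tc)
  withr::with_seed(45, g <- rbinom(35, 2, 0.3))
  res <- dbfTest(gowerCenter(D), g, n_moment_perm = 100, seed = 3)
  ad <- vegan::adonis2(as.dist(D) ~ g, permutations = 10)
  expect_equal(res$pseudo_F, ad$F[1], tolerance = 1e-8)
})

test_that("pseudo-F is invariant to affine rescaling and relabeling", {
  tc <- randomTaxaCounts(n_samples = 30, n_asv = 10, seed = 55)
  D <- brayCurtis(tc)
  Gm <- gowerCenter(D)
  withr::with_seed(56, g <- rbinom(30, 2, 0.4))
  f0 <- dbfTest(Gm, g, n_moment_perm = 50, seed = 4)$pseudo_F
  f1 <- dbfTest(Gm, 3 * g + 7, n_moment_perm = 50, seed = 4)$pseudo_F
  expect_equal(f1, f0, tolerance = 1e-10)

  withr::with_seed(57, perm <- sample(30))
  M <- gowerValues(Gm)[perm, perm]
  Gp <- new("GowerMatrix", mat = M, q = 0L)
  f2 <- dbfTest(Gp, g[perm], n_moment_perm = 50, seed = 4)$pseudo_F
  expect_equal(f2, f0, tolerance = 1e-10)
})

test_that("analytic and permutation p-values agree on moderate signals", {
  withr::with_seed(66, {
    diffs <- numeric(0)
    for (i in 1:6) {
      n <- 80
      Y <- matrix(rnorm(n * 5), n, 5)
      g <- rbinom(n, 2, 0.3)
      Y[, 1] <- Y[, 1] + 0.12 * i * g
      D <- as.matrix(dist(Y))
      res <- dbfTest(gowerCenter(D), g, n_perm = 4000,
                     n_moment_perm = 1000, seed = 100 + i)
      if (res$p_perm >= 0.01 && res$p_perm <= 0.5)
        diffs <- c(diffs, abs(res$p_analytic - res$p_perm))
    }
  })
  expect_gt(length(diffs), 0)
  expect_lt(max(diffs), 0.02)
})

test_that("the beta scan respects QC, missingness and errors", {
  cfg <- simConfig(n_samples = 60, n_variants = 10, n_asv = 8,
                   missing_rate = 0.05)
  coh <- simulateCohort(cfg, seed = 71)
  rar <- rarefyCounts(coh$counts, depth = 2000, seed = 1)
  Gm <- partialOutCovariates(
    gowerCenter(brayCurtis(rar)),
    coh$covariates[colnames(counts(rar)), ])
  keep <- setNames(rep(TRUE, 10), colnames(dosage(coh$genotypes)))
  keep[3] <- FALSE  # e.g. failed imputation quality
  sc <- snpScanBeta(Gm, coh$genotypes, keep, n_moment_perm = 100,
                    seed = 5)
  expect_false("var00003" %in% sc$id)
  expect_equal(nrow(sc), 9)
  expect_true(all(is.finite(sc$pseudo_F)))
  expect_true(all(sc$p > 0 & sc$p <= 1))
})

test_that("a variant shifting composition is detected by the beta scan", {
  withr::with_seed(88, {
    n <- 100
    g <- rbinom(n, 2, 0.4)
    # two community states keyed to dosage
    m <- t(sapply(1:8, function(j) rpois(n, 50)))
    m[1, ] <- rpois(n, 30 + 40 * g)
    m[2, ] <- rpois(n, 90 - 30 * g)
  })
  dimnames(m) <- list(sprintf("t%d", 1:8), sprintf("s%03d", 1:n))
  tc <- TaxaCounts(m, data.frame(feature_id = rownames(m),
                                 kingdom = "B"))
  D <- brayCurtis(tc)
  Gm <- gowerCenter(D)
  dmat <- cbind(v_signal = g,
                v_null = withr::with_seed(89, rbinom(n, 2, 0.4)))
  rownames(dmat) <- colnames(m)
  sc <- snpScanBeta(Gm, toyGenotypes(dmat), n_moment_perm = 500,
                    seed = 6)
  expect_lt(sc$p[sc$id == "v_signal"], 0.001)
  expect_gt(sc$p[sc$id == "v_null"], 0.001)
})
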