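test_that("HWE exact p matches full enumeration", {
  expect_equal(hweExactP(1, 0, 1), 1 / 3)
  expect_equal(hweExactP(0, 2, 0), 1.0)
  expect_equal(hweExactP(5, 0, 0), 1.0)  # monomorphic
  withr::with_seed(31, {
    for (i in 1:25) {
      nAA <- rpois(1, 30); nAa <- rpois(1, 20); naa <- rpois(1, 10)
      if (nAA + nAa + naa == 0) next
      expect_equal(hweExactP(nAA, nAa, naa),
                   hweEnumOracle(nAA, nAa, naa), tolerance = 1e-10)
    }
  })
})

test_that("variant QC applies each rule strictly", {
  # dosages [0,1,2,2]: alt freq 0.625, MAF 0.375 -> passes MAF
  d1 <- matrix(c(0, 1, 2, 2), 4, 1)
  qc1 <- variantQC(toyGenotypes(d1), hwe_alpha = 0)
  expect_equal(qc1$report$maf, 0.375)
  expect_true(qc1$keep[1])

  # 1 missing of 4 calls: call rate 0.75 -> dropped
  d2 <- matrix(c(0, 1, NA, 2), 4, 1)
  qc2 <- variantQC(toyGenotypes(d2), hwe_alpha = 0)
  expect_false(qc2$keep[1])
  expect_equal(qc2$report$reason, "low_callrate")

  # call rate exactly at the threshold is dropped (strict >)
  d3 <- matrix(c(rep(c(0, 1), 9), 1, NA), ncol = 1)  # 19/20 called
  qc3 <- variantQC(toyGenotypes(d3), callrate_min = 0.95,
                   hwe_alpha = 0)
  expect_false(qc3$keep[1])
})

test_that("a toy matrix with one violation per rule leaves the survivors", {
  n <- 200
  withr::with_seed(40, {
    good1 <- rbinom(n, 2, 0.3)
    good2 <- rbinom(n, 2, 0.4)
    low_maf <- rbinom(n, 2, 0.01)
    low_call <- rbinom(n, 2, 0.3); low_call[1:20] <- NA  # 90% calls
    hwe_bad <- c(rep(0, 100), rep(2, 100))  # no hets at f = 0.5
  })
  d <- cbind(good1, low_maf, low_call, hwe_bad, good2)
  qc <- variantQC(toyGenotypes(d))
  expect_equal(unname(qc$keep),
               c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(unname(qc$report$reason[2:4]),
               c("low_maf", "low_callrate", "hwe_fail"))
  expect_equal(sum(qc$drop_counts), 3)
})

test_that("imputation-quality filter only acts when requested", {
  d <- matrix(rbinom(80, 2, 0.4), 40, 2)
  g <- toyGenotypes(d, impR2 = c(0.5, 0.9))
  expect_true(all(variantQC(g, hwe_alpha = 0)$keep))
  qc <- variantQC(g, hwe_alpha = 0, r2_min = 0.6)
  expect_equal(unname(qc$keep), c(FALSE, TRUE))
})

test_that("the NB fit honors the log-link intercept and offset identities", {
  # intercept-only MLE of the mean is the sample mean
  fit <- fitNbGlm(c(a = 1, b = 2, c = 3))
  expect_equal(unname(fit$mu), rep(2, 3), tolerance = 1e-6)
  expect_equal(fit$n_used, 3)

  # shifting every offset by c shifts the intercept by -c, mu unchanged
  y <- setNames(rpois(50, 20) + 1, paste0("s", 1:50))
  off <- setNames(rep(0, 50), names(y))
  f0 <- fitNbGlm(y, offset = off)
  f1 <- fitNbGlm(y, offset = off + 1.5)
  expect_equal(unname(f1$coefficients["(Intercept)"]),
               unname(f0$coefficients["(Intercept)"]) - 1.5,
               tolerance = 1e-6)
  expect_equal(f1$mu, f0$mu, tolerance = 1e-6)
})

test_that("the NB fit recovers known parameters from simulated data", {
  n <- 2000
  cov <- simulateCovariates(n, seed = 51)
  X <- mbGWAS:::buildDesign(cov)
  beta_age <- 0.03
  withr::with_seed(52, {
    eta <- log(50) + beta_age * (cov$age - mean(cov$age))
    y <- rnbinom(n, mu = exp(eta), size = 2)
  })
  names(y) <- rownames(cov)
  fit <- fitNbGlm(y, cov)
  est <- fit$coefficients[["age"]]
  se <- summary(fit$glm)$coefficients["age", "Std. Error"]
  expect_lt(abs(est - beta_age), 3 * se)
  expect_lt(abs(fit$theta - 2) / 2, 0.2)
})

test_that("zero-count samples are excluded before fitting", {
  y <- setNames(c(0, 0, rpois(60, 15) + 1), paste0("s", 1:62))
  fit <- fitNbGlm(y)
  expect_equal(fit$n_used, 60)
  expect_false(any(c("s1", "s2") %in% fit$samples))
})

test_that("Dunn-Smyth residuals are seeded, bounded and normal", {
  y <- setNames(rnbinom(400, mu = 30, size = 2) + 1, paste0("s", 1:400))
  fit <- fitNbGlm(y)
  r1 <- dunnSmythResiduals(fit, y, seed = 9)
  r2 <- dunnSmythResiduals(fit, y, seed = 9)
  expect_identical(as.numeric(r1), as.numeric(r2))
  r3 <- dunnSmythResiduals(fit, y, seed = 10)
  expect_false(identical(as.numeric(r1), as.numeric(r3)))

  lo <- qnorm(pnbinom(y[fit$samples] - 1, mu = fit$mu,
                      size = fit$theta))
  hi <- qnorm(pmin(pnbinom(y[fit$samples], mu = fit$mu,
                           size = fit$theta), 1 - 1e-12))
  expect_true(all(r1 >= lo - 1e-10 & r1 <= hi + 1e-10))
})

test_that("residuals from a correctly specified model are standard normal", {
  withr::with_seed(61, {
    y <- rnbinom(5000, mu = 40, size = 2)
  })
  y <- setNames(y, paste0("s", 1:5000))
  fit <- fitNbGlm(y)
  r <- dunnSmythResiduals(fit, y, seed = 62)
  ks <- ks.test(as.numeric(r), "pnorm")
  expect_gt(ks$p.value, 0.01)
})

test_that("the residual scan equals the closed-form OLS oracle", {
  # tiny hand case
  g <- c(0, 1, 2, 2)
  r <- c(0.1, 0.9, 2.1, 1.9)
  beta_hand <- sum((g - mean(g)) * (r - mean(r))) /
    sum((g - mean(g))^2)
  d <- matrix(g, 4, 1, dimnames = list(paste0("s", 1:4), "v1"))
  rv <- setNames(r, rownames(d))
  sc <- snpScanUnivariate(rv, toyGenotypes(d))
  expect_equal(sc$beta, beta_hand, tolerance = 1e-12)
  lmfit <- summary(lm(r ~ g))
  expect_equal(sc$se, lmfit$coefficients["g", "Std. Error"],
               tolerance = 1e-10)
  expect_equal(sc$p, lmfit$coefficients["g", "Pr(>|t|)"],
               tolerance = 1e-10)

  # random instances vs lm(), including missing genotypes
  withr::with_seed(70, {
    for (i in 1:10) {
      n <- 40
      gv <- rbinom(n, 2, 0.4)
      gv[sample(n, 3)] <- NA
      rr <- rnorm(n)
      d <- matrix(gv, n, 1,
                  dimnames = list(paste0("s", 1:n), "v1"))
      sc <- snpScanUnivariate(setNames(rr, rownames(d)),
                              toyGenotypes(d))
      ok <- !is.na(gv)
      lf <- summary(lm(rr[ok] ~ gv[ok]))
      expect_equal(sc$beta, lf$coefficients[2, "Estimate"],
                   tolerance = 1e-10)
      expect_equal(sc$p, lf$coefficients[2, "Pr(>|t|)"],
                   tolerance = 1e-10)
      expect_equal(sc$n, sum(ok))
    }
  })
})

test_that("degenerate and monomorphic variants are flagged", {
  d <- cbind(v1 = c(0, 1, 2), v2 = c(1, 1, 1))
  rownames(d) <- paste0("s", 1:3)
  r <- setNames(c(0, 1, 2), rownames(d))
  sc <- snpScanUnivariate(r, toyGenotypes(d))
  expect_equal(sc$beta[1], 1)
  expect_equal(sc$p[1], 0)
  expect_equal(sc$flag[1], "degenerate_fit")
  expect_equal(sc$flag[2], "monomorphic")
  expect_true(is.na(sc$p[2]))
})

test_that("flipping ref/alt labels negates beta and keeps p", {
  withr::with_seed(81, {
    n <- 120
    gv <- rbinom(n, 2, 0.3)
    rr <- 0.2 * gv + rnorm(n)
  })
  d1 <- matrix(gv, n, 1, dimnames = list(paste0("s", 1:n), "v1"))
  d2 <- matrix(2 - gv, n, 1, dimnames = dimnames(d1))
  r <- setNames(rr, rownames(d1))
  s1 <- snpScanUnivariate(r, toyGenotypes(d1))
  s2 <- snpScanUnivariate(r, toyGenotypes(d2))
  expect_equal(s2$beta, -s1$beta, tolerance = 1e-10)
  expect_equal(s2$t, -s1$t, tolerance = 1e-10)
  expect_equal(s2$p, s1$p, tolerance = 1e-10)
})
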