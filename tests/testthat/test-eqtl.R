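test_that("quantile normalization matches the rank-average oracle", {
  # two individuals (1,2,3) and (4,5,6), already on log scale: the
  # averaged quantiles are (2.5, 3.5, 4.5) and both monotone columns
  # receive them unchanged
  expr <- make_expr(cbind(i01 = c(1, 2, 3), i02 = c(4, 5, 6)))
  out <- preprocess_expression(expr, "blood", log2_transform = FALSE,
                               detection_filter = FALSE)
  expect_equal(unname(out$values[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out$values[, 2]), c(2.5, 3.5, 4.5))
})

test_that("single-individual quantile normalization is the identity", {
  expr <- make_expr(matrix(c(5, 1, 7), ncol = 1))
  out <- preprocess_expression(expr, "blood", log2_transform = FALSE,
                               detection_filter = FALSE)
  expect_equal(unname(out$values[, 1]), c(5, 1, 7))
})

test_that("detection filters follow the mode's semantics", {
  m <- matrix(2, 3, 4)
  blood <- make_expr(m, detection = c(0.95, 0.85, 0.91))
  kept <- preprocess_expression(blood, "blood", log2_transform = FALSE)
  expect_equal(kept$probe_meta$probe_id, c("p01", "p03"))  # 0.85 removed

  brain <- make_expr(m, detection = c(0.005, 0.5, 0.009))
  kept2 <- preprocess_expression(brain, "brain", log2_transform = FALSE)
  expect_equal(kept2$probe_meta$probe_id, c("p01", "p03"))
})

test_that("non-positive intensities stop before log2", {
  expr <- make_expr(matrix(c(1, -2, 3, 4), 2, 2))
  expect_error(preprocess_expression(expr, "blood"), "non-positive")
})

test_that("noiseless dosage fit reports the exact slope with p = 0", {
  dosage <- rep(0:2, each = 10)
  y <- 2 + 0.5 * dosage
  expect_warning(f <- fit_dosage_model(y, dosage), "zero residual")
  expect_equal(f$B, 0.5, tolerance = 1e-12)
  expect_equal(f$SE, 0)
  expect_equal(f$p, 0)
})

test_that("dosage fits match a normal-equations + t-distribution oracle", {
  set.seed(31)
  for (r in 1:20) {
    n <- 40
    dosage <- sample(0:2, n, replace = TRUE, prob = c(.2, .4, .4))
    covs <- cbind(rnorm(n), rbinom(n, 1, 0.5))
    y <- 1 + 0.3 * dosage + 0.1 * covs[, 1] - 0.2 * covs[, 2] + rnorm(n, 0, 0.5)
    f <- fit_dosage_model(y, dosage, covs)

    X <- cbind(1, dosage, covs)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% beta
    df <- n - ncol(X)
    s2 <- sum(res^2) / df
    se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
    tval <- beta[2] / se
    p <- 2 * pt(abs(tval), df, lower.tail = FALSE)

    expect_equal(f$B, beta[2], tolerance = 1e-8)
    expect_equal(f$SE, se, tolerance = 1e-8)
    expect_equal(f$t, tval, tolerance = 1e-8)
    expect_equal(f$p, p, tolerance = 1e-8)
    expect_equal(f$ci95[1], beta[2] - qt(.975, df) * se, tolerance = 1e-8)
  }
})

test_that("fits are invariant under identical permutation of individuals", {
  set.seed(13)
  n <- 50
  dosage <- sample(0:2, n, replace = TRUE)
  covs <- matrix(rnorm(n), ncol = 1)
  y <- 0.4 * dosage + rnorm(n)
  f1 <- fit_dosage_model(y, dosage, covs)
  perm <- sample(n)
  f2 <- fit_dosage_model(y[perm], dosage[perm], covs[perm, , drop = FALSE])
  expect_equal(f1$B, f2$B, tolerance = 1e-12)
  expect_equal(f1$p, f2$p, tolerance = 1e-12)
})

test_that("recoding dosage as 2 - dosage flips B and preserves p", {
  set.seed(17)
  n <- 60
  dosage <- sample(0:2, n, replace = TRUE)
  y <- 0.25 * dosage + rnorm(n, 0, 0.4)
  a <- fit_dosage_model(y, dosage)
  b <- fit_dosage_model(y, 2 - dosage)
  expect_equal(a$B, -b$B, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("constant dosage and collinear covariates are handled", {
  y <- rnorm(20)
  expect_error(fit_dosage_model(y, rep(1, 20)), "no genotype variance")
  dosage <- rep(0:1, 10)
  covs <- cbind(a = dosage * 2, b = rnorm(20))  # a collinear with dosage
  expect_warning(f <- fit_dosage_model(y, dosage, covs), "collinear")
  expect_true(is.finite(f$B))
})

test_that("Bonferroni threshold is exact with a 2-significant-figure display", {
  expect_equal(bonferroni_threshold(0.05, 28), 0.05 / 28)
  expect_equal(format_threshold(bonferroni_threshold(0.05, 28)), "0.0018")
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 40), 0.00025)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("cis scan joins by individual ID and drops excluded individuals", {
  sim <- sim_cohort_fixture(n = 120, h2_freq = 0.25, seed = 19)
  calls <- call_inversion(sim$genotypes, qc = FALSE)
  expr <- simulate_expression(sim$truth, c(0.5, 0), noise_sd = 0.1, seed = 3)
  res1 <- run_cis_eqtl(expr, calls, tissue = "blood")

  # permuting the expression columns must not change any estimate
  perm <- sample(ncol(expr$values))
  expr_perm <- expression_table(expr$values[, perm], expr$probe_meta,
                                expr$individual_ids[perm])
  res2 <- run_cis_eqtl(expr_perm, calls, tissue = "blood")
  expect_equal(res1$B, res2$B, tolerance = 1e-12)
  expect_equal(res1$p, res2$p, tolerance = 1e-12)
})

test_that("probes outside the cis window are absent from the scan", {
  sim <- sim_cohort_fixture(n = 60, seed = 23)
  expr <- simulate_expression(sim$truth, c(0.3, 0.3), noise_sd = 0.2, seed = 2)
  expr$probe_meta$start[2] <- 1e6   # far outside cis
  expr$probe_meta$end[2] <- 1e6 + 49
  calls <- call_inversion(sim$genotypes, qc = FALSE)
  res <- run_cis_eqtl(expr, calls, tissue = "blood")
  expect_equal(res$probe_id, "probe001")
  expect_warning(
    run_cis_eqtl(expr, calls, cis = genomic_interval("chr1", 1, 2),
                 tissue = "blood"),
    "no probes")
})

test_that("null p-values are uniform and an unrelated covariate barely moves B", {
  # 1,000 independent null probes on one cohort: KS test against U(0,1)
  sim <- sim_cohort_fixture(n = 150, h2_freq = 0.25, seed = 29)
  calls <- call_inversion(sim$genotypes, qc = FALSE)
  j <- dplyr::inner_join(tidy(calls), sim$truth, by = "individual_id")
  d <- j$dosage
  set.seed(77)
  pvals <- vapply(1:1000, function(i) {
    fit_dosage_model(rnorm(length(d)), d)$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)

  # adding a covariate uncorrelated with dosage and outcome shifts B
  # by far less than its standard error on average
  set.seed(78)
  shifts <- vapply(1:50, function(i) {
    y <- 0.3 * d + rnorm(length(d), 0, 0.3)
    z <- rnorm(length(d))
    f0 <- fit_dosage_model(y, d)
    f1 <- fit_dosage_model(y, d, cbind(z))
    abs(f0$B - f1$B) / f0$SE
  }, numeric(1))
  expect_lt(mean(shifts), 3)
})

test_that("missing covariates drop individuals listwise", {
  sim <- sim_cohort_fixture(n = 80, seed = 31)
  calls <- call_inversion(sim$genotypes, qc = FALSE)
  covars <- simulate_covariates(80, seed = 1,
                                individual_ids = sim$truth$individual_id)
  covars$age[1:5] <- NA
  expr <- simulate_expression(sim$truth, 0.4, covariates = covars,
                              noise_sd = 0.2, seed = 2)
  res <- run_cis_eqtl(expr, calls, covariates = covars, tissue = "blood")
  expect_lte(res$n[1], 75)
})

test_that("categorical covariates one-hot encode dropping the first level", {
  covars <- tibble::tibble(individual_id = sprintf("i%02d", 1:6),
                           age = c(50, 60, 70, 55, 65, 75),
                           batch = c("b1", "b2", "b3", "b1", "b2", "b3"))
  m <- encode_covariates(covars, covars$individual_id)
  expect_equal(colnames(m), c("age", "batchb2", "batchb3"))
  expect_equal(unname(m[, "batchb2"]), c(0, 1, 0, 0, 1, 0))
})
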