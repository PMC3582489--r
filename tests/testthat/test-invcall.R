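test_that("qc_filter applies the standard thresholds in order", {
  # 50 individuals x 3 informative SNPs; then add pathological columns
  set.seed(7)
  base <- matrix(sample(0:2, 50 * 3, replace = TRUE, prob = c(.25, .5, .25)),
                 50, 3)
  low_maf <- c(rep(1L, 4), rep(2L, 46))             # MAF 0.04 -> dropped
  hwe_bad <- rep(c(0L, 2L), 25)                     # no hets: HWE p ~ 1e-12
  dos <- cbind(base, low_maf, hwe_bad)
  # individual 1 missing 60% of genotypes -> dropped
  dos[1, 1:3] <- NA
  gt <- make_gt(dos, pos = 1:5 * 100)

  out <- suppressMessages(qc_filter(gt))
  expect_equal(nrow(out$dosages), 49)
  expect_false("i01" %in% out$individual_ids)
  expect_false("s04" %in% out$snp_meta$snp_id)  # MAF 0.04 < 0.05
  expect_false("s05" %in% out$snp_meta$snp_id)  # HWE failure

  # per-SNP HWE boundary: p ~ 1e-4 retained, p ~ 1e-6 dropped
  p_s5 <- hwe_chisq(25, 0, 24)$p
  expect_lt(p_s5, 1e-5)
  expect_error(suppressMessages(qc_filter(make_gt(cbind(low_maf), pos = 1))),
               "empty after QC")
})

test_that("normalization matches the hand-computed oracle", {
  # column (0,1,2): mu = 1, p = 0.5, sd = 0.5 -> (-2, 0, 2)
  gt <- make_gt(cbind(c(0L, 1L, 2L), c(0L, 1L, 2L)), pos = c(10, 20))
  z <- encode_and_normalize(gt)
  expect_equal(unname(z[, 1]), c(-2, 0, 2))

  # constant column dropped with warning
  gt2 <- make_gt(cbind(c(0L, 1L, 2L), c(1L, 1L, 1L), c(0L, 1L, 2L)),
                 pos = c(10, 20, 30))
  expect_warning(z2 <- encode_and_normalize(gt2), "zero-variance")
  expect_equal(ncol(z2), 2L)
  expect_error(suppressWarnings(
    encode_and_normalize(make_gt(cbind(c(1L, 1L, 1L), c(0L, 1L, 2L)),
                                 pos = c(10, 20)))),
    "fewer than 2")
})

test_that("normalized columns are mean-centered and missing maps to 0", {
  set.seed(3)
  dos <- matrix(sample(0:2, 40 * 8, replace = TRUE), 40, 8)
  dos[sample(length(dos), 20)] <- NA
  z <- suppressWarnings(encode_and_normalize(make_gt(dos, pos = 1:8)))
  expect_true(all(abs(colMeans(z)) < 1e-12))
  miss <- is.na(make_gt(dos, pos = 1:8)$dosages[, attr(z, "kept_snps")])
  expect_true(all(z[miss] == 0))
})

test_that("principal components agree with a dense eigendecomposition oracle", {
  set.seed(11)
  for (r in 1:20) {
    m <- matrix(rnorm(30 * 15), 30, 15)
    sc <- principal_components(m, k = 2)
    # oracle: eigenvectors of the sample covariance of the centered matrix
    mc <- sweep(m, 2, colMeans(m))
    eg <- eigen(stats::cov(mc), symmetric = TRUE)
    for (j in 1:2) {
      o <- mc %*% eg$vectors[, j]
      got <- sc[[paste0("pc", j)]]
      expect_lt(min(max(abs(got - o)), max(abs(got + o))), 1e-8)
    }
    expect_equal(attr(sc, "explained_variance"), eg$values[1:2],
                 tolerance = 1e-10)
  }
})

test_that("explained variance is ordered and rank limits are enforced", {
  set.seed(5)
  base <- rnorm(10)
  rank1 <- outer(base, c(1, 2, 3))          # all columns proportional
  sc <- principal_components(rank1, k = 2)
  ev <- attr(sc, "explained_variance")
  expect_gt(ev[1], ev[2])
  expect_equal(ev[2], 0, tolerance = 1e-20)
  expect_error(principal_components(rank1, k = 4), "rank")
})

test_that("noiseless cohort collapses to exactly three PC1 values", {
  # 9 individuals, 3 per genotype class, fully divergent clades, no
  # within-clade variation: PC1 must take exactly 3 distinct values
  pools <- simulate_haplotype_pools(12, 0, divergence = 1, flip_rate = 0,
                                    seed = 4)
  haps <- list(H1 = pools$h1_prototype, H2 = pools$h2_prototype)
  combo <- rbind(matrix(rep(haps$H1 + haps$H1, 3), 3, byrow = TRUE),
                 matrix(rep(haps$H1 + haps$H2, 3), 3, byrow = TRUE),
                 matrix(rep(haps$H2 + haps$H2, 3), 3, byrow = TRUE))
  gt <- make_gt(combo, pos = pools$snp_positions)
  sc <- suppressWarnings(pca_genotypes(gt))
  expect_equal(length(unique(round(sc$pc1, 9))), 3L)
})

test_that("perfectly separated PC1 clusters are called without exclusions", {
  scores <- tibble::tibble(individual_id = sprintf("i%02d", 1:9),
                           pc1 = c(-5, -5, -5, 0, 0, 5, 5, 5, 5),
                           pc2 = 0)
  calls <- call_inversion_genotypes(scores)
  expect_equal(sum(calls$label == "H2H2"), 3)
  expect_equal(sum(calls$label == "H1H2"), 2)
  expect_equal(sum(calls$label == "H1H1"), 4)
  expect_equal(attr(calls, "n_excluded"), 0)   # SD = 0 clusters exclude nobody
  expect_equal(calls$dosage[calls$label == "H1H1"][1], 2L)
})

test_that("an individual far between clusters is excluded", {
  set.seed(2)
  pc1 <- c(rnorm(20, -5, 0.1), rnorm(20, 0, 0.1), rnorm(20, 5, 0.1), 2.5)
  scores <- tibble::tibble(pc1 = pc1)
  calls <- call_inversion_genotypes(scores)
  expect_equal(calls$label[61], "EXCLUDED")
  expect_true(is.na(calls$dosage[61]))
  g <- glance(calls)
  expect_equal(g$n_H1H1 + g$n_H1H2 + g$n_H2H2 + g$n_excluded, 61L)
})

test_that("raising sd_limit never increases the excluded count", {
  set.seed(9)
  pc1 <- c(rnorm(50, -4), rnorm(50, 0), rnorm(50, 4))
  scores <- tibble::tibble(pc1 = pc1)
  excl <- vapply(c(1, 2, 3, 4, 6),
                 function(s) attr(call_inversion_genotypes(scores, s),
                                  "n_excluded"),
                 integer(1))
  expect_true(all(diff(excl) <= 0))
})

test_that("degenerate PC1 input raises a clustering error", {
  expect_error(call_inversion_genotypes(tibble::tibble(pc1 = c(1, 1, 1, 2))),
               "degenerate")
  expect_error(call_inversion_genotypes(tibble::tibble(pc1 = c(1, 2))),
               "3 individuals")
})

test_that("calls recover simulated truth at realistic divergence", {
  pools <- simulate_haplotype_pools(60, 20, divergence = 0.8,
                                    flip_rate = 0.05, seed = 5)
  sim <- simulate_cohort(pools, 400, h2_freq = 0.21, seed = 55)
  calls <- call_inversion(sim$genotypes, qc = FALSE)
  j <- dplyr::inner_join(tidy(calls), sim$truth, by = "individual_id")
  ok <- j$label != "EXCLUDED"
  expect_gte(mean(j$dosage[ok] == j$true_dosage[ok]), 0.99)
})

test_that("noiseless pipeline recovery is exact for any seed", {
  for (seed in c(1, 17, 99)) {
    sim <- sim_cohort_fixture(n = 150, h2_freq = 0.2, divergence = 1,
                              flip_rate = 0, seed = seed)
    calls <- call_inversion(sim$genotypes, qc = FALSE)
    j <- dplyr::inner_join(tidy(calls), sim$truth, by = "individual_id")
    expect_true(all(j$label != "EXCLUDED"))
    expect_true(all(j$dosage == j$true_dosage))
  }
})

test_that("HWE chi-square reproduces published genotype-count p-values", {
  expect_equal(round(hwe_chisq(19, 160, 252)$p, 2), 0.31)
  expect_equal(round(hwe_chisq(13, 54, 77)$p, 2), 0.43)
  # exact Hardy-Weinberg proportions: chi2 = 0, p = 1
  r <- hwe_chisq(25, 50, 25)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  expect_error(hwe_chisq(0, 0, 0), "total")
  expect_error(hwe_chisq(-1, 5, 5), "non-negative")
})

test_that("HWE chi-square is invariant under swapping homozygote classes", {
  set.seed(21)
  for (r in 1:25) {
    cnt <- rmultinom(1, 200, c(0.1, 0.4, 0.5))
    a <- hwe_chisq(cnt[1], cnt[2], cnt[3])
    b <- hwe_chisq(cnt[3], cnt[2], cnt[1])
    expect_equal(a$chi2, b$chi2, tolerance = 1e-12)
  }
})
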