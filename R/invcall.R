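#' Genotype-level QC filter
#'
#' Applies the standard pre-PCA quality filters in a fixed order:
#' first individuals with a missing-genotype fraction at or above
#' `max_ind_missing` are dropped, then SNPs failing call rate, minor
#' allele frequency, or the per-SNP Hardy-Weinberg test (MAF and HWE are
#' recomputed after the individual drop).
#'
#' @param genotypes a [genotype_table].
#' @param max_ind_missing drop individuals with missing fraction >= this
#'   (default 0.05).
#' @param min_snp_callrate keep SNPs with call rate above this
#'   (default 0.95, i.e. per-SNP missingness below 0.05).
#' @param min_maf keep SNPs with sample MAF above this (default 0.05).
#' @param min_hwe_p drop SNPs with HWE p below this (default 1e-5).
#' @return filtered [genotype_table]; the counts removed at each step are
#'   recorded in the `"qc_log"` attribute and emitted as a message.
#' @export
qc_filter <- function(genotypes, max_ind_missing = 0.05,
                      min_snp_callrate = 0.95, min_maf = 0.05,
                      min_hwe_p = 1e-5) {
  if (ncol(genotypes$dosages) == 0) abort_param("empty genotype table")

  ind_keep <- individual_missing_rate(genotypes) < max_ind_missing
  gt <- subset_genotypes(genotypes, individuals = which(ind_keep))

  callrate_ok <- snp_call_rate(gt) > min_snp_callrate
  maf_ok <- sample_maf(gt) > min_maf
  hwe_p <- apply(gt$dosages, 2, function(d) {
    tab <- tabulate(d + 1L, nbins = 3L)  # counts of dosage 0,1,2 = mm,mM,MM
    hwe_chisq(tab[1], tab[2], tab[3])$p
  })
  hwe_ok <- hwe_p >= min_hwe_p
  snp_keep <- callrate_ok & maf_ok & hwe_ok
  if (!any(snp_keep))
    stop("empty after QC: no SNPs pass call-rate/MAF/HWE filters",
         call. = FALSE)
  out <- subset_genotypes(gt, snps = which(snp_keep))

  log <- tibble::tibble(
    step = c("individual_missing", "snp_callrate", "snp_maf", "snp_hwe"),
    removed = c(sum(!ind_keep), sum(!callrate_ok),
                sum(callrate_ok & !maf_ok),
                sum(callrate_ok & maf_ok & !hwe_ok))
  )
  message(sprintf("QC: dropped %d individuals, %d SNPs (callrate %d, MAF %d, HWE %d)",
                  sum(!ind_keep), sum(!snp_keep), sum(!callrate_ok),
                  sum(callrate_ok & !maf_ok),
                  sum(callrate_ok & maf_ok & !hwe_ok)))
  attr(out, "qc_log") <- log
  out
}

#' EIGENSTRAT-style genotype normalization
#'
#' Centers each SNP column and scales it by the binomial standard
#' deviation at the estimated allele frequency: with column mean `mu_j`
#' over non-missing entries and `p_j = mu_j / 2`,
#' `z_ij = (g_ij - mu_j) / sqrt(p_j (1 - p_j))`. Missing entries are set
#' to 0 after centering (the column mean), and zero-variance columns
#' (`p_j` 0 or 1, or a constant column) are dropped with a warning.
#'
#' @param genotypes a [genotype_table].
#' @param pseudocount if `TRUE`, estimate the allele frequency with a
#'   pseudocount, `p_j = (1 + sum g) / (2 + 2 n)`, instead of the plain
#'   `mu_j / 2`.
#' @return numeric matrix individuals x polymorphic SNPs; kept column
#'   indices in attribute `"kept_snps"`.
#' @examples
#' gt <- genotype_table(matrix(c(0L, 1L, 2L), 3, 1),
#'                      tibble::tibble(snp_id = "s1", chrom = "chr17",
#'                                     pos = 1, minor = "A", major = "G",
#'                                     maf = 0.5))
#' encode_and_normalize(gt)  # column (-2, 0, 2)
#' @export
encode_and_normalize <- function(genotypes, pseudocount = FALSE) {
  g <- genotypes$dosages
  mu <- colMeans(g, na.rm = TRUE)
  n_obs <- colSums(!is.na(g))
  p <- if (pseudocount) (1 + colSums(g, na.rm = TRUE)) / (2 + 2 * n_obs)
       else mu / 2
  const <- apply(g, 2, function(col) {
    v <- col[!is.na(col)]
    length(unique(v)) <= 1L
  })
  keep <- !(p <= 0 | p >= 1 | const | is.nan(p))
  if (any(!keep))
    warning(sprintf("dropping %d zero-variance SNP column(s)", sum(!keep)))
  if (sum(keep) < 2)
    stop("fewer than 2 polymorphic SNPs remain after normalization",
         call. = FALSE)
  g <- g[, keep, drop = FALSE]
  mu <- mu[keep]; p <- p[keep]
  z <- sweep(g, 2, mu, "-")
  z <- sweep(z, 2, sqrt(p * (1 - p)), "/")
  z[is.na(z)] <- 0
  attr(z, "kept_snps") <- which(keep)
  z
}

#' Principal components of a normalized genotype matrix
#'
#' Projects individuals onto the top-`k` eigenvectors of the sample
#' covariance across individuals. The PC1 sign is fixed by an
#' orientation rule: PC1 correlates non-negatively with `orient` (by
#' default the per-individual mean raw dosage across the interval), so a
#' higher PC1 means a more H1-like genotype. Tied eigenvalues are
#' resolved by input column order (the underlying LAPACK ordering is
#' deterministic for a fixed matrix).
#'
#' @param z normalized matrix from [encode_and_normalize()]
#'   (individuals x SNPs).
#' @param k number of components (default 2).
#' @param orient numeric vector per individual used to fix the PC1 sign;
#'   `NULL` leaves signs as returned by the decomposition.
#' @return a `pc_scores` tibble: `individual_id` (when row names exist),
#'   `pc1`, `pc2`, ...; eigenvalue variances in attribute
#'   `"explained_variance"`.
#' @export
principal_components <- function(z, k = 2, orient = NULL) {
  if (nrow(z) < 2 || ncol(z) < 2)
    abort_param("matrix must have at least 2 rows and 2 columns")
  zc <- sweep(z, 2, colMeans(z), "-")   # covariance eigenvectors need column centering
  if (k > min(dim(zc)))
    stop(sprintf("k = %d exceeds matrix rank (at most %d)", k, min(dim(zc))),
         call. = FALSE)
  sv <- svd(zc, nu = 0, nv = k)
  ev <- sv$d^2 / (nrow(z) - 1)
  # rank-deficient input is fine: trailing components have zero variance
  scores <- zc %*% sv$v[, seq_len(k), drop = FALSE]
  if (!is.null(orient)) {
    for (j in seq_len(k)) {
      r <- suppressWarnings(stats::cor(scores[, j], orient))
      if (!is.na(r) && r < 0) scores[, j] <- -scores[, j]
    }
  }
  out <- tibble::as_tibble(stats::setNames(as.data.frame(scores),
                                           paste0("pc", seq_len(k))))
  if (!is.null(rownames(z)))
    out <- dplyr::bind_cols(tibble::tibble(individual_id = rownames(z)), out)
  attr(out, "explained_variance") <- ev[seq_len(k)]
  class(out) <- c("pc_scores", class(out))
  out
}

#' PCA of a genotype table
#'
#' Convenience wrapper: [encode_and_normalize()] then
#' [principal_components()] with the PC1 orientation tied to mean raw
#' dosage (more major-allele copies across the inversion interval =
#' more H1-like).
#'
#' @inheritParams encode_and_normalize
#' @inheritParams principal_components
#' @return a `pc_scores` tibble.
#' @export
pca_genotypes <- function(genotypes, k = 2, pseudocount = FALSE) {
  z <- encode_and_normalize(genotypes, pseudocount = pseudocount)
  principal_components(z, k = k,
                       orient = rowMeans(genotypes$dosages, na.rm = TRUE))
}

#' Call inversion genotypes from PC1
#'
#' Clusters PC1 into three groups with deterministic one-dimensional
#' k-means (k = 3, Lloyd iterations, centers initialized at the 1/6, 1/2
#' and 5/6 sample quantiles of PC1), orders clusters by mean PC1, and
#' maps them to H1-allele dosage: highest PC1 cluster = H1/H1 (dosage 2),
#' middle = H1/H2 (1), lowest = H2/H2 (0). After fitting, any individual
#' lying more than `sd_limit` within-cluster standard deviations from its
#' own cluster mean is labeled `EXCLUDED` (a single pass; the clusters
#' are not refit). A cluster with zero SD (degenerate, noiseless case)
#' excludes nobody. Genotype counts and the Hardy-Weinberg chi-square
#' test are computed on the remaining individuals.
#'
#' @param scores a `pc_scores` tibble from [pca_genotypes()] (needs
#'   `pc1`; `pc2` is carried through for plotting when present).
#' @param sd_limit exclusion threshold in within-cluster SDs (default 3).
#' @return an `inversion_calls` tibble: `individual_id`, `pc1`, `pc2`,
#'   `label` (`H1H1`/`H1H2`/`H2H2`/`EXCLUDED`), `dosage` (2/1/0, `NA`
#'   when excluded). Cluster means/SDs, class counts and the HWE test
#'   live in attributes and are summarized by [glance.inversion_calls()].
#' @export
call_inversion_genotypes <- function(scores, sd_limit = 3.0) {
  pc1 <- scores$pc1
  if (length(pc1) < 3) abort_param("need at least 3 individuals")
  if (any(!is.finite(pc1))) abort_param("PC1 scores must be finite")
  if (length(unique(pc1)) < 3)
    stop("degenerate clustering: fewer than 3 distinct PC1 values",
         call. = FALSE)

  # two deterministic initializations: the 1/6, 1/2, 5/6 sample quantiles
  # (mass-based) and the same fractions of the PC1 range (spread-based).
  # The mass-based start can collapse onto the majority cluster when the
  # genotype classes are very unbalanced (e.g. 62/33/4%), so both are run
  # and the lower within-SS solution kept; the result stays order-free.
  inits <- list(
    stats::quantile(pc1, c(1, 3, 5) / 6, names = FALSE, type = 7),
    min(pc1) + c(1, 3, 5) / 6 * diff(range(pc1))
  )
  fits <- lapply(inits, function(centers) {
    if (length(unique(centers)) < 3) {
      u <- sort(unique(pc1))
      centers <- u[round(seq(1, length(u), length.out = 3))]
    }
    km <- tryCatch(
      stats::kmeans(pc1, centers = matrix(centers, ncol = 1),
                    algorithm = "Lloyd", iter.max = 100),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (!is.null(km))
      list(cluster = km$cluster, ss = sum(km$withinss))
    else {
      cl <- apply(abs(outer(pc1, centers, "-")), 1, which.min)
      mu <- tapply(pc1, factor(cl, levels = 1:3), mean)
      list(cluster = cl, ss = sum((pc1 - mu[cl])^2, na.rm = TRUE))
    }
  })
  assign <- fits[[which.min(vapply(fits, `[[`, numeric(1), "ss"))]]$cluster

  means <- tapply(pc1, factor(assign, levels = 1:3), mean)
  if (any(is.na(means)))
    warning("empty cluster after k-means; that genotype class has count 0")
  ord <- order(means)                       # ascending PC1
  dosage_of_cluster <- integer(3)
  dosage_of_cluster[ord] <- 0:2             # lowest PC1 -> H2/H2 (0)
  dosage <- dosage_of_cluster[assign]

  cl_mean <- tapply(pc1, dosage, mean)
  cl_sd <- tapply(pc1, dosage, stats::sd)
  cl_sd[is.na(cl_sd)] <- 0                  # singleton cluster: SD 0, no exclusion
  dev <- abs(pc1 - cl_mean[as.character(dosage)])
  lim <- cl_sd[as.character(dosage)]
  excluded <- lim > 0 & dev > sd_limit * lim

  lab <- unname(c(`0` = "H2H2", `1` = "H1H2", `2` = "H1H1")[as.character(dosage)])
  lab[excluded] <- "EXCLUDED"
  dosage[excluded] <- NA_integer_

  counts <- c(n_H1H1 = sum(lab == "H1H1"), n_H1H2 = sum(lab == "H1H2"),
              n_H2H2 = sum(lab == "H2H2"))
  hwe <- hwe_chisq(counts[["n_H2H2"]], counts[["n_H1H2"]], counts[["n_H1H1"]])

  out <- tibble::tibble(
    individual_id = if ("individual_id" %in% names(scores)) scores$individual_id
                    else sprintf("ind%04d", seq_along(pc1)),
    pc1 = pc1,
    pc2 = if ("pc2" %in% names(scores)) scores$pc2 else NA_real_,
    label = lab,
    dosage = as.integer(dosage)
  )
  structure(out,
            class = c("inversion_calls", class(out)),
            cluster_mean = as.numeric(cl_mean), cluster_sd = as.numeric(cl_sd),
            counts = counts, n_excluded = sum(excluded),
            hwe_chi2 = hwe$chi2, hwe_p = hwe$p, sd_limit = sd_limit)
}

#' Summarize inversion calls
#'
#' @param x an `inversion_calls` tibble.
#' @param ... unused.
#' @return one-row tibble: class counts, exclusions, HWE chi-square and p.
#' @exportS3Method generics::glance
#' @export
glance.inversion_calls <- function(x, ...) {
  cnt <- attr(x, "counts")
  tibble::tibble(
    n = nrow(x), n_H1H1 = cnt[["n_H1H1"]], n_H1H2 = cnt[["n_H1H2"]],
    n_H2H2 = cnt[["n_H2H2"]], n_excluded = attr(x, "n_excluded"),
    hwe_chi2 = attr(x, "hwe_chi2"), hwe_p = attr(x, "hwe_p")
  )
}

#' @exportS3Method generics::tidy
#' @export
tidy.inversion_calls <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("individual_id", "pc1", "pc2", "label", "dosage")])
}

#' One-degree-of-freedom Hardy-Weinberg chi-square test
#'
#' Estimates the minor-allele frequency from the genotype counts,
#' `q = (2 a + b) / (2N)` with `a` minor homozygotes and `b`
#' heterozygotes, forms HWE expected counts `(N q^2, 2N q(1-q),
#' N (1-q)^2)`, and compares with a chi-square statistic on 1 df
#' (3 classes minus 1 estimated allele frequency minus 1). Classes with
#' expected count 0 contribute nothing.
#'
#' @param n_hom_minor,n_het,n_hom_major non-negative genotype counts;
#'   total >= 1.
#' @return list with `chi2` and upper-tail `p`.
#' @examples
#' hwe_chisq(19, 160, 252)  # p = 0.31
#' hwe_chisq(13, 54, 77)    # p = 0.43
#' @export
hwe_chisq <- function(n_hom_minor, n_het, n_hom_major) {
  obs <- c(n_hom_minor, n_het, n_hom_major)
  if (any(obs < 0)) abort_param("genotype counts must be non-negative")
  N <- sum(obs)
  if (N < 1) abort_param("total genotype count must be >= 1")
  q <- (2 * n_hom_minor + n_het) / (2 * N)
  expct <- N * c(q^2, 2 * q * (1 - q), (1 - q)^2)
  nz <- expct > 0
  chi2 <- sum((obs[nz] - expct[nz])^2 / expct[nz])
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Full inversion-calling pipeline for a genotype table
#'
#' QC filter (optional), subset to the inversion interval, normalize,
#' PCA, and call genotypes.
#'
#' @param genotypes a [genotype_table].
#' @param interval inversion interval (default the 17q21.31 window).
#' @param sd_limit exclusion threshold, see [call_inversion_genotypes()].
#' @param qc apply [qc_filter()] first (default TRUE).
#' @param ... passed to [qc_filter()].
#' @return an `inversion_calls` tibble.
#' @export
call_inversion <- function(genotypes, interval = inversion_interval_default(),
                           sd_limit = 3.0, qc = TRUE, ...) {
  if (qc) genotypes <- qc_filter(genotypes, ...)
  local <- select_region(genotypes, interval)
  if (ncol(local$dosages) < 2)
    stop("fewer than 2 SNPs in the inversion interval", call. = FALSE)
  scores <- pca_genotypes(local, k = 2)
  call_inversion_genotypes(scores, sd_limit = sd_limit)
}
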