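#' Default study intervals
#'
#' The inversion interval and the cis window (1 Mb each side of the
#' inversion) used throughout, on UCSC March 2006 text coordinates.
#' @name study_intervals
NULL

#' @rdname study_intervals
#' @export
inversion_interval_default <- function() genomic_interval("chr17", 40850001, 41850000)

#' @rdname study_intervals
#' @export
cis_interval_default <- function() genomic_interval("chr17", 39899921, 42989253)

#' Simulate two divergent haplotype prototype pools
#'
#' Builds the generative haplotype model for a polymorphic inversion: two
#' clade prototypes (H1, the direct orientation; H2, the inverted one)
#' that differ at `round(divergence * n_inside)` of the sites inside the
#' inversion. Recombination between orientations is suppressed, so the
#' clades stay divergent; within-clade diversity enters as independent
#' per-site flips at rate `flip_rate` when haplotypes are drawn. Sites
#' outside the inversion are clade-independent common variants with MAF
#' drawn uniformly in \[0.05, 0.5\].
#'
#' @param n_inside number of SNPs inside the inversion (>= 2).
#' @param n_outside number of flanking SNPs in the cis region.
#' @param divergence fraction of inside sites fixed between clades, in (0, 1\].
#' @param flip_rate per-site within-clade flip probability, in \[0, 0.5).
#' @param seed integer seed.
#' @param inversion,cis genomic intervals the positions are drawn in.
#' @return a `haplotype_pools` object: `h1_prototype`, `h2_prototype`
#'   (binary vectors), `within_clade_flip_rate`, `snp_positions`,
#'   `inside_inversion` mask, `outside_maf`, `chrom`.
#' @examples
#' pools <- simulate_haplotype_pools(60, 20, divergence = 0.8,
#'                                   flip_rate = 0.05, seed = 1)
#' sum(pools$h1_prototype != pools$h2_prototype)  # 48 divergent sites
#' @export
simulate_haplotype_pools <- function(n_inside, n_outside = 0,
                                     divergence = 0.8, flip_rate = 0.05,
                                     seed = 1,
                                     inversion = inversion_interval_default(),
                                     cis = cis_interval_default()) {
  if (n_inside < 2) abort_param("n_inside must be >= 2")
  if (!(divergence > 0 && divergence <= 1))
    abort_param("divergence must lie in (0, 1]")
  if (!(flip_rate >= 0 && flip_rate < 0.5))
    abort_param("flip_rate must lie in [0, 0.5)")
  set.seed(seed)

  pos_in <- sort(sample(seq(inversion$start, inversion$end), n_inside))
  pos_out <- if (n_outside > 0) {
    flank <- c(seq(cis$start, inversion$start - 1L),
               seq(inversion$end + 1L, cis$end))
    sort(sample(flank, n_outside))
  } else numeric(0)
  pos <- sort(c(pos_in, pos_out))
  inside <- pos %in% pos_in

  n <- n_inside + n_outside
  h1 <- rbinom(n, 1L, 0.5)
  h2 <- h1
  n_div <- round(divergence * n_inside)
  div_sites <- sample(which(inside), n_div)
  h2[div_sites] <- 1L - h2[div_sites]
  # outside sites carry no clade signal; record their population MAF
  outside_maf <- rep(NA_real_, n)
  outside_maf[!inside] <- runif(sum(!inside), 0.05, 0.5)

  structure(list(h1_prototype = h1, h2_prototype = h2,
                 within_clade_flip_rate = flip_rate,
                 snp_positions = pos, inside_inversion = inside,
                 outside_maf = outside_maf, chrom = inversion$chrom,
                 divergent_sites = sort(div_sites)),
            class = "haplotype_pools")
}

# draw one haplotype (binary allele vector) from a clade
draw_haplotype <- function(pools, clade) {
  proto <- if (clade == "H1") pools$h1_prototype else pools$h2_prototype
  h <- proto
  inside <- pools$inside_inversion
  flips <- runif(sum(inside)) < pools$within_clade_flip_rate
  h[inside][flips] <- 1L - h[inside][flips]
  out <- !inside
  if (any(out)) h[out] <- as.integer(runif(sum(out)) < pools$outside_maf[out])
  h
}

#' Simulate a genotyped cohort under Hardy-Weinberg sampling
#'
#' Each individual receives two haplotypes drawn independently, each from
#' clade H2 with probability `h2_freq` (random-mating HWE sampling, so the
#' three inversion genotypes occur at p^2 : 2pq : q^2). Per-site genotypes
#' are allele sums recoded to the m/m = 0, m/M = 1, M/M = 2 convention
#' with the minor allele re-determined from sample frequency (ties broken
#' so the H1-prototype allele counts as major). Genotypes are masked
#' missing independently at `missing_rate`.
#'
#' @param pools a `haplotype_pools` from [simulate_haplotype_pools()].
#' @param n_individuals cohort size (>= 3; fewer makes downstream
#'   clustering impossible).
#' @param h2_freq H2 clade frequency in \[0, 1\] (about 0.2 in European
#'   populations).
#' @param missing_rate per-genotype missing probability in \[0, 1).
#' @param seed integer seed.
#' @return list with `genotypes` (a [genotype_table]) and `truth` (a
#'   `sim_truth` tibble: `individual_id`, `true_dosage` = H1-haplotype
#'   count, `ambiguous`).
#' @examples
#' pools <- simulate_haplotype_pools(60, 0, seed = 1)
#' sim <- simulate_cohort(pools, 200, h2_freq = 0.2, seed = 2)
#' table(sim$truth$true_dosage)
#' @export
simulate_cohort <- function(pools, n_individuals, h2_freq = 0.2,
                            missing_rate = 0, seed = 1) {
  if (n_individuals < 3)
    abort_param("n_individuals must be >= 3 (downstream clustering impossible)")
  if (h2_freq < 0 || h2_freq > 1) abort_param("h2_freq must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1)
    abort_param("missing_rate must lie in [0, 1)")
  set.seed(seed)

  n_snp <- length(pools$h1_prototype)
  clades <- matrix(ifelse(runif(2 * n_individuals) < h2_freq, "H2", "H1"),
                   nrow = n_individuals, ncol = 2)
  hapA <- t(vapply(seq_len(n_individuals),
                   function(i) draw_haplotype(pools, clades[i, 1]),
                   integer(n_snp)))
  hapB <- t(vapply(seq_len(n_individuals),
                   function(i) draw_haplotype(pools, clades[i, 2]),
                   integer(n_snp)))
  raw <- hapA + hapB  # counts of allele "1" per site

  ids <- sprintf("ind%04d", seq_len(n_individuals))
  truth <- tibble::tibble(
    individual_id = ids,
    true_dosage = rowSums(clades == "H1"),
    ambiguous = FALSE
  )

  gt <- build_genotype_table(raw, pools, ids, missing_rate)
  truth <- structure(truth, class = c("sim_truth", class(truth)),
                     haplotypes = list(A = hapA, B = hapB),
                     pools = pools,
                     major_is_allele1 = attr(gt, "major_is_allele1"))
  list(genotypes = gt, truth = truth)
}

# recode raw allele-1 counts to major-allele dosage and assemble the table.
# major_is_allele1 may be supplied to keep a previous orientation.
build_genotype_table <- function(raw, pools, ids, missing_rate = 0,
                                 major_is_allele1 = NULL) {
  n_snp <- ncol(raw)
  freq1 <- colMeans(raw) / 2
  if (is.null(major_is_allele1)) {
    # ties (freq exactly 0.5) break toward the H1-prototype allele as major
    major_is_allele1 <- freq1 > 0.5 |
      (freq1 == 0.5 & pools$h1_prototype == 1L)
  }
  dos <- raw
  dos[, !major_is_allele1] <- 2L - dos[, !major_is_allele1, drop = FALSE]
  # dosage now counts the major allele (m/m = 0 convention)

  if (missing_rate > 0) {
    mask <- matrix(runif(length(dos)) < missing_rate, nrow = nrow(dos))
    dos[mask] <- NA_integer_
  }

  alleles <- c("A", "G")  # allele 0 = A, allele 1 = G by construction
  major <- ifelse(major_is_allele1, alleles[2], alleles[1])
  minor <- ifelse(major_is_allele1, alleles[1], alleles[2])
  maf <- pmin(freq1, 1 - freq1)
  meta <- tibble::tibble(
    snp_id = sprintf("snp%04d", seq_len(n_snp)),
    chrom = pools$chrom, pos = pools$snp_positions,
    minor = minor, major = major, maf = maf,
    inside_inversion = pools$inside_inversion
  )
  out <- genotype_table(dos, meta, ids)
  attr(out, "major_is_allele1") <- major_is_allele1
  out
}

#' Inject recombinant (ambiguous) individuals
#'
#' Replaces one haplotype of a random subset of individuals with a single
#' crossover product whose inside-inversion sequence is H1-like on one
#' side of a random breakpoint and H2-like on the other. Such individuals
#' have no well-defined inversion dosage; under PCA their PC1 falls
#' between the genotype clusters and the caller should exclude them
#' (> 3 SD from every cluster mean). Their truth rows are marked
#' `ambiguous` and `true_dosage` is set to `NA`.
#'
#' @param genotypes a [genotype_table] from [simulate_cohort()].
#' @param truth the matching `sim_truth`.
#' @param fraction fraction of individuals to convert, in \[0, 0.5).
#' @param seed integer seed.
#' @return list with updated `genotypes` and `truth`.
#' @export
inject_recombinants <- function(genotypes, truth, fraction, seed = 1) {
  if (fraction < 0 || fraction >= 0.5)
    abort_param("fraction must lie in [0, 0.5)")
  n_rec <- round(fraction * nrow(genotypes$dosages))
  if (n_rec == 0) return(list(genotypes = genotypes, truth = truth))
  set.seed(seed)

  pools <- attr(truth, "pools")
  haps <- attr(truth, "haplotypes")
  major1 <- attr(truth, "major_is_allele1")
  pick <- sample(nrow(genotypes$dosages), n_rec)
  inside_idx <- which(pools$inside_inversion)

  for (i in pick) {
    # crossover at a random inside site: left half H1-like, right H2-like
    brk <- sample(seq_along(inside_idx)[-1], 1)
    rec <- pools$h1_prototype
    right <- inside_idx[seq(brk, length(inside_idx))]
    rec[right] <- pools$h2_prototype[right]
    haps$A[i, ] <- rec
  }
  raw <- haps$A + haps$B
  gt <- build_genotype_table(raw, pools, genotypes$individual_ids,
                             missing_rate = 0, major_is_allele1 = major1)
  # re-apply original missingness pattern
  gt$dosages[is.na(genotypes$dosages)] <- NA_integer_
  gt2 <- genotype_table(gt$dosages, gt$snp_meta, gt$individual_ids)
  attr(gt2, "major_is_allele1") <- major1

  truth$ambiguous[pick] <- TRUE
  truth$true_dosage[pick] <- NA_integer_
  attr(truth, "haplotypes") <- haps
  list(genotypes = gt2, truth = truth)
}

#' Simulate a covariate table
#'
#' Age uniform on 40-80 years, gender Bernoulli(0.5), and optionally a
#' categorical batch factor with `batch_levels` levels.
#'
#' @param n_individuals cohort size.
#' @param seed integer seed.
#' @param batch_levels 0 for no batch factor, else number of levels.
#' @param individual_ids optional IDs (defaults to the simulator's).
#' @return tibble with `individual_id`, `age`, `gender`, optionally `batch`.
#' @export
simulate_covariates <- function(n_individuals, seed = 1, batch_levels = 0,
                                individual_ids = sprintf("ind%04d", seq_len(n_individuals))) {
  set.seed(seed)
  out <- tibble::tibble(
    individual_id = individual_ids,
    age = runif(n_individuals, 40, 80),
    gender = ifelse(runif(n_individuals) < 0.5, "male", "female")
  )
  if (batch_levels > 0)
    out$batch <- sprintf("batch%d", sample.int(batch_levels, n_individuals,
                                               replace = TRUE))
  out
}

#' Simulate dosage-linked expression
#'
#' Generates probe expression as a linear function of true inversion
#' dosage plus covariate effects and Gaussian noise:
#' `y_ij = intercept_i + B_i * dosage_j + X_j gamma + e`,
#' `e ~ N(0, noise_sd^2)`. `B_i` is the log2-expression change per H1
#' copy. Probe metadata (gene, interval inside the cis window, random
#' 50-mer sequence) is generated alongside; the detection statistic is
#' 1.0 for all probes unless `low_detection_probes` requests otherwise.
#'
#' @param truth `sim_truth` from [simulate_cohort()] (supplies dosages).
#' @param probe_effects numeric vector of per-copy effects, one per probe.
#' @param covariates optional covariate tibble from [simulate_covariates()];
#'   numeric columns enter with effects `covariate_effects`.
#' @param covariate_effects named numeric vector (defaults: age 0.002,
#'   gender 0.05 for the male level).
#' @param noise_sd residual standard deviation (> 0 unless `exact = TRUE`
#'   noiseless runs are wanted; 0 is allowed and yields deterministic
#'   expression).
#' @param intercepts per-probe intercepts (default 8, a typical log2
#'   array intensity).
#' @param seed integer seed.
#' @param cis interval the probe coordinates are drawn in.
#' @param low_detection_probes indices of probes to mark with detection
#'   0.5 (blood mode) so the detection filter has something to remove.
#' @return an [expression_table]; true effects are recorded in
#'   `probe_meta$true_effect`.
#' @export
simulate_expression <- function(truth, probe_effects, covariates = NULL,
                                covariate_effects = c(age = 0.002, gender = 0.05),
                                noise_sd = 0.3, intercepts = 8, seed = 1,
                                cis = cis_interval_default(),
                                low_detection_probes = integer(0)) {
  if (noise_sd < 0) abort_param("noise_sd must be >= 0")
  n_probes <- length(probe_effects)
  n_ind <- nrow(truth)
  if (!is.null(covariates) && nrow(covariates) != n_ind)
    abort_param("covariates row count must equal individual count")
  set.seed(seed)

  dosage <- truth$true_dosage
  dosage[is.na(dosage)] <- 1L  # recombinants behave like carriers of one H1-like haplotype
  intercepts <- rep_len(intercepts, n_probes)

  cov_term <- rep(0, n_ind)
  if (!is.null(covariates)) {
    if ("age" %in% names(covariates) && "age" %in% names(covariate_effects))
      cov_term <- cov_term + covariate_effects[["age"]] * covariates$age
    if ("gender" %in% names(covariates) && "gender" %in% names(covariate_effects))
      cov_term <- cov_term + covariate_effects[["gender"]] * (covariates$gender == "male")
  }

  vals <- matrix(NA_real_, n_probes, n_ind)
  for (i in seq_len(n_probes)) {
    mu <- intercepts[i] + probe_effects[i] * dosage + cov_term
    vals[i, ] <- mu + if (noise_sd > 0) rnorm(n_ind, 0, noise_sd) else 0
  }

  starts <- sort(sample(seq(cis$start, cis$end - 49L), n_probes))
  detection <- rep(1, n_probes)
  detection[low_detection_probes] <- 0.5
  meta <- tibble::tibble(
    probe_id = sprintf("probe%03d", seq_len(n_probes)),
    gene = sprintf("GENE%03d", seq_len(n_probes)),
    chrom = cis$chrom, start = starts, end = starts + 49L,
    sequence = random_50mers(n_probes),
    detection = detection,
    true_effect = probe_effects
  )
  expression_table(vals, meta, truth$individual_id)
}

random_50mers <- function(n) {
  vapply(seq_len(n),
         function(i) paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                           collapse = ""),
         character(1))
}
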