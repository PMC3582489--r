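#' Genotype dosage table
#'
#' Container for an individuals-by-SNPs dosage matrix plus SNP metadata.
#' Dosages follow the m/m = 0, m/M = 1, M/M = 2 encoding, i.e. each value
#' counts copies of the *major* allele; `NA` marks a missing genotype.
#' SNP positions must be strictly increasing within a chromosome, and MAF
#' lies in \[0, 0.5\].
#'
#' @param dosages integer matrix, rows = individuals, columns = SNPs,
#'   values in `{0, 1, 2, NA}`.
#' @param snp_meta tibble with columns `snp_id`, `chrom`, `pos`,
#'   `minor`, `major`, `maf`.
#' @param individual_ids character vector, one per matrix row.
#' @return a `genotype_table`.
#' @export
genotype_table <- function(dosages, snp_meta, individual_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  snp_meta <- tibble::as_tibble(snp_meta)
  if (is.null(individual_ids))
    individual_ids <- sprintf("ind%04d", seq_len(nrow(dosages)))
  stopifnot(nrow(snp_meta) == ncol(dosages),
            length(individual_ids) == nrow(dosages))
  bad <- !(dosages %in% c(0L, 1L, 2L) | is.na(dosages))
  if (any(bad)) abort_param("dosage values must be 0, 1, 2 or NA")
  for (ch in unique(snp_meta$chrom)) {
    p <- snp_meta$pos[snp_meta$chrom == ch]
    if (any(diff(p) <= 0))
      abort_param(sprintf("SNP positions not strictly increasing on %s", ch))
  }
  if (any(snp_meta$maf < 0 | snp_meta$maf > 0.5, na.rm = TRUE))
    abort_param("MAF must lie in [0, 0.5]")
  rownames(dosages) <- individual_ids
  colnames(dosages) <- snp_meta$snp_id
  structure(list(dosages = dosages, snp_meta = snp_meta,
                 individual_ids = as.character(individual_ids)),
            class = "genotype_table")
}

subset_genotypes <- function(x, individuals = NULL, snps = NULL) {
  d <- x$dosages; meta <- x$snp_meta; ids <- x$individual_ids
  if (!is.null(individuals)) {
    d <- d[individuals, , drop = FALSE]
    ids <- ids[individuals]
  }
  if (!is.null(snps)) {
    d <- d[, snps, drop = FALSE]
    meta <- meta[snps, , drop = FALSE]
  }
  genotype_table(d, meta, ids)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d individuals x %d SNPs (%s)\n",
              nrow(x$dosages), ncol(x$dosages),
              paste(unique(x$snp_meta$chrom), collapse = ",")))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing: %.2f%%; MAF range: [%.3f, %.3f]\n", 100 * miss,
              min(x$snp_meta$maf), max(x$snp_meta$maf)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a genotype table into long form
#'
#' @param x a [genotype_table].
#' @param ... unused.
#' @return tibble with one row per (individual, SNP): `individual_id`,
#'   `snp_id`, `chrom`, `pos`, `dosage`.
#' @exportS3Method generics::tidy
#' @export
tidy.genotype_table <- function(x, ...) {
  tibble::tibble(
    individual_id = rep(x$individual_ids, times = ncol(x$dosages)),
    snp_id  = rep(x$snp_meta$snp_id, each = nrow(x$dosages)),
    chrom   = rep(x$snp_meta$chrom, each = nrow(x$dosages)),
    pos     = rep(x$snp_meta$pos, each = nrow(x$dosages)),
    dosage  = as.integer(x$dosages)
  )
}

# per-individual missing fraction / per-SNP call rate helpers
individual_missing_rate <- function(x) rowMeans(is.na(x$dosages))
snp_call_rate <- function(x) colMeans(!is.na(x$dosages))

# recompute sample MAF from the dosage matrix (dosage counts major allele)
sample_maf <- function(x) {
  maj <- colMeans(x$dosages, na.rm = TRUE) / 2
  pmin(maj, 1 - maj)
}
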