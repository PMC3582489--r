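#' Read genotypes from VCF or dosage TSV
#'
#' VCF reading (via vcfR) uses GT fields only: `0/0`, `0/1`, `1/1` and
#' `./.` map to hom-ref, het, hom-alt and missing; phased separators are
#' accepted. Non-biallelic records are skipped with a warning. After
#' parsing, the minor allele is determined from sample frequency and
#' dosages are recoded to the m/m = 0, m/M = 1, M/M = 2 convention
#' (dosage counts the major allele).
#'
#' The dosage TSV dialect is written by [write_genotypes()]: one row per
#' SNP, columns `snp_id`, `chrom`, `pos`, `minor`, `major`, `maf`, then
#' one column per individual with `.` for missing.
#'
#' @param path file path.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return a [genotype_table].
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_param(sprintf("file not found: %s", path))
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | fix$ALT == "."
  if (any(multi)) {
    warning(sprintf("skipping %d non-biallelic record(s)", sum(multi)))
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")   # SNPs x individuals
  g <- gsub("\\|", "/", gt)
  bad <- !is.na(g) & !g %in% c("0/0", "0/1", "1/0", "1/1", "./.")
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("unparseable GT '%s' at record %d (%s)", g[bad][1], idx[1],
                 colnames(g)[idx[2]]), call. = FALSE)
  }
  alt_count <- matrix(NA_integer_, nrow(g), ncol(g))
  alt_count[g == "0/0"] <- 0L
  alt_count[g %in% c("0/1", "1/0")] <- 1L
  alt_count[g == "1/1"] <- 2L
  alt_count <- t(alt_count)          # individuals x SNPs

  freq_alt <- colMeans(alt_count, na.rm = TRUE) / 2
  major_is_alt <- !is.na(freq_alt) & freq_alt > 0.5
  dos <- alt_count
  dos[, !major_is_alt] <- 2L - dos[, !major_is_alt, drop = FALSE]
  maf <- pmin(freq_alt, 1 - freq_alt)
  maf[is.na(maf)] <- 0

  meta <- tibble::tibble(
    snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                    sprintf("%s:%s", fix$CHROM, fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.numeric(fix$POS),
    minor = ifelse(major_is_alt, fix$REF, fix$ALT),
    major = ifelse(major_is_alt, fix$ALT, fix$REF),
    maf = maf
  )
  genotype_table(dos, meta, colnames(gt))
}

read_genotypes_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), na = ".",
                        progress = FALSE)
  meta_cols <- c("snp_id", "chrom", "pos", "minor", "major", "maf")
  if (!all(meta_cols %in% names(df)))
    abort_param("dosage TSV missing metadata columns")
  ind_cols <- setdiff(names(df), c(meta_cols, "inside_inversion"))
  dos <- t(as.matrix(df[, ind_cols]))
  storage.mode(dos) <- "integer"
  genotype_table(dos, df[, intersect(names(df), c(meta_cols, "inside_inversion"))],
                 ind_cols)
}

#' Write genotypes as dosage TSV or VCF
#'
#' @param gt a [genotype_table].
#' @param path output path.
#' @param format `"dosage_tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path, format = c("dosage_tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "dosage_tsv") {
    df <- dplyr::bind_cols(
      gt$snp_meta[, c("snp_id", "chrom", "pos", "minor", "major", "maf")],
      tibble::as_tibble(t(gt$dosages))
    )
    readr::write_tsv(df, path, na = ".", progress = FALSE)
  } else {
    write_genotypes_vcf(gt, path)
  }
  invisible(path)
}

# minimal VCF 4.2 writer: REF = major, ALT = minor, so alt count = 2 - dosage
write_genotypes_vcf <- function(gt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gt$individual_ids), collapse = "\t")),
             con)
  gt_strings <- c("1/1", "0/1", "0/0")  # dosage 0,1,2 -> alt count 2,1,0
  for (j in seq_len(ncol(gt$dosages))) {
    d <- gt$dosages[, j]
    calls <- ifelse(is.na(d), "./.", gt_strings[d + 1L])
    m <- gt$snp_meta[j, ]
    writeLines(paste(c(m$chrom, format(m$pos, scientific = FALSE), m$snp_id,
                       m$major, m$minor, ".", "PASS", ".", "GT", calls),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write an expression TSV
#'
#' Layout: one row per probe; metadata columns `probe_id`, `gene`,
#' `chrom`, `start`, `end`, `detection` (and optionally `sequence`),
#' then one numeric column per individual. A non-numeric expression cell
#' is a parse error reporting its coordinates.
#'
#' @param path file path.
#' @return an [expression_table].
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort_param(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  meta_cols <- intersect(c("probe_id", "gene", "chrom", "start", "end",
                           "sequence", "detection", "true_effect"), names(df))
  ind_cols <- setdiff(names(df), meta_cols)
  for (cc in ind_cols) {
    if (!is.numeric(df[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))))[1]
      abort_param(sprintf("non-numeric expression value at probe row %d, column '%s'",
                          bad, cc))
    }
  }
  expression_table(as.matrix(df[, ind_cols]), df[, meta_cols], ind_cols)
}

#' @rdname read_expression
#' @param expr an [expression_table].
#' @export
write_expression <- function(expr, path) {
  df <- dplyr::bind_cols(expr$probe_meta, tibble::as_tibble(expr$values))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Write / read an eQTL association table
#'
#' TSV with columns `probe_id`, `gene`, `tissue`, `n`, `B`, `SE`, `t`,
#' `CI_low`, `CI_high`, `p`, `significant`. Values round-trip to full
#' double precision.
#'
#' @param eqtl an eQTL results tibble from [run_cis_eqtl()].
#' @param path output path.
#' @export
write_results <- function(eqtl, path) {
  cols <- c("probe_id", "gene", "tissue", "n", "B", "SE", "t",
            "CI_low", "CI_high", "p", "significant")
  readr::write_tsv(eqtl[, cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}

#' Read probe intervals from BED
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention on read (start + 1, end unchanged).
#'
#' @param path BED file (3+ columns; column 4, when present, is the
#'   probe id).
#' @return tibble with `probe_id`, `chrom`, `start`, `end`.
#' @export
read_probes_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  tibble::tibble(
    probe_id = if (ncol(df) >= 4) df[[4]] else sprintf("probe%03d", seq_len(nrow(df))),
    chrom = df[[1]], start = df[[2]] + 1L, end = df[[3]]
  )
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA file.
#' @return tibble with `transcript_id`, `gene` (id up to the first `_` or
#'   the full id), `sequence`.
#' @export
read_transcripts <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    abort_param("read_transcripts requires the Biostrings package")
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  tibble::tibble(
    transcript_id = ids,
    gene = sub("_.*$", "", ids),
    sequence = as.character(seqs)
  )
}

#' Write a covariate / truth table as TSV
#' @param df a tibble.
#' @param path output path.
#' @export
write_table_tsv <- function(df, path) {
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}
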