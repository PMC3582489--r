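# small in-code fixtures shared across tests

# genotype table straight from a dosage matrix (individuals x SNPs)
make_gt <- function(dos, pos = seq_len(ncol(dos)), chrom = "chr17",
                    maf = NULL) {
  dos <- as.matrix(dos)
  if (is.null(maf)) {
    mu <- colMeans(dos, na.rm = TRUE) / 2
    maf <- pmin(mu, 1 - mu)
  }
  genotype_table(
    dos,
    tibble::tibble(snp_id = sprintf("s%02d", seq_len(ncol(dos))),
                   chrom = chrom, pos = pos,
                   minor = "A", major = "G", maf = maf),
    sprintf("i%02d", seq_len(nrow(dos)))
  )
}

# expression table from a probe x individual matrix
make_expr <- function(vals, start = seq(41e6, by = 100, length.out = nrow(vals)),
                      detection = rep(1, nrow(vals)), sequence = NULL,
                      chrom = "chr17") {
  vals <- as.matrix(vals)
  meta <- tibble::tibble(
    probe_id = sprintf("p%02d", seq_len(nrow(vals))),
    gene = sprintf("G%02d", seq_len(nrow(vals))),
    chrom = chrom, start = start, end = start + 49,
    detection = detection
  )
  if (!is.null(sequence)) meta$sequence <- sequence
  expression_table(vals, meta,
                   colnames(vals) %||% sprintf("i%02d", seq_len(ncol(vals))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal VCF text for n individuals x records given as alt-allele counts
write_tiny_vcf <- function(path, alt_counts, pos = seq_len(nrow(alt_counts)) * 10,
                           chrom = "chr17") {
  ids <- sprintf("i%02d", seq_len(ncol(alt_counts)))
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"))
  gtmap <- c("0/0", "0/1", "1/1")
  for (r in seq_len(nrow(alt_counts))) {
    calls <- ifelse(is.na(alt_counts[r, ]), "./.", gtmap[alt_counts[r, ] + 1L])
    lines <- c(lines, paste(c(chrom, pos[r], sprintf("rs%d", r), "A", "G", ".",
                              "PASS", ".", "GT", calls), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# standard small simulated cohort used by several tests
sim_cohort_fixture <- function(n = 200, h2_freq = 0.2, divergence = 1,
                               flip_rate = 0, n_inside = 40, n_outside = 0,
                               missing_rate = 0, seed = 1) {
  pools <- simulate_haplotype_pools(n_inside, n_outside,
                                    divergence = divergence,
                                    flip_rate = flip_rate, seed = seed)
  simulate_cohort(pools, n, h2_freq = h2_freq, missing_rate = missing_rate,
                  seed = seed + 100)
}
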