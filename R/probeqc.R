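#' Flag common SNPs inside probe footprints
#'
#' An expression probe whose 50-mer genomic footprint contains a common
#' polymorphism can report genotype, not expression: the mismatch under
#' the probe changes hybridization efficiency by allele. A SNP confounds
#' a probe iff `probe.start <= pos <= probe.end` (1-based inclusive) and
#' its MAF exceeds `maf_min` (default 0.01, the conventional "common"
#' cutoff).
#'
#' @param probes tibble with `probe_id`, `chrom`, `start`, `end` (or an
#'   [expression_table], whose `probe_meta` is used). Probes without
#'   interval annotation are skipped with a warning.
#' @param snp_meta tibble with `snp_id`, `chrom`, `pos`, `maf` (e.g. the
#'   `snp_meta` of a [genotype_table]).
#' @param maf_min MAF threshold; SNPs at or below it are ignored.
#' @return tibble, one row per probe: `probe_id`, `n_snps_in_probe`,
#'   `snp_confounded`, and `snps` (list-column of the flagged SNP rows).
#' @export
snps_in_probe <- function(probes, snp_meta, maf_min = 0.01) {
  if (inherits(probes, "expression_table")) probes <- probes$probe_meta
  probes <- tibble::as_tibble(probes)
  no_iv <- is.na(probes$start) | is.na(probes$end)
  if (any(no_iv)) {
    warning(sprintf("skipping %d probe(s) without interval annotation",
                    sum(no_iv)))
    probes <- probes[!no_iv, , drop = FALSE]
  }
  common <- snp_meta[snp_meta$maf > maf_min, , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(probes)), function(i) {
    p <- probes[i, ]
    hit <- common[common$chrom == p$chrom &
                    common$pos >= p$start & common$pos <= p$end,
                  c("snp_id", "pos", "maf"), drop = FALSE]
    tibble::tibble(probe_id = p$probe_id,
                   n_snps_in_probe = nrow(hit),
                   snp_confounded = nrow(hit) > 0,
                   snps = list(hit))
  })
}

#' Ungapped percent-identity scan of a probe against transcripts
#'
#' For each transcript, slides the 50-mer probe over every ungapped
#' offset on both strands (the reverse complement of the transcript is
#' scanned too) and reports the best percent identity,
#' `100 * matches / 50`; `N` never matches. This is a local stand-in for
#' a BLAST search of the probe against a transcript database: at 50-mer
#' scale and >= 90% identity, cross-hybridizing targets are near-exact
#' ungapped matches, so gapped alignment adds nothing. A probe hitting
#' more than one distinct gene at `min_identity` or better is flagged
#' `multi_target` — its signal may sum over a paralog family rather than
#' measure one gene.
#'
#' Transcripts shorter than the probe are scored over their best partial
#' overlap when that overlap is at least 25 bases, and skipped otherwise
#' (the denominator stays 50).
#'
#' @param probe_seq 50-character string over ACGTN.
#' @param transcripts tibble with `transcript_id`, `sequence` and
#'   optionally `gene` (defaults to the transcript id), e.g. from
#'   [read_transcripts()].
#' @param min_identity percent identity at or above which a transcript
#'   counts as a cross-hybridization hit (default 90).
#' @return tibble, one row per scored transcript: `transcript_id`,
#'   `gene`, `percent_identity`, `hit`; attribute `"multi_target"`.
#' @examples
#' tx <- tibble::tibble(transcript_id = "t1",
#'                      sequence = strrep("ACGTACGTAC", 10))
#' probe <- substr(tx$sequence, 11, 60)
#' probe_identity_scan(probe, tx)  # 100% hit
#' @export
probe_identity_scan <- function(probe_seq, transcripts, min_identity = 90.0) {
  if (nchar(probe_seq) != 50)
    stop("probe sequence must be exactly 50 bases", call. = FALSE)
  if (!grepl("^[ACGTN]+$", probe_seq))
    abort_param("probe sequence must be over ACGTN")
  if (!"gene" %in% names(transcripts)) transcripts$gene <- transcripts$transcript_id
  probe <- strsplit(probe_seq, "")[[1]]

  rows <- purrr::map(seq_len(nrow(transcripts)), function(i) {
    tx <- transcripts$sequence[[i]]
    best <- max(best_ungapped_matches(probe, tx),
                best_ungapped_matches(probe, revcomp(tx)))
    if (is.na(best)) return(NULL)
    tibble::tibble(transcript_id = transcripts$transcript_id[i],
                   gene = transcripts$gene[i],
                   percent_identity = 100 * best / 50)
  })
  out <- dplyr::bind_rows(Filter(Negate(is.null), rows))
  if (nrow(out)) {
    out$hit <- out$percent_identity >= min_identity
    attr(out, "multi_target") <- length(unique(out$gene[out$hit])) > 1
  } else {
    out <- tibble::tibble(transcript_id = character(), gene = character(),
                          percent_identity = numeric(), hit = logical())
    attr(out, "multi_target") <- FALSE
  }
  out
}

# best number of matching positions of probe (char vector) against any
# ungapped placement on transcript string; NA if no placement with >= 25
# overlapping bases exists
best_ungapped_matches <- function(probe, transcript) {
  tchars <- strsplit(transcript, "")[[1]]
  L <- length(tchars); P <- length(probe)
  valid <- probe != "N"
  if (L >= P) {
    best <- 0L
    for (off in 0:(L - P)) {
      m <- sum(probe == tchars[(off + 1):(off + P)] & valid)
      if (m > best) best <- m
    }
    return(best)
  }
  if (L < 25) return(NA_integer_)
  best <- 0L
  # slide the short transcript along the probe (full containment)
  for (off in 0:(P - L)) {
    m <- sum(probe[(off + 1):(off + L)] == tchars & valid[(off + 1):(off + L)])
    if (m > best) best <- m
  }
  best
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

#' Combined probe artifact report
#'
#' Runs [snps_in_probe()] and, for probes with sequences,
#' [probe_identity_scan()] against the supplied transcript set; one row
#' per probe with both flags.
#'
#' @param probes probe tibble or [expression_table] (needs `sequence`
#'   for the cross-hybridization scan).
#' @param snp_meta SNP metadata tibble, see [snps_in_probe()].
#' @param transcripts transcript tibble, see [probe_identity_scan()];
#'   `NULL` skips the scan.
#' @param maf_min,min_identity thresholds for the two checks.
#' @return tibble: `probe_id`, `n_snps_in_probe`, `snp_confounded`,
#'   `n_cross_hyb`, `multi_target`, list-columns `snps` and `cross_hyb`.
#' @export
probe_qc_report <- function(probes, snp_meta, transcripts = NULL,
                            maf_min = 0.01, min_identity = 90.0) {
  if (inherits(probes, "expression_table")) probes <- probes$probe_meta
  rep1 <- snps_in_probe(probes, snp_meta, maf_min = maf_min)
  if (is.null(transcripts) || !"sequence" %in% names(probes)) {
    rep1$n_cross_hyb <- NA_integer_
    rep1$multi_target <- NA
    rep1$cross_hyb <- list(NULL)
    return(rep1)
  }
  xh <- purrr::map(seq_len(nrow(probes)), function(i) {
    s <- probes$sequence[i]
    if (is.na(s)) return(NULL)
    probe_identity_scan(s, transcripts, min_identity = min_identity)
  })
  rep1$n_cross_hyb <- vapply(xh, function(h) if (is.null(h)) NA_integer_
                             else sum(h$hit), integer(1))
  rep1$multi_target <- vapply(xh, function(h) if (is.null(h)) NA
                              else attr(h, "multi_target"), logical(1))
  rep1$cross_hyb <- xh
  rep1
}
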