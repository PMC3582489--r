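#' Genomic intervals (1-based, inclusive)
#'
#' All user-facing coordinates in this package are 1-based and inclusive at
#' both ends, the convention of UCSC browser text positions. BED intervals
#' (0-based half-open) are converted on read by [read_probes_bed()].
#'
#' @param chrom chromosome name, e.g. `"chr17"`.
#' @param start,end 1-based inclusive bounds, `1 <= start <= end`.
#' @return a `genomic_interval` object (named list).
#' @examples
#' genomic_interval("chr17", 40850001, 41850000)
#' parse_region("chr17:39,899,921-42,989,253")
#' @export
genomic_interval <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(chrom) != 1L || length(start) != 1L || length(end) != 1L)
    abort_param("genomic_interval expects scalar chrom/start/end")
  if (is.na(start) || is.na(end) || start < 1 || start > end)
    abort_param("invalid interval: need 1 <= start <= end")
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "genomic_interval")
}

#' @rdname genomic_interval
#' @param x a region string `"chrom:start-end"`; commas in numbers allowed.
#' @export
parse_region <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))[[1]]
  if (length(m) != 4L) abort_param(sprintf("cannot parse region '%s'", x))
  genomic_interval(m[2],
                   as.numeric(gsub(",", "", m[3])),
                   as.numeric(gsub(",", "", m[4])))
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s:%s-%s\n", x$chrom,
              format(x$start, big.mark = ",", scientific = FALSE),
              format(x$end, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' @export
format.genomic_interval <- function(x, ...) {
  sprintf("%s:%.0f-%.0f", x$chrom, x$start, x$end)
}

interval_contains <- function(outer, inner) {
  outer$chrom == inner$chrom && outer$start <= inner$start && inner$end <= outer$end
}

in_interval <- function(chrom, pos, interval) {
  chrom == interval$chrom & pos >= interval$start & pos <= interval$end
}

#' Subset a table to a genomic interval
#'
#' Keeps records whose position (SNPs) or whose annotated interval start
#' (probes) falls inside `interval`, 1-based inclusive at both bounds.
#' Input order is preserved; an empty result is an empty table, not an
#' error. Idempotent: applying the same interval twice equals once.
#'
#' @param x a [genotype_table], [expression_table], or a data frame with
#'   `chrom` and `pos` (or `start`) columns.
#' @param interval a [genomic_interval] or region string.
#' @param ... unused.
#' @return object of the same class, subset to the interval.
#' @export
select_region <- function(x, interval, ...) UseMethod("select_region")

as_interval <- function(interval) {
  if (is.character(interval)) parse_region(interval) else interval
}

#' @export
select_region.genotype_table <- function(x, interval, ...) {
  interval <- as_interval(interval)
  keep <- in_interval(x$snp_meta$chrom, x$snp_meta$pos, interval)
  subset_genotypes(x, snps = which(keep))
}

#' @export
select_region.expression_table <- function(x, interval, ...) {
  interval <- as_interval(interval)
  keep <- in_interval(x$probe_meta$chrom, x$probe_meta$start, interval)
  subset_expression(x, probes = which(keep))
}

#' @export
select_region.data.frame <- function(x, interval, ...) {
  interval <- as_interval(interval)
  pos <- if ("pos" %in% names(x)) x$pos else x$start
  x[in_interval(x$chrom, pos, interval), , drop = FALSE]
}
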