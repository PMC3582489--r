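#' Expression table
#'
#' Probes-by-individuals expression matrix with per-probe metadata:
#' gene symbol, genomic interval, optional 50-mer probe sequence, and a
#' per-probe detection statistic (mean detection value for blood-style
#' arrays, detection p-value for brain-style arrays).
#'
#' @param values numeric matrix, rows = probes, columns = individuals.
#' @param probe_meta tibble with columns `probe_id`, `gene`, `chrom`,
#'   `start`, `end`, optionally `sequence` (50-mer over ACGTN) and
#'   `detection`.
#' @param individual_ids character, one per column.
#' @return an `expression_table`.
#' @export
expression_table <- function(values, probe_meta, individual_ids = colnames(values)) {
  values <- as.matrix(values)
  probe_meta <- tibble::as_tibble(probe_meta)
  if (is.null(individual_ids))
    individual_ids <- sprintf("ind%04d", seq_len(ncol(values)))
  stopifnot(nrow(probe_meta) == nrow(values),
            length(individual_ids) == ncol(values))
  if (!"detection" %in% names(probe_meta)) probe_meta$detection <- 1
  if ("sequence" %in% names(probe_meta)) {
    seqs <- probe_meta$sequence[!is.na(probe_meta$sequence)]
    if (length(seqs) && any(!grepl("^[ACGTN]{50}$", seqs)))
      abort_param("probe sequences must match [ACGTN]{50}")
  }
  rownames(values) <- probe_meta$probe_id
  colnames(values) <- individual_ids
  structure(list(values = values, probe_meta = probe_meta,
                 individual_ids = as.character(individual_ids)),
            class = "expression_table")
}

subset_expression <- function(x, probes = NULL, individuals = NULL) {
  v <- x$values; meta <- x$probe_meta; ids <- x$individual_ids
  if (!is.null(probes)) {
    v <- v[probes, , drop = FALSE]
    meta <- meta[probes, , drop = FALSE]
  }
  if (!is.null(individuals)) {
    v <- v[, individuals, drop = FALSE]
    ids <- ids[individuals]
  }
  expression_table(v, meta, ids)
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %d probes x %d individuals\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Tidy an expression table into long form
#'
#' @param x an [expression_table].
#' @param ... unused.
#' @return tibble with one row per (probe, individual).
#' @exportS3Method generics::tidy
#' @export
tidy.expression_table <- function(x, ...) {
  tibble::tibble(
    probe_id = rep(x$probe_meta$probe_id, times = ncol(x$values)),
    gene = rep(x$probe_meta$gene, times = ncol(x$values)),
    individual_id = rep(x$individual_ids, each = nrow(x$values)),
    expression = as.numeric(x$values)
  )
}
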