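#' Preprocess an expression table
#'
#' Log2 transform followed by quantile normalization across individuals
#' (tied ranks receive the mean of the quantiles they span), then the
#' mode's detection filter: blood-style arrays keep probes with mean
#' detection value above 0.90; brain-style arrays keep probes detected at
#' p below 0.01. With a single individual, quantile normalization is the
#' identity.
#'
#' @param raw an [expression_table] with positive intensities.
#' @param mode `"blood"` or `"brain"`; decides the detection-filter
#'   semantics (the `detection` probe column is a mean detection value
#'   for blood, a detection p-value for brain).
#' @param log2_transform set `FALSE` when intensities are already on the
#'   log2 scale.
#' @param detection_filter set `FALSE` to skip the detection filter.
#' @return preprocessed [expression_table].
#' @export
preprocess_expression <- function(raw, mode = c("blood", "brain"),
                                  log2_transform = TRUE,
                                  detection_filter = TRUE) {
  mode <- match.arg(mode)
  v <- raw$values
  if (log2_transform) {
    if (any(v <= 0, na.rm = TRUE))
      stop("non-positive intensity: cannot log2 transform", call. = FALSE)
    v <- log2(v)
  }
  if (ncol(v) > 1) v <- limma::normalizeQuantiles(v, ties = TRUE)
  out <- expression_table(v, raw$probe_meta, raw$individual_ids)
  if (detection_filter) {
    keep <- if (mode == "blood") out$probe_meta$detection > 0.90
            else out$probe_meta$detection < 0.01
    out <- subset_expression(out, probes = which(keep))
  }
  out
}

#' Fit the allele-dosage linear model for one probe
#'
#' Ordinary least squares of expression on an intercept, H1-allele
#' dosage (H1/H1 = 2, H1/H2 = 1, H2/H2 = 0) and covariates. `B` is the
#' dosage coefficient: the change in (log2) expression per H1 copy. The
#' two-sided p-value comes from the t distribution with `n - k - 1`
#' degrees of freedom and the 95% CI is `B +/- t_{0.975, df} * SE`.
#' Collinear covariate columns are dropped with a warning and the model
#' refit. A perfect fit (zero residual variance) is reported as SE = 0,
#' p = 0 with a warning rather than failing.
#'
#' @param y numeric expression vector.
#' @param dosage vector in `{0, 1, 2}`, non-constant.
#' @param covariates optional numeric matrix / data frame of covariates
#'   (already encoded; see [encode_covariates()]).
#' @return a `dosage_fit` object; [tidy()] returns the association row.
#' @export
fit_dosage_model <- function(y, dosage, covariates = NULL) {
  if (length(unique(dosage)) < 2)
    stop("no genotype variance: dosage is constant", call. = FALSE)
  X <- cbind(dosage = as.numeric(dosage))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == length(y))
    X <- cbind(X, covariates)
  }
  n <- length(y)
  if (n <= ncol(X) + 1)
    abort_param("need n > number of predictors + 1")

  if (is.null(colnames(X))) colnames(X) <- paste0("c", seq_len(ncol(X)))
  colnames(X)[colnames(X) == ""] <-
    paste0("c", seq_len(ncol(X)))[colnames(X) == ""]
  dat <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    warning(sprintf("dropping collinear covariate(s): %s",
                    paste(dropped, collapse = ", ")))
    keep <- !is.na(stats::coef(fit))[-1]
    X <- X[, keep, drop = FALSE]
    dat <- data.frame(y = y, X, check.names = FALSE)
    fit <- stats::lm(y ~ ., data = dat)
  }
  k <- ncol(X)
  df <- n - k - 1
  co <- stats::coef(fit)[["dosage"]]
  # summary.lm warns about "essentially perfect fit"; handled explicitly below
  sm <- suppressWarnings(summary(fit))
  se <- sm$coefficients["dosage", "Std. Error"]
  if (sm$sigma^2 < .Machine$double.eps * max(1, mean(y^2))) {
    warning("zero residual variance: perfect fit, reporting SE = 0, p = 0")
    se <- 0
  }
  if (se > 0) {
    tval <- co / se
    p <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
    tcrit <- stats::qt(0.975, df = df)
    ci <- c(co - tcrit * se, co + tcrit * se)
  } else {
    tval <- sign(co) * Inf
    p <- 0
    ci <- c(co, co)
  }
  structure(list(B = co, SE = se, t = tval, p = p,
                 ci95 = ci, n = n, df = df, k = k, lm_fit = fit),
            class = "dosage_fit")
}

#' @export
print.dosage_fit <- function(x, ...) {
  cat(sprintf("<dosage_fit> n = %d, B = %.4g (95%% CI %.4g, %.4g), t = %.3g, p = %s\n",
              x$n, x$B, x$ci95[1], x$ci95[2], x$t, format_pval(x$p)))
  invisible(x)
}

#' @rdname fit_dosage_model
#' @param x a `dosage_fit`.
#' @param ... unused.
#' @exportS3Method generics::tidy
#' @export
tidy.dosage_fit <- function(x, ...) {
  tibble::tibble(term = "dosage", B = x$B, SE = x$SE, t = x$t,
                 CI_low = x$ci95[1], CI_high = x$ci95[2], p = x$p)
}

#' @rdname fit_dosage_model
#' @exportS3Method generics::glance
#' @export
glance.dosage_fit <- function(x, ...) {
  tibble::tibble(n = x$n, df = x$df, n_predictors = x$k)
}

#' Encode a covariate table as a numeric design block
#'
#' Numeric columns pass through; character/factor columns are one-hot
#' encoded with the first level dropped (treatment coding). The
#' `individual_id` column is used for alignment, never as a covariate.
#'
#' @param covariates tibble with an `individual_id` column.
#' @param ids individual IDs in the required row order.
#' @return numeric matrix with one row per id; attribute `"complete"`
#'   flags rows without missing values.
#' @export
encode_covariates <- function(covariates, ids) {
  df <- covariates[match(ids, covariates$individual_id), , drop = FALSE]
  df$individual_id <- NULL
  if (ncol(df) == 0) {
    m <- matrix(numeric(0), nrow = length(ids), ncol = 0)
    attr(m, "complete") <- rep(TRUE, length(ids))
    return(m)
  }
  blocks <- lapply(names(df), function(nm) {
    col <- df[[nm]]
    if (is.numeric(col)) {
      m <- matrix(col, ncol = 1, dimnames = list(NULL, nm))
    } else {
      f <- factor(col)
      if (nlevels(f) < 2) return(NULL)
      m <- stats::model.matrix(~f)[, -1, drop = FALSE]
      # model.matrix drops NA rows; rebuild at full length
      full <- matrix(NA_real_, length(col), ncol(m),
                     dimnames = list(NULL, paste0(nm, levels(f)[-1])))
      full[!is.na(col), ] <- m
      m <- full
    }
    m
  })
  m <- do.call(cbind, Filter(Negate(is.null), blocks))
  if (is.null(m)) m <- matrix(numeric(0), nrow = length(ids), ncol = 0)
  attr(m, "complete") <- if (ncol(m)) stats::complete.cases(m) else rep(TRUE, length(ids))
  m
}

#' Bonferroni significance threshold
#'
#' `alpha / m` at full precision; the reporting layer displays it at two
#' significant figures (0.05 / 28 displays as 0.0018) but comparisons
#' always use the exact value.
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of tests, >= 1.
#' @return numeric threshold.
#' @examples
#' bonferroni_threshold(0.05, 28)          # 0.001785714...
#' format_threshold(bonferroni_threshold(0.05, 28))  # "0.0018"
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!(alpha > 0 && alpha < 1)) abort_param("alpha must lie in (0, 1)")
  if (m < 1) abort_param("m must be >= 1")
  alpha / m
}

#' Cis-eQTL scan over an expression table
#'
#' Tests every probe inside the cis interval for a linear allele-dosage
#' effect, one tissue at a time. Individuals are joined across the
#' expression, calls and covariate tables by ID, never by column order;
#' `EXCLUDED` individuals and individuals with missing covariates are
#' dropped. Significance is flagged at the Bonferroni threshold
#' `alpha / m` with `m` = the number of probes tested in this dataset.
#'
#' @param expr a preprocessed [expression_table].
#' @param calls an `inversion_calls` tibble.
#' @param covariates covariate tibble with `individual_id` (or `NULL`).
#' @param cis cis interval (default 1 Mb each side of the inversion).
#' @param tissue tissue label for the output.
#' @param alpha family-wise error rate (default 0.05).
#' @return an `eqtl_table` tibble: `probe_id`, `gene`, `tissue`, `n`,
#'   `B`, `SE`, `t`, `CI_low`, `CI_high`, `p`, `significant`; the
#'   threshold and `m` are attached as attributes.
#' @export
run_cis_eqtl <- function(expr, calls, covariates = NULL,
                         cis = cis_interval_default(), tissue = "tissue",
                         alpha = 0.05) {
  expr_cis <- select_region(expr, cis)
  if (nrow(expr_cis$values) == 0) {
    warning("no probes overlap the cis interval")
    return(empty_eqtl_table(alpha))
  }
  called <- dplyr::filter(tidy.inversion_calls(calls), .data$label != "EXCLUDED")
  if (length(unique(called$dosage)) < 2)
    stop("calls contain fewer than 2 genotype classes", call. = FALSE)

  ids <- intersect(expr_cis$individual_ids, called$individual_id)
  cov_m <- if (!is.null(covariates)) {
    ids <- intersect(ids, covariates$individual_id)
    encode_covariates(covariates, ids)
  } else NULL
  if (!is.null(cov_m)) {
    ok <- attr(cov_m, "complete")
    ids <- ids[ok]
    cov_m <- cov_m[ok, , drop = FALSE]
  }
  dosage <- called$dosage[match(ids, called$individual_id)]
  vmat <- expr_cis$values[, match(ids, expr_cis$individual_ids), drop = FALSE]

  m <- nrow(vmat)
  thr <- bonferroni_threshold(alpha, m)
  rows <- purrr::map(seq_len(m), function(i) {
    f <- fit_dosage_model(vmat[i, ], dosage, cov_m)
    tibble::tibble(
      probe_id = expr_cis$probe_meta$probe_id[i],
      gene = expr_cis$probe_meta$gene[i],
      tissue = tissue, n = f$n, B = f$B, SE = f$SE, t = f$t,
      CI_low = f$ci95[1], CI_high = f$ci95[2], p = f$p,
      significant = f$p < thr
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("eqtl_table", class(out)),
            m = m, alpha = alpha, threshold = thr)
}

empty_eqtl_table <- function(alpha) {
  structure(
    tibble::tibble(probe_id = character(), gene = character(),
                   tissue = character(), n = integer(), B = numeric(),
                   SE = numeric(), t = numeric(), CI_low = numeric(),
                   CI_high = numeric(), p = numeric(), significant = logical()),
    class = c("eqtl_table", "tbl_df", "tbl", "data.frame"),
    m = 0L, alpha = alpha, threshold = NA_real_)
}

#' @exportS3Method generics::glance
#' @export
glance.eqtl_table <- function(x, ...) {
  tibble::tibble(m = attr(x, "m"), alpha = attr(x, "alpha"),
                 threshold = attr(x, "threshold"),
                 n_significant = sum(x$significant))
}
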