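#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()].
#' Defaults reproduce the study settings: inversion interval
#' chr17:40,850,001-41,850,000, cis window chr17:39,899,921-42,989,253
#' (1 Mb each side), 3 SD exclusion, alpha 0.05, probe-QC MAF cutoff
#' 0.01. The inversion interval must be contained in the cis interval.
#'
#' A simulation block (used when no input paths are given) carries the
#' generator settings: cohort size, H2 frequency, clade divergence,
#' within-clade flip rate, per-probe effects, noise SD and seed.
#'
#' @param inversion_interval,cis_interval [genomic_interval]s or region
#'   strings.
#' @param sd_limit,alpha,maf_min analysis thresholds.
#' @param qc named list overriding [qc_filter()] thresholds.
#' @param detection_mode `"blood"` or `"brain"`.
#' @param simulation named list of generator settings (see Details).
#' @param paths named list of input files (`genotypes`, `expression`,
#'   `covariates`, `transcripts`), each optional.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(inversion_interval = inversion_interval_default(),
                            cis_interval = cis_interval_default(),
                            sd_limit = 3.0, alpha = 0.05, maf_min = 0.01,
                            qc = list(), detection_mode = "blood",
                            simulation = NULL, paths = list()) {
  inversion_interval <- as_interval(inversion_interval)
  cis_interval <- as_interval(cis_interval)
  if (!interval_contains(cis_interval, inversion_interval))
    abort_param("inversion_interval must be contained in cis_interval")
  if (!(sd_limit > 0)) abort_param("sd_limit must be positive")
  if (!(alpha > 0 && alpha < 1)) abort_param("alpha must lie in (0, 1)")
  structure(list(inversion_interval = inversion_interval,
                 cis_interval = cis_interval, sd_limit = sd_limit,
                 alpha = alpha, maf_min = maf_min, qc = qc,
                 detection_mode = detection_mode,
                 simulation = simulation, paths = paths),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Sections mirror the [pipeline_config()] arguments; intervals are
#' given as `"chrom:start-end"` strings.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, c(
    if (!is.null(y$inversion_interval)) list(inversion_interval = y$inversion_interval),
    if (!is.null(y$cis_interval)) list(cis_interval = y$cis_interval),
    y[intersect(names(y), c("sd_limit", "alpha", "maf_min", "qc",
                            "detection_mode", "simulation", "paths"))]
  ))
}

#' Default demonstration simulation settings
#'
#' A blood-style cohort: 431 individuals (437 simulated, matching the
#' study's pre-exclusion size, would differ only by the recombinant
#' fraction), H2 frequency 0.21, 60 inside-inversion SNPs at divergence
#' 0.8 with flip rate 0.05, 20 flanking SNPs, one causal probe with
#' B = 0.37 per H1 copy among 28 probes, residual SD 0.3, age and
#' gender covariates.
#'
#' @param seed integer seed.
#' @return named list for the `simulation` block of [pipeline_config()].
#' @export
demo_simulation <- function(seed = 1) {
  list(n_individuals = 437, h2_freq = 0.21, n_inside = 60, n_outside = 20,
       divergence = 0.8, flip_rate = 0.05, missing_rate = 0.01,
       recombinant_fraction = 0.014,
       probe_effects = c(0.37, rep(0, 27)), noise_sd = 0.3, seed = seed)
}

simulate_inputs <- function(sim) {
  pools <- simulate_haplotype_pools(sim$n_inside, sim$n_outside,
                                    divergence = sim$divergence,
                                    flip_rate = sim$flip_rate,
                                    seed = sim$seed)
  cohort <- simulate_cohort(pools, sim$n_individuals, h2_freq = sim$h2_freq,
                            missing_rate = sim$missing_rate %||% 0,
                            seed = sim$seed + 1)
  if (!is.null(sim$recombinant_fraction) && sim$recombinant_fraction > 0)
    cohort <- inject_recombinants(cohort$genotypes, cohort$truth,
                                  sim$recombinant_fraction,
                                  seed = sim$seed + 2)
  covars <- simulate_covariates(sim$n_individuals, seed = sim$seed + 3,
                                individual_ids = cohort$truth$individual_id)
  expr <- simulate_expression(cohort$truth, sim$probe_effects,
                              covariates = covars,
                              noise_sd = sim$noise_sd, seed = sim$seed + 4)
  list(genotypes = cohort$genotypes, truth = cohort$truth,
       covariates = covars, expression = expr)
}

#' Run the full inversion-eQTL pipeline
#'
#' Stages, in order: simulate or ingest inputs; genotype QC; PCA
#' inversion call (with HWE validation); expression preprocessing;
#' cis-eQTL scan with Bonferroni flagging; probe QC. Writes `calls.tsv`,
#' `eqtl.tsv`, `probe_flags.tsv`, `pc_scatter.tsv`, `report.txt` and
#' `log.txt` into `out_dir`. Deterministic for a fixed config: running
#' twice yields byte-identical outputs.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if needed).
#' @param tissue tissue label for the association table.
#' @return invisibly, a list with `calls`, `eqtl`, `probe_flags`, and
#'   (for simulated runs) `truth`.
#' @export
run_pipeline <- function(config, out_dir = "invexpr_run", tissue = "whole_blood") {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "log.txt")
  cat(sprintf("invexpr pipeline\nconfig: sd_limit=%g alpha=%g maf_min=%g mode=%s\n",
              config$sd_limit, config$alpha, config$maf_min,
              config$detection_mode), file = logf)
  stage <- function(name, code) {
    cat(sprintf("stage %s\n", name), file = logf, append = TRUE)
    tryCatch(code, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  inputs <- stage("simulate/ingest", {
    if (!is.null(config$paths$genotypes)) {
      fmt <- if (grepl("\\.vcf$", config$paths$genotypes)) "vcf" else "dosage_tsv"
      list(genotypes = read_genotypes(config$paths$genotypes, fmt),
           expression = if (!is.null(config$paths$expression))
             read_expression(config$paths$expression),
           covariates = if (!is.null(config$paths$covariates))
             readr::read_tsv(config$paths$covariates,
                             col_types = readr::cols(), progress = FALSE),
           truth = NULL)
    } else if (!is.null(config$simulation)) {
      simulate_inputs(config$simulation)
    } else abort_param("config needs either input paths or a simulation block")
  })

  gt_qc <- stage("qc", do.call(qc_filter, c(list(inputs$genotypes), config$qc)))
  calls <- stage("pca-call", {
    local <- select_region(gt_qc, config$inversion_interval)
    scores <- pca_genotypes(local, k = 2)
    call_inversion_genotypes(scores, sd_limit = config$sd_limit)
  })
  write_table_tsv(tidy.inversion_calls(calls), file.path(out_dir, "calls.tsv"))
  write_table_tsv(tidy.inversion_calls(calls)[, c("pc1", "pc2", "label")],
                  file.path(out_dir, "pc_scatter.tsv"))

  eqtl <- stage("eqtl", {
    if (is.null(inputs$expression)) return(empty_eqtl_table(config$alpha))
    expr <- preprocess_expression(inputs$expression,
                                  mode = config$detection_mode,
                                  log2_transform = FALSE)
    run_cis_eqtl(expr, calls, covariates = inputs$covariates,
                 cis = config$cis_interval, tissue = tissue,
                 alpha = config$alpha)
  })
  write_results(eqtl, file.path(out_dir, "eqtl.tsv"))

  flags <- stage("probe-qc", {
    if (is.null(inputs$expression)) return(NULL)
    tx <- if (!is.null(config$paths$transcripts))
      read_transcripts(config$paths$transcripts) else NULL
    probe_qc_report(inputs$expression, gt_qc$snp_meta, transcripts = tx,
                    maf_min = config$maf_min)
  })
  if (!is.null(flags))
    write_table_tsv(dplyr::select(flags, -dplyr::any_of(c("snps", "cross_hyb"))),
                    file.path(out_dir, "probe_flags.tsv"))

  writeLines(pipeline_report(calls, eqtl, config, tissue),
             file.path(out_dir, "report.txt"))
  invisible(list(calls = calls, eqtl = eqtl, probe_flags = flags,
                 truth = inputs$truth))
}

# report in the study's display style: counts with half-up integer
# percentages, HWE p to 2 decimals, B/CI to 2 decimals, p-values in
# scientific notation with 2 significant digits
pipeline_report <- function(calls, eqtl, config, tissue) {
  g <- glance.inversion_calls(calls)
  n_called <- g$n_H1H1 + g$n_H1H2 + g$n_H2H2
  pct <- round_half_up(100 * c(g$n_H1H1, g$n_H1H2, g$n_H2H2) / n_called)
  lines <- c(
    "Inversion genotype calls",
    sprintf("  interval: %s; exclusion: >%g SD from cluster mean",
            format(config$inversion_interval), config$sd_limit),
    sprintf("  H1/H1 %d (%d%%), H1/H2 %d (%d%%), H2/H2 %d (%d%%); %d excluded",
            g$n_H1H1, pct[1], g$n_H1H2, pct[2], g$n_H2H2, pct[3],
            g$n_excluded),
    sprintf("  Hardy-Weinberg p = %.2f", g$hwe_p),
    ""
  )
  if (nrow(eqtl)) {
    ge <- glance.eqtl_table(eqtl)
    lines <- c(lines,
      sprintf("Cis-eQTL scan (%s): %d probes tested, threshold %s (alpha %g)",
              tissue, ge$m, format_threshold(ge$threshold), ge$alpha),
      sprintf("  %-10s %-10s B = %6.2f (%.2f, %.2f)  p = %s%s",
              eqtl$probe_id, eqtl$gene, eqtl$B, eqtl$CI_low, eqtl$CI_high,
              format_pval(eqtl$p),
              ifelse(eqtl$significant, "  *", "")))
  }
  lines
}

#' One-command synthetic demonstration
#'
#' Simulates the demonstration cohort ([demo_simulation()]) and runs the
#' full pipeline on it.
#'
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return the [run_pipeline()] result, invisibly.
#' @export
run_demo <- function(seed = 1, out_dir = "invexpr_demo") {
  cfg <- pipeline_config(simulation = demo_simulation(seed))
  run_pipeline(cfg, out_dir = out_dir)
}
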