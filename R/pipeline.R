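# Pipeline orchestration: one configuration object governs every
# threshold; each stage is a function over files so the whole workflow is
# scriptable (inst/cli/tmbflow.R wraps these in a command-line tool).
# Every output table names the config hash and seed in a header comment.

config_defaults <- function() {
  list(
    seed = 1L,
    target_size_mb = 30,
    filter = list(
      min_qual = 10, min_depth = 30, max_pop_af = 0.01, low_vaf_cut = 0.05,
      germ_het_band = c(0.45, 0.55), hom_vaf_cut = NULL,
      drop_synonymous = TRUE, drop_noncoding = TRUE
    ),
    qc = list(
      mean_target_coverage = c(100, 150), uniformity = c(80, 90),
      pct_duplicates = c(40, 20), base_enrichment = c(60, 80)
    ),
    bootstrap = list(n_iterations = 1000, level = 90),
    simulation = list(
      n_samples = 20,
      cancer_labels = c("brain", "colorectal", "lung", "breast", "ovary",
                        "head_and_neck"),
      true_tmb_range = c(1, 40), purity_range = c(0.3, 0.7),
      n_germline_het = 3000, n_germline_hom = 1500, n_other = 300,
      n_noise = 200,
      pool_size = 20000, frac_common = 0.7, n_donors = 30,
      complete_panel = FALSE,
      qc_tier_weights = c(good = 0.7, intermediate = 0.2, poor = 0.1)
    )
  )
}

#' Pipeline configuration
#'
#' Builds the configuration governing every pipeline threshold, starting
#' from package defaults, optionally overridden by a YAML file and then by
#' named arguments. Unknown keys are rejected at every level.
#'
#' @param path optional YAML file with (partial) configuration.
#' @param ... named overrides of top-level keys (e.g. `seed = 42`, or
#'   `filter = list(min_depth = 50)` to override one nested value).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- config_defaults()
  merge_over <- function(base, over, where) {
    unknown <- setdiff(names(over), names(base))
    if (length(unknown) > 0) {
      stopf("unknown configuration key(s) %s %s",
            paste(unknown, collapse = ", "), where)
    }
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]])) {
        merge_over(base[[k]], over[[k]], sprintf("in '%s'", k))
      } else {
        over[[k]]
      }
    }
    base
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    cfg <- merge_over(cfg, yaml::read_yaml(path), "at top level")
  }
  over <- list(...)
  if (length(over) > 0) cfg <- merge_over(cfg, over, "at top level")
  # validate by constructing the component objects
  as_filter_config(cfg)
  as_qc_thresholds(cfg)
  if (!is_scalar_num(cfg$target_size_mb) || cfg$target_size_mb <= 0) {
    stopf("target_size_mb must be > 0")
  }
  structure(cfg, class = "pipeline_config")
}

as_filter_config <- function(config) do.call(filter_config, config$filter)

as_qc_thresholds <- function(config) do.call(qc_thresholds, config$qc)

config_hash <- function(config) {
  stamp_hash(deparse(unclass(config), control = "all"))
}

provenance <- function(config) {
  sprintf("tmbflow config_hash=%s seed=%d", config_hash(config),
          as.integer(config$seed))
}

prepare_output_dir <- function(output_dir, overwrite) {
  if (dir.exists(output_dir) && length(dir(output_dir)) > 0 && !overwrite) {
    stopf("output directory %s is not empty (use overwrite = TRUE)", output_dir)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  invisible(output_dir)
}

#' Simulate a cohort to disk
#'
#' Generates a synthetic matched cohort and writes per-sample tumor and
#' normal VCFs, a ground-truth TSV, a QC metrics TSV, and the baseline
#' panel TSV into `output_dir`. Byte-identical across reruns for a fixed
#' configuration.
#'
#' @param config a [pipeline_config()].
#' @param output_dir output directory.
#' @param overwrite allow writing into a non-empty directory.
#' @return character vector of files written, invisibly.
#' @export
run_simulate <- function(config, output_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$simulation
  prepare_output_dir(output_dir, overwrite)
  pool <- make_germline_pool(
    size = sim$pool_size, frac_common = sim$frac_common,
    seed = derive_seed(config$seed, 7)
  )
  sampler <- function(i, seed) {
    sim_params(
      true_tmb = stats::runif(1, sim$true_tmb_range[1], sim$true_tmb_range[2]),
      purity = stats::runif(1, sim$purity_range[1], sim$purity_range[2]),
      n_germline_het = sim$n_germline_het,
      n_germline_hom = sim$n_germline_hom,
      n_other = sim$n_other, n_noise = sim$n_noise,
      seed = derive_seed(seed, i)
    )
  }
  cohort <- generate_cohort(
    n_samples = sim$n_samples, cancer_labels = sim$cancer_labels,
    params_sampler = sampler, seed = config$seed, pool = pool
  )
  panel <- generate_baseline_panel(
    pool, n_donors = sim$n_donors, seed = derive_seed(config$seed, 11),
    complete = isTRUE(sim$complete_panel)
  )
  meta <- provenance(config)
  files <- character()
  for (pair in cohort$pairs) {
    tf <- file.path(output_dir, paste0(pair$truth$sample_id, ".tumor.vcf"))
    nf <- file.path(output_dir, paste0(pair$truth$sample_id, ".normal.vcf"))
    write_vcf(pair$tumor, tf, meta = meta)
    write_vcf(pair$normal, nf, meta = meta)
    files <- c(files, tf, nf)
  }
  truth_path <- file.path(output_dir, "truth.tsv")
  write_tsv(cohort$truth, truth_path, comment = meta)

  tiers <- with_seed(derive_seed(config$seed, 13), {
    sample(names(sim$qc_tier_weights), sim$n_samples, replace = TRUE,
           prob = sim$qc_tier_weights)
  })
  qc_rows <- lapply(seq_len(sim$n_samples), function(i) {
    m <- generate_qc_metrics(tiers[i], seed = derive_seed(config$seed, 1000 + i),
                             thresholds = as_qc_thresholds(config))
    cbind(data.frame(sample_id = cohort$truth$sample_id[i]),
          as.data.frame(m))
  })
  qc_path <- file.path(output_dir, "qc_metrics.tsv")
  write_tsv(do.call(rbind, qc_rows), qc_path, comment = meta)

  panel_path <- file.path(output_dir, "baseline_panel.tsv")
  write_tsv(panel_keys_table(panel), panel_path, comment = meta)
  invisible(c(files, truth_path, qc_path, panel_path))
}

panel_keys_table <- function(panel) {
  parts <- strsplit(sort(panel$keys), ":", fixed = TRUE)
  data.frame(
    chrom = vapply(parts, `[`, character(1), 1),
    pos = as.integer(vapply(parts, `[`, character(1), 2)),
    ref = vapply(parts, `[`, character(1), 3),
    alt = vapply(parts, `[`, character(1), 4),
    stringsAsFactors = FALSE
  )
}

read_panel_tsv <- function(path, n_donors = 1) {
  t <- read_tsv(path)
  baseline_panel(paste(t$chrom, t$pos, t$ref, t$alt, sep = ":"), n_donors)
}

discover_pairs <- function(input_dir, mode) {
  tumors <- sort(list.files(input_dir, pattern = "\\.tumor\\.vcf$",
                            full.names = TRUE))
  if (length(tumors) == 0) stopf("no *.tumor.vcf files in %s", input_dir)
  ids <- sub("\\.tumor\\.vcf$", "", basename(tumors))
  normals <- file.path(input_dir, paste0(ids, ".normal.vcf"))
  if (mode == "tumor_normal" && !all(file.exists(normals))) {
    stopf("missing matched normal VCF(s) for: %s",
          paste(ids[!file.exists(normals)], collapse = ", "))
  }
  data.frame(sample_id = ids, tumor = tumors, normal = normals,
             stringsAsFactors = FALSE)
}

#' Estimate TMB for every sample in a directory
#'
#' Reads per-sample VCFs from `input_dir` (as laid out by
#' [run_simulate()]), applies the requested workflow, and writes the
#' per-sample TMB table (`tmb.tsv`, all samples with their QC status), the
#' QC-passed cohort table (`cohort.tsv`), and — for the tumor-only
#' workflow — the per-sample filter trace (`filter_trace.tsv`).
#'
#' Samples failing QC (cumulative score < 3 from `qc_metrics.tsv`) appear
#' in `tmb.tsv` flagged `qc_passed = FALSE` and are excluded from
#' `cohort.tsv`. When no QC metrics file exists, all samples pass.
#'
#' @param config a [pipeline_config()].
#' @param input_dir directory with `<id>.tumor.vcf` (and
#'   `<id>.normal.vcf` in `tumor_normal` mode), optional
#'   `qc_metrics.tsv`, `truth.tsv`, and `baseline_panel.tsv` (required in
#'   `tumor_only` mode).
#' @param output_dir output directory.
#' @param mode `"tumor_only"` or `"tumor_normal"`.
#' @param overwrite allow writing into a non-empty directory.
#' @return the per-sample TMB data.frame, invisibly.
#' @export
run_tmb <- function(config, input_dir, output_dir,
                    mode = c("tumor_only", "tumor_normal"),
                    overwrite = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  mode <- match.arg(mode)
  pairs <- discover_pairs(input_dir, mode)
  prepare_output_dir(output_dir, overwrite)
  cfg <- as_filter_config(config)
  meta <- provenance(config)

  panel <- NULL
  if (mode == "tumor_only") {
    panel_path <- file.path(input_dir, "baseline_panel.tsv")
    if (!file.exists(panel_path)) {
      stopf("tumor_only mode requires %s", panel_path)
    }
    panel <- read_panel_tsv(panel_path)
  }

  qc_path <- file.path(input_dir, "qc_metrics.tsv")
  qc_passed <- stats::setNames(rep(TRUE, nrow(pairs)), pairs$sample_id)
  qc_report <- NULL
  if (file.exists(qc_path)) {
    qc_report <- score_qc_table(read_tsv(qc_path), as_qc_thresholds(config))
    idx <- match(pairs$sample_id, qc_report$sample_id)
    qc_passed[!is.na(idx)] <- qc_report$passed[idx[!is.na(idx)]]
  }

  truth_path <- file.path(input_dir, "truth.tsv")
  cancer <- stats::setNames(rep(NA_character_, nrow(pairs)), pairs$sample_id)
  if (file.exists(truth_path)) {
    tt <- read_tsv(truth_path)
    idx <- match(pairs$sample_id, tt$sample_id)
    cancer[!is.na(idx)] <- tt$cancer_type[idx[!is.na(idx)]]
  }

  rows <- vector("list", nrow(pairs))
  traces <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    tumor <- read_vcf(pairs$tumor[i], "tumor", sample_id = pairs$sample_id[i])
    if (mode == "tumor_only") {
      res <- tumor_only_somatic(tumor, panel, cfg)
      somatic <- res$callset
      traces[[i]] <- cbind(sample_id = pairs$sample_id[i], res$trace)
    } else {
      normal <- read_vcf(pairs$normal[i], "normal",
                         sample_id = pairs$sample_id[i])
      somatic <- matched_subtraction(tumor, normal, cfg)
    }
    rows[[i]] <- as.data.frame(
      tmb_for_sample(somatic, config$target_size_mb, mode)
    )
  }
  tmb_table <- do.call(rbind, rows)
  tmb_table$cancer_type <- unname(cancer[tmb_table$sample_id])
  tmb_table$qc_passed <- unname(qc_passed[tmb_table$sample_id])

  write_tsv(tmb_table, file.path(output_dir, "tmb.tsv"), comment = meta)
  cohort <- tmb_table[tmb_table$qc_passed,
                      c("sample_id", "cancer_type", "tmb", "qc_passed")]
  write_tsv(cohort, file.path(output_dir, "cohort.tsv"), comment = meta)
  if (!is.null(qc_report)) {
    write_tsv(qc_report, file.path(output_dir, "qc_report.tsv"), comment = meta)
  }
  if (mode == "tumor_only") {
    write_tsv(do.call(rbind, traces), file.path(output_dir, "filter_trace.tsv"),
              comment = meta)
  }
  invisible(tmb_table)
}

read_cohort_tsv <- function(path, name = "cohort") {
  t <- read_tsv(path)
  need <- c("sample_id", "cancer_type", "tmb")
  missing_cols <- setdiff(need, names(t))
  if (length(missing_cols) > 0) {
    stopf("%s (%s): missing column(s) %s", name, path,
          paste(missing_cols, collapse = ", "))
  }
  t$tmb <- suppressWarnings(as.numeric(t$tmb))
  bad <- which(is.na(t$tmb))
  if (length(bad) > 0) {
    stopf("%s (%s): unparseable tmb value at data line %d", name, path, bad[1])
  }
  check_cohort_table(t, name)
}

#' Cohort-level statistics reports
#'
#' Reads a per-sample TMB table and writes the per-cancer summary, the
#' percentile table, and the bootstrap ninth-decile estimate; when an
#' external cohort table (e.g. a TCGA-derived per-sample TMB TSV) is
#' given, also writes the per-cancer Kruskal-Wallis comparison.
#'
#' @param config a [pipeline_config()].
#' @param tmb_path TSV with columns `sample_id`, `cancer_type`, `tmb`.
#' @param output_dir output directory.
#' @param external_path optional external-cohort TSV (same columns).
#' @param overwrite allow writing into a non-empty directory.
#' @return list of the computed tables, invisibly.
#' @export
run_cohort <- function(config, tmb_path, output_dir, external_path = NULL,
                       overwrite = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- read_cohort_tsv(tmb_path)
  prepare_output_dir(output_dir, overwrite)
  meta <- provenance(config)

  summary_t <- per_cancer_summary(cohort)
  pct <- percentile_table(cohort)
  boot <- bootstrap_decile(
    cohort$tmb, n_iterations = config$bootstrap$n_iterations,
    level = config$bootstrap$level, seed = derive_seed(config$seed, 17)
  )
  boot_t <- data.frame(
    percentile_level = boot$percentile_level,
    n_iterations = boot$n_iterations,
    mean_value = boot$mean_value,
    sd_value = stats::sd(boot$per_iteration_values),
    n_samples = nrow(cohort)
  )
  write_tsv(summary_t, file.path(output_dir, "per_cancer_summary.tsv"),
            comment = meta)
  write_tsv(pct, file.path(output_dir, "percentiles.tsv"), comment = meta)
  write_tsv(boot_t, file.path(output_dir, "bootstrap.tsv"), comment = meta)

  comparison <- NULL
  if (!is.null(external_path)) {
    external <- read_cohort_tsv(external_path, "external")
    comparison <- compare_cohorts(cohort, external)
    write_tsv(as.data.frame(comparison),
              file.path(output_dir, "comparison.tsv"), comment = meta)
  }
  invisible(list(summary = summary_t, percentiles = pct, bootstrap = boot,
                 comparison = comparison))
}

#' Validate the tumor-only workflow against matched subtraction
#'
#' Runs both workflows over every matched pair in `input_dir` and reports
#' the per-sample TMB pairs with their Pearson correlation.
#'
#' @param config a [pipeline_config()].
#' @param input_dir directory with matched `<id>.tumor.vcf` /
#'   `<id>.normal.vcf` files and `baseline_panel.tsv`.
#' @param output_dir optional; when given, writes `validation.tsv`.
#' @param overwrite allow writing into a non-empty directory.
#' @return list with `table` (per-sample TMB pairs), `pearson_r`,
#'   `r_squared`.
#' @export
run_validate <- function(config, input_dir, output_dir = NULL,
                         overwrite = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  pairs <- discover_pairs(input_dir, "tumor_normal")
  panel <- read_panel_tsv(file.path(input_dir, "baseline_panel.tsv"))
  cfg <- as_filter_config(config)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    tumor <- read_vcf(pairs$tumor[i], "tumor", sample_id = pairs$sample_id[i])
    normal <- read_vcf(pairs$normal[i], "normal",
                       sample_id = pairs$sample_id[i])
    to <- tmb_for_sample(tumor_only_somatic(tumor, panel, cfg)$callset,
                         config$target_size_mb, "tumor_only")
    tn <- tmb_for_sample(matched_subtraction(tumor, normal, cfg),
                         config$target_size_mb, "tumor_normal")
    data.frame(sample_id = pairs$sample_id[i], tmb_tumor_only = to$tmb,
               tmb_tumor_normal = tn$tmb, stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  corr <- correlation_validation(table[, c("tmb_tumor_only", "tmb_tumor_normal")])
  if (!is.null(output_dir)) {
    prepare_output_dir(output_dir, overwrite)
    write_tsv(table, file.path(output_dir, "validation.tsv"),
              comment = c(provenance(config),
                          sprintf("pearson_r=%.6f r_squared=%.6f",
                                  corr$pearson_r, corr$r_squared)))
  }
  c(list(table = table), corr)
}
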