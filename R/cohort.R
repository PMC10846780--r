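# Cohort-level statistics over per-sample TMB scores: percentile
# distributions, the bootstrap ninth-decile ("phantom cohort") estimate,
# per-cancer summaries, two-cohort Kruskal-Wallis comparison, and the
# tumor-only vs tumor-normal correlation validation.

#' Linear-interpolation percentile
#'
#' Single percentile definition shared by every consumer in the package
#' (deciles, medians, percentile tables): linear interpolation between
#' order statistics (`stats::quantile` type 7). Level 0 is the minimum,
#' level 100 the maximum.
#'
#' @param scores non-empty numeric vector.
#' @param level percentile level in \[0, 100\].
#' @return the percentile value (vectorised over `level`).
#' @examples
#' percentile(c(1, 2, 3, 4), 50)  # 2.5
#' @export
percentile <- function(scores, level) {
  if (length(scores) == 0) stopf("scores must be non-empty")
  if (anyNA(scores)) stopf("scores must not contain NA")
  if (!is.numeric(level) || anyNA(level) || any(level < 0 | level > 100)) {
    stopf("level must be in [0, 100]")
  }
  unname(stats::quantile(scores, probs = level / 100, type = 7, names = FALSE))
}

#' Bootstrap estimate of a TMB percentile
#'
#' Generates `n_iterations` phantom cohorts by resampling the observed
#' scores with replacement at full cohort size, takes the `level`
#' percentile of each, and averages them — by default the ninth decile
#' (90th percentile) over 1,000 iterations.
#'
#' @param scores non-empty numeric vector of per-sample TMB values.
#' @param n_iterations number of phantom cohorts (default 1000).
#' @param level percentile level (default 90, the ninth decile).
#' @param seed RNG seed; the bootstrap consumes its own stream.
#' @return an object of class `tmb_boot` with fields `n_iterations`,
#'   `percentile_level`, `per_iteration_values`, `mean_value`, `seed`.
#' @export
bootstrap_decile <- function(scores, n_iterations = 1000, level = 90,
                             seed = 1) {
  if (length(scores) == 0) stopf("scores must be non-empty")
  if (!is_count(n_iterations) || n_iterations < 1) {
    stopf("n_iterations must be >= 1")
  }
  n <- length(scores)
  vals <- with_seed(seed, {
    vapply(seq_len(n_iterations), function(i) {
      percentile(scores[sample.int(n, n, replace = TRUE)], level)
    }, numeric(1))
  })
  structure(
    list(
      n_iterations = as.integer(n_iterations),
      percentile_level = level,
      per_iteration_values = vals,
      mean_value = mean(vals),
      seed = seed
    ),
    class = "tmb_boot"
  )
}

#' @export
print.tmb_boot <- function(x, ...) {
  cat(sprintf(
    "<tmb_boot> mean %g-th percentile over %d phantom cohorts: %.4g (sd %.3g)\n",
    x$percentile_level, x$n_iterations, x$mean_value,
    stats::sd(x$per_iteration_values)
  ))
  invisible(x)
}

check_cohort_table <- function(cohort, name = "cohort") {
  stopifnot(is.data.frame(cohort))
  need <- c("sample_id", "cancer_type", "tmb")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0) {
    stopf("%s table missing column(s): %s", name,
          paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(cohort$sample_id)) stopf("%s: duplicate sample ids", name)
  if (any(cohort$tmb < 0, na.rm = TRUE)) stopf("%s: negative TMB values", name)
  cohort
}

#' Per-cancer TMB summary
#'
#' @param cohort data.frame with columns `sample_id`, `cancer_type`,
#'   `tmb`.
#' @return data.frame with one row per cancer type: `cancer_type`, `n`,
#'   `min`, `max`, `median` (median via [percentile()] at level 50).
#' @export
per_cancer_summary <- function(cohort) {
  check_cohort_table(cohort)
  types <- sort(unique(cohort$cancer_type))
  out <- lapply(types, function(ct) {
    x <- cohort$tmb[cohort$cancer_type == ct]
    data.frame(cancer_type = ct, n = length(x), min = min(x), max = max(x),
               median = percentile(x, 50), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Percentile table for one or more TMB series
#'
#' @param cohort data.frame with `cancer_type` and `tmb` columns.
#' @param levels percentile grid (default 5, 10, ..., 95).
#' @param by_cancer add one column per cancer type alongside the overall
#'   cohort column.
#' @return data.frame: `level` plus one value column per series; values
#'   are non-decreasing down each column.
#' @export
percentile_table <- function(cohort, levels = seq(5, 95, by = 5),
                             by_cancer = TRUE) {
  check_cohort_table(cohort)
  out <- data.frame(level = levels, overall = percentile(cohort$tmb, levels))
  if (by_cancer) {
    for (ct in sort(unique(cohort$cancer_type))) {
      out[[ct]] <- percentile(cohort$tmb[cohort$cancer_type == ct], levels)
    }
  }
  out
}

#' Compare TMB distributions between two cohorts per cancer type
#'
#' For every cancer type with at least `min_n` samples in each cohort,
#' runs a two-group Kruskal-Wallis rank test (tie-corrected, asymptotic
#' chi-square p-value) of the TMB values between the cohorts. P-values are
#' reported raw (unadjusted).
#'
#' @param a,b cohort data.frames with `sample_id`, `cancer_type`, `tmb`.
#' @param min_n minimum per-cohort group size for a cancer type to be
#'   compared (default 30).
#' @return an object of class `cohort_comparison`: a data.frame with
#'   columns `cancer_type`, `n_a`, `n_b`, `median_a`, `median_b`,
#'   `statistic` (Kruskal-Wallis H), `p_value`.
#' @export
compare_cohorts <- function(a, b, min_n = 30) {
  check_cohort_table(a, "a")
  check_cohort_table(b, "b")
  shared <- intersect(unique(a$cancer_type), unique(b$cancer_type))
  rows <- list()
  for (ct in sort(shared)) {
    xa <- a$tmb[a$cancer_type == ct]
    xb <- b$tmb[b$cancer_type == ct]
    if (length(xa) < min_n || length(xb) < min_n) next
    kw <- stats::kruskal.test(list(xa, xb))
    rows[[ct]] <- data.frame(
      cancer_type = ct, n_a = length(xa), n_b = length(xb),
      median_a = percentile(xa, 50), median_b = percentile(xb, 50),
      statistic = unname(kw$statistic), p_value = unname(kw$p.value),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else data.frame(
    cancer_type = character(), n_a = integer(), n_b = integer(),
    median_a = numeric(), median_b = numeric(), statistic = numeric(),
    p_value = numeric(), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("cohort_comparison", "data.frame")
  out
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("Two-cohort TMB comparison (Kruskal-Wallis, unadjusted p-values)\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Tumor-only vs tumor-normal TMB correlation
#'
#' Pearson product-moment correlation between per-sample TMB estimated by
#' the tumor-only filtration workflow and by matched tumor-normal
#' subtraction, over the same samples. Both r and r squared are reported.
#'
#' @param paired two-column data.frame or matrix: column 1 tumor-only TMB,
#'   column 2 tumor-normal TMB, one row per sample (>= 3 rows).
#' @return list with `pearson_r` and `r_squared`.
#' @export
correlation_validation <- function(paired) {
  paired <- as.matrix(paired)
  if (!is.numeric(paired) || ncol(paired) != 2) {
    stopf("paired must be a two-column numeric table")
  }
  if (nrow(paired) < 3) stopf("need at least 3 pairs")
  if (anyNA(paired)) stopf("paired values must not contain NA")
  for (j in 1:2) {
    if (stats::var(paired[, j]) == 0) {
      stopf("zero variance in %s TMB values",
            c("tumor-only", "tumor-normal")[j])
    }
  }
  r <- stats::cor(paired[, 1], paired[, 2], method = "pearson")
  list(pearson_r = r, r_squared = r^2)
}
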