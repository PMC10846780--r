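# Sequencing-QC scoring: four metrics, 0/1/2 each, cumulative 0-8 score,
# category, and cohort gating at pass >= 3.

QC_METRICS <- c("mean_target_coverage", "uniformity", "pct_duplicates",
                "base_enrichment")

#' QC scoring thresholds
#'
#' Two cut-points per metric split its range into 0/1/2 score bands. For a
#' higher-is-better metric, `score1_cut <= value < score2_cut` scores 1 and
#' `value >= score2_cut` scores 2; for lower-is-better the inequalities
#' flip. Boundary values always take the higher score.
#'
#' Defaults: mean target coverage >= 150x scores 2, 100-149 scores 1;
#' uniformity >= 90\% scores 2, 80-89.99 scores 1; duplicate reads <= 20\%
#' scores 2, 20.01-40 scores 1; base enrichment >= 80\% scores 2, 60-79.99
#' scores 1. All four cut-point pairs are configurable, so a laboratory
#' with its own validated QC bands can reproduce them exactly.
#'
#' @param mean_target_coverage,uniformity,pct_duplicates,base_enrichment
#'   numeric length-2 vectors `c(score1_cut, score2_cut)`.
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(mean_target_coverage = c(100, 150),
                          uniformity = c(80, 90),
                          pct_duplicates = c(40, 20),
                          base_enrichment = c(60, 80)) {
  th <- list(
    mean_target_coverage = list(cuts = mean_target_coverage,
                                higher_is_better = TRUE,
                                range = c(0, Inf)),
    uniformity = list(cuts = uniformity, higher_is_better = TRUE,
                      range = c(0, 100)),
    pct_duplicates = list(cuts = pct_duplicates, higher_is_better = FALSE,
                          range = c(0, 100)),
    base_enrichment = list(cuts = base_enrichment, higher_is_better = TRUE,
                           range = c(0, 100))
  )
  for (m in QC_METRICS) {
    cuts <- th[[m]]$cuts
    if (!is.numeric(cuts) || length(cuts) != 2 || anyNA(cuts)) {
      stopf("%s: cut-points must be two numbers", m)
    }
    ok <- if (th[[m]]$higher_is_better) cuts[1] < cuts[2] else cuts[2] < cuts[1]
    if (!ok) stopf("%s: cut-points out of order for its quality direction", m)
  }
  structure(th, class = "qc_thresholds")
}

#' Score one QC metric as 0, 1, or 2
#'
#' Piecewise-constant and monotone in the metric's quality direction;
#' values exactly at a cut-point take the higher score.
#'
#' @param value metric value, within the metric's valid range.
#' @param metric metric name (one of the four scored metrics).
#' @param thresholds a [qc_thresholds()] object.
#' @return integer score 0, 1, or 2.
#' @examples
#' score_metric(200, "mean_target_coverage")  # 2
#' score_metric(100, "pct_duplicates")        # 0: all reads duplicated
#' @export
score_metric <- function(value, metric = QC_METRICS,
                         thresholds = qc_thresholds()) {
  metric <- match.arg(metric)
  stopifnot(inherits(thresholds, "qc_thresholds"))
  t <- thresholds[[metric]]
  if (!is.numeric(value) || anyNA(value) ||
      any(value < t$range[1] | value > t$range[2])) {
    stopf("%s: value outside valid range [%s, %s]", metric,
          t$range[1], t$range[2])
  }
  if (t$higher_is_better) {
    as.integer((value >= t$cuts[1]) + (value >= t$cuts[2]))
  } else {
    as.integer((value <= t$cuts[1]) + (value <= t$cuts[2]))
  }
}

#' Score a sample's QC metrics
#'
#' Scores the four metrics 0/1/2 each, sums them to a cumulative 0-8 score,
#' assigns the category — good (6-8), intermediate (3-5), poor (0-2) — and
#' the pass flag (cumulative >= 3).
#'
#' @param metrics named list or one-row data.frame with the four metric
#'   values (`mean_target_coverage`, `uniformity`, `pct_duplicates`,
#'   `base_enrichment`).
#' @param thresholds a [qc_thresholds()] object.
#' @return an object of class `qc_score` with fields `per_metric`
#'   (named integer vector), `cumulative`, `category`, `passed`.
#' @export
score_sample <- function(metrics, thresholds = qc_thresholds()) {
  missing_m <- setdiff(QC_METRICS, names(metrics))
  if (length(missing_m) > 0) {
    stopf("metrics missing: %s", paste(missing_m, collapse = ", "))
  }
  per <- vapply(QC_METRICS, function(m) {
    score_metric(as.numeric(metrics[[m]]), m, thresholds)
  }, integer(1))
  qc_score_from_per_metric(per)
}

# Assemble a qc_score from four 0/1/2 per-metric scores; the single place
# the category bands and pass rule are encoded.
qc_score_from_per_metric <- function(per_metric) {
  stopifnot(length(per_metric) == 4, all(per_metric %in% 0:2))
  cum <- as.integer(sum(per_metric))
  category <- if (cum >= 6) "good" else if (cum >= 3) "intermediate" else "poor"
  structure(
    list(per_metric = per_metric, cumulative = cum, category = category,
         passed = cum >= 3L),
    class = "qc_score"
  )
}

#' @export
print.qc_score <- function(x, ...) {
  cat(sprintf("<qc_score> cumulative %d/8 (%s), %s\n", x$cumulative,
              x$category, if (x$passed) "pass" else "fail"))
  print(x$per_metric)
  invisible(x)
}

#' Gate a cohort on QC pass status
#'
#' Partitions sample ids into passed (cumulative score >= 3) and failed,
#' preserving input order.
#'
#' @param scores named list of `qc_score` objects; names are sample ids.
#' @return list with character vectors `passed` and `failed`.
#' @export
gate_cohort <- function(scores) {
  ids <- names(scores)
  if (length(scores) > 0 && (is.null(ids) || any(!nzchar(ids)))) {
    stopf("scores must be a named list keyed by sample id")
  }
  if (anyDuplicated(ids)) {
    stopf("duplicate sample id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  ok <- vapply(scores, function(s) isTRUE(s$passed), logical(1))
  list(passed = ids[ok], failed = ids[!ok])
}

#' Score a cohort QC metrics table
#'
#' Applies [score_sample()] to each row of a metrics table (as produced by
#' [generate_qc_metrics()] or read from a metrics TSV) and returns the
#' table extended with per-metric scores, the cumulative score, category,
#' and pass flag.
#'
#' @param metrics data.frame with `sample_id` and the four metric columns.
#' @param thresholds a [qc_thresholds()] object.
#' @return data.frame QC report, one row per sample.
#' @export
score_qc_table <- function(metrics, thresholds = qc_thresholds()) {
  stopifnot(is.data.frame(metrics), "sample_id" %in% names(metrics))
  if (anyDuplicated(metrics$sample_id)) {
    stopf("duplicate sample id(s) in metrics table")
  }
  scores <- lapply(seq_len(nrow(metrics)), function(i) {
    score_sample(metrics[i, , drop = FALSE], thresholds)
  })
  per <- do.call(rbind, lapply(scores, function(s) s$per_metric))
  colnames(per) <- paste0("score_", QC_METRICS)
  cbind(
    metrics,
    as.data.frame(per),
    cumulative = vapply(scores, function(s) s$cumulative, integer(1)),
    category = vapply(scores, function(s) s$category, character(1)),
    passed = vapply(scores, function(s) s$passed, logical(1))
  )
}
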