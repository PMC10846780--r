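# TMB scoring: somatic mutation count per megabase of exome target.

#' Compute a TMB score
#'
#' TMB = number of true somatic mutations divided by the exome target size
#' in Mb.
#'
#' @param somatic_count non-negative integer count of somatic mutations.
#' @param target_size_mb exome capture size in Mb (> 0). There is no
#'   universal capture size; it must match the panel the variants were
#'   called on (a conventional whole-exome scale of 30 Mb is used as the
#'   package default elsewhere).
#' @return TMB in mutations per Mb.
#' @examples
#' compute_tmb(60, 30)   # 2 mut/Mb
#' compute_tmb(651, 30)  # 21.7 mut/Mb
#' @export
compute_tmb <- function(somatic_count, target_size_mb) {
  if (!is_count(somatic_count)) stopf("somatic_count must be a non-negative integer")
  if (!is_scalar_num(target_size_mb) || target_size_mb <= 0) {
    stopf("target_size_mb must be > 0")
  }
  somatic_count / target_size_mb
}

#' TMB result for one filtered sample
#'
#' @param cs a filtered somatic `callset` (output of [tumor_only_somatic()]
#'   or [matched_subtraction()]).
#' @param target_size_mb exome capture size in Mb.
#' @param workflow `"tumor_only"` or `"tumor_normal"`.
#' @return an object of class `tmb_result` with fields `sample_id`,
#'   `somatic_count`, `target_size_mb`, `tmb`, `workflow`.
#' @export
tmb_for_sample <- function(cs, target_size_mb = 30,
                           workflow = c("tumor_only", "tumor_normal")) {
  stopifnot(inherits(cs, "callset"))
  workflow <- match.arg(workflow)
  n <- nrow(cs$records)
  structure(
    list(
      sample_id = cs$sample_id,
      somatic_count = as.integer(n),
      target_size_mb = target_size_mb,
      tmb = compute_tmb(n, target_size_mb),
      workflow = workflow
    ),
    class = "tmb_result"
  )
}

#' @export
print.tmb_result <- function(x, ...) {
  cat(sprintf(
    "<tmb_result> %s (%s): %d somatic / %.4g Mb = %.4g mut/Mb\n",
    x$sample_id, x$workflow, x$somatic_count, x$target_size_mb, x$tmb
  ))
  invisible(x)
}

#' @export
as.data.frame.tmb_result <- function(x, ...) {
  data.frame(
    sample_id = x$sample_id, workflow = x$workflow,
    somatic_count = x$somatic_count, target_size_mb = x$target_size_mb,
    tmb = x$tmb, stringsAsFactors = FALSE
  )
}
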