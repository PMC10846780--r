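# Staged somatic filtration for tumor-only call sets, and matched
# tumor-normal subtraction (the validation workflow).
#
# Stage 1 keeps high-quality coding variants (quality >= 10, depth >= 30x,
# synonymous and noncoding removed). Stage 2 eliminates germline variants
# in three levels: population allele frequency above 1% in any annotated
# database (tolerant), VAF at or below 0.05 or inside the closed
# heterozygous band 0.5 +/- 0.05 (stringent), and membership in a
# healthy-donor baseline panel. Every level is a per-record predicate, so
# the sequential composition equals the conjunction of predicates and the
# level order cannot change the result.

#' Filtration thresholds
#'
#' @param min_qual minimum variant quality retained (default 10,
#'   inclusive).
#' @param min_depth minimum read depth retained (default 30x, inclusive).
#' @param max_pop_af population-frequency cut: a variant above this
#'   frequency in any annotated database is treated as a polymorphism and
#'   removed (default 0.01).
#' @param low_vaf_cut VAF at or below this is removed as noise /
#'   sub-threshold evidence (default 0.05).
#' @param germ_het_band closed VAF interval removed as germline
#'   heterozygous (default \[0.45, 0.55\], i.e. 0.5 +/- 0.05).
#' @param hom_vaf_cut optional: when set (e.g. 0.95), VAF at or above it
#'   is removed as germline homozygous. Off by default; high-VAF germline
#'   is otherwise caught by the population and baseline levels.
#' @param drop_synonymous,drop_noncoding remove synonymous / noncoding
#'   records in stage 1 (both default `TRUE`).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(min_qual = 10, min_depth = 30, max_pop_af = 0.01,
                          low_vaf_cut = 0.05, germ_het_band = c(0.45, 0.55),
                          hom_vaf_cut = NULL, drop_synonymous = TRUE,
                          drop_noncoding = TRUE) {
  cfg <- list(
    min_qual = min_qual, min_depth = min_depth, max_pop_af = max_pop_af,
    low_vaf_cut = low_vaf_cut, germ_het_band = germ_het_band,
    hom_vaf_cut = hom_vaf_cut, drop_synonymous = isTRUE(drop_synonymous),
    drop_noncoding = isTRUE(drop_noncoding)
  )
  if (!is_scalar_num(cfg$min_qual) || cfg$min_qual < 0) stopf("min_qual must be >= 0")
  if (!is_count(cfg$min_depth)) stopf("min_depth must be a non-negative integer")
  if (!is_prob(cfg$max_pop_af)) stopf("max_pop_af must be in [0, 1]")
  band <- cfg$germ_het_band
  if (!is.numeric(band) || length(band) != 2 || anyNA(band)) {
    stopf("germ_het_band must be two numbers")
  }
  if (!(0 <= cfg$low_vaf_cut && cfg$low_vaf_cut < band[1] &&
        band[1] < band[2] && band[2] <= 1)) {
    stopf("require 0 <= low_vaf_cut < germ_het_band[1] < germ_het_band[2] <= 1")
  }
  if (!is.null(cfg$hom_vaf_cut) &&
      (!is_scalar_num(cfg$hom_vaf_cut) || cfg$hom_vaf_cut <= band[2] ||
       cfg$hom_vaf_cut > 1)) {
    stopf("hom_vaf_cut must be in (germ_het_band[2], 1]")
  }
  structure(cfg, class = "filter_config")
}

keep_subset <- function(cs, keep) {
  cs$records <- cs$records[keep, , drop = FALSE]
  rownames(cs$records) <- NULL
  cs
}

#' Stage 1: high-quality coding variant filtration
#'
#' Retains records with quality >= `min_qual`, depth >= `min_depth`
#' (both boundaries inclusive), and — with the default drop flags — a
#' coding nonsynonymous consequence. Order-preserving; output is a subset
#' of the input.
#'
#' @param cs a `callset`.
#' @param cfg a [filter_config()].
#' @return the filtered `callset`.
#' @export
stage1_filter <- function(cs, cfg = filter_config()) {
  stopifnot(inherits(cs, "callset"), inherits(cfg, "filter_config"))
  r <- cs$records
  keep <- r$qual >= cfg$min_qual & r$depth >= cfg$min_depth
  if (cfg$drop_synonymous) keep <- keep & r$consequence != "coding_synonymous"
  if (cfg$drop_noncoding) keep <- keep & r$consequence != "noncoding"
  keep_subset(cs, keep)
}

#' Stage 2 level 1 (tolerant): population-frequency filter
#'
#' Removes a record iff any annotated population allele frequency (any
#' `af_*` column, e.g. global or South Asian) exceeds `max_pop_af` — the
#' variant is a common polymorphism, hence germline. Records with no AF
#' annotation are retained: absence from the databases is no evidence of
#' being polymorphic.
#'
#' @inheritParams stage1_filter
#' @return the filtered `callset`.
#' @export
level1_population_filter <- function(cs, cfg = filter_config()) {
  stopifnot(inherits(cs, "callset"), inherits(cfg, "filter_config"))
  r <- cs$records
  cols <- af_columns(r)
  if (length(cols) == 0 || nrow(r) == 0) return(cs)
  af <- as.matrix(r[, cols, drop = FALSE])
  if (any(af < 0 | af > 1, na.rm = TRUE)) {
    stopf("sample %s: population AF outside [0, 1]", cs$sample_id)
  }
  polymorphic <- rowSums(af > cfg$max_pop_af, na.rm = TRUE) > 0
  keep_subset(cs, !polymorphic)
}

#' Stage 2 level 2 (stringent): VAF-band germline filter
#'
#' Removes a record iff its VAF is at or below `low_vaf_cut`, falls inside
#' the closed germline heterozygous band, or — when `hom_vaf_cut` is set —
#' is at or above that homozygous cut.
#'
#' @inheritParams stage1_filter
#' @return the filtered `callset`.
#' @export
level2_vaf_filter <- function(cs, cfg = filter_config()) {
  stopifnot(inherits(cs, "callset"), inherits(cfg, "filter_config"))
  v <- cs$records$vaf
  drop <- v <= cfg$low_vaf_cut |
    (v >= cfg$germ_het_band[1] & v <= cfg$germ_het_band[2])
  if (!is.null(cfg$hom_vaf_cut)) drop <- drop | v >= cfg$hom_vaf_cut
  keep_subset(cs, !drop)
}

#' Stage 2 level 3: baseline-panel filter
#'
#' Removes a record iff its canonical variant key is present in the
#' healthy-donor baseline panel.
#'
#' @inheritParams stage1_filter
#' @param panel a [baseline_panel()] with at least one key.
#' @return the filtered `callset`.
#' @export
level3_baseline_filter <- function(cs, panel) {
  stopifnot(inherits(cs, "callset"), inherits(panel, "baseline_panel"))
  if (length(panel$keys) == 0) stopf("baseline panel is empty")
  keep_subset(cs, !variant_key(cs) %in% panel$keys)
}

#' Tumor-only somatic filtration (stage 1 + three-level germline removal)
#'
#' Applies [stage1_filter()], [level1_population_filter()],
#' [level2_vaf_filter()], and [level3_baseline_filter()] in sequence and
#' records the surviving count after each step.
#'
#' @param cs a tumor `callset`.
#' @param panel a [baseline_panel()].
#' @param cfg a [filter_config()].
#' @return list with `callset` (the somatic survivors) and `trace`
#'   (data.frame of step names and non-increasing record counts:
#'   input, stage1, level1, level2, level3).
#' @export
tumor_only_somatic <- function(cs, panel, cfg = filter_config()) {
  stopifnot(inherits(cs, "callset"))
  if (cs$source != "tumor") {
    stopf("tumor_only_somatic expects a tumor call set, got source '%s'",
          cs$source)
  }
  steps <- list(
    stage1 = function(x) stage1_filter(x, cfg),
    level1 = function(x) level1_population_filter(x, cfg),
    level2 = function(x) level2_vaf_filter(x, cfg),
    level3 = function(x) level3_baseline_filter(x, panel)
  )
  counts <- c(input = nrow(cs$records))
  out <- cs
  for (s in names(steps)) {
    out <- steps[[s]](out)
    counts[s] <- nrow(out$records)
  }
  list(
    callset = out,
    trace = data.frame(step = names(counts), n = as.integer(counts),
                       row.names = NULL, stringsAsFactors = FALSE)
  )
}

#' Matched tumor-normal subtraction
#'
#' The validation workflow: stage-1 filtration of the tumor call set with
#' the same thresholds as the tumor-only workflow, then removal of every
#' record whose canonical variant key occurs anywhere in the matched
#' normal call set. Survivors are taken as true somatic variants.
#'
#' @param tumor a tumor `callset`.
#' @param normal the matched normal `callset`.
#' @param cfg a [filter_config()]; only its stage-1 thresholds apply.
#' @return the subtracted tumor `callset`.
#' @export
matched_subtraction <- function(tumor, normal, cfg = filter_config()) {
  stopifnot(inherits(tumor, "callset"), inherits(normal, "callset"))
  if (tumor$source != "tumor") stopf("first argument must have source 'tumor'")
  if (normal$source != "normal") stopf("second argument must have source 'normal'")
  out <- stage1_filter(tumor, cfg)
  normal_keys <- variant_key(normal)
  keep_subset(out, !variant_key(out) %in% normal_keys)
}
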