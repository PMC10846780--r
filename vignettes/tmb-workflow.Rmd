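---
title: "Estimating tumor mutation burden from tumor-only exomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tumor mutation burden from tumor-only exomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmbflow)
```

## The problem

Tumor mutation burden (TMB) — the number of somatic coding mutations per
megabase of sequenced exome — is a biomarker for response to immune
checkpoint inhibition. Computing it is trivial when a matched normal
sample is available: variants shared with the normal are germline, the
rest are somatic. In routine clinical practice a matched normal is often
not sequenced, so the germline component (tens of thousands of inherited
variants per exome, against typically tens to a few thousand somatic
ones) must be removed statistically. Doing this badly overestimates TMB
by an order of magnitude.

`tmbflow` implements a staged tumor-only workflow:

1. **Stage 1 — high-quality coding filtration.** Keep calls with variant
   quality ≥ 10 and depth ≥ 30× (both inclusive), and drop synonymous and
   noncoding consequences. These are caller-scale quality thresholds;
   both are `filter_config()` fields.
2. **Stage 2 — three-level germline elimination.**
   * *Level 1 (tolerant, population frequency):* remove any variant whose
     allele frequency exceeds 1% in **any** annotated population database
     (the package carries a global and a South Asian frequency, as
     `af_*` record columns; more databases extend the schema). Variants
     absent from all databases are retained — absence is no evidence of
     being polymorphic.
   * *Level 2 (stringent, VAF):* remove variants with variant allele
     fraction ≤ 0.05 (noise and sub-threshold evidence) or inside the
     closed band 0.5 ± 0.05 (germline heterozygous). An optional
     `hom_vaf_cut` (e.g. 0.95) also removes the homozygous shoulder; it
     is off by default, since high-VAF germline is otherwise caught by
     levels 1 and 3 — enabling it additionally discards high-VAF somatic
     events in highly pure tumors, which is why we leave the stricter
     reading opt-in.
   * *Level 3 (baseline):* remove variants present in a panel pooled from
     healthy-donor germline call sets, keyed by normalized
     chrom:pos:ref:alt identity.
3. **TMB scoring.** TMB = surviving somatic count / exome target size in
   Mb. There is no universal exome size: `target_size_mb` is an explicit
   parameter (default 30 Mb, a conventional whole-exome capture scale)
   rather than a constant hidden in the code, because it rescales every
   score and must match the capture the variants were called on.

Each stage-2 level is a *per-record predicate*: the sequential
composition equals the conjunction of the three predicates, so the level
order cannot change the surviving set. The tests verify this by
permuting the level order and by comparing against a deliberately naive
record-at-a-time oracle.

## Sample QC gating

Before cohort statistics, samples are gated on four sequencing-QC
metrics: mean target coverage, uniformity of coverage, percent duplicate
reads, and base enrichment. Each metric scores 0, 1 or 2 (equal weight);
the cumulative 0–8 score categorizes the sample as good (6–8),
intermediate (3–5) or poor (0–2), and samples scoring ≥ 3 pass into the
cohort. The per-metric cut-points in `qc_thresholds()` are package
defaults chosen as plausible exome-QC conventions (coverage 100/150×,
uniformity 80/90%, duplicates 40/20%, enrichment 60/80%); a laboratory
with its own validated bands supplies them through the same object —
the scoring, categorization and gating logic is independent of the
numeric cuts. Boundary values always take the higher score; that
tie-break is stated once and tested everywhere.

## The matched-pair validation oracle

`matched_subtraction()` applies the same stage-1 thresholds to the tumor
call set and then removes every variant whose key occurs in the matched
normal — the classic tumor–normal workflow, used here as the reference
the tumor-only workflow is validated against. `run_validate()` runs both
workflows over matched pairs and reports the Pearson correlation between
the two per-sample TMB series (and its square, since both statistics are
quoted in practice).

## What the synthetic cohort emulates — and what it does not

No patient-level data ships with the package; a seeded generator
produces matched pairs with known ground truth:

* **Germline structure.** Each sample draws its germline variants from a
  shared population pool (`make_germline_pool()`), so the same sites
  recur across samples and in healthy-donor baseline panels. Het VAF is
  Normal(0.5, `het_vaf_sd`) truncated to [0, 1] — the binomial-sampling
  approximation at exome depths — with `het_vaf_sd` = 0.03 by default
  (roughly 120× coverage); hom VAF is Uniform(0.95, 1). VAFs are drawn
  independently in tumor and normal, as two sequencing observations of
  the same genotype.
* **Population AFs.** A `frac_common` share (default 0.7) of pool
  variants is polymorphic, with AF log-uniform on (0.01, 0.5]; rare
  variants carry AF ≤ 0.01 or none. Only the 1% boundary matters to the
  filter; the log-uniform shape is a neutral stand-in.
* **Somatic signal.** Somatic variants appear only in the tumor, with
  VAF = purity × Beta(2, 2) clonal fraction. By default
  (`recoverable_frac = 1`) somatic VAFs are kept out of the level-2
  removal zones, representing the regime in which the three-level filter
  can succeed; lowering `recoverable_frac` lets one measure how much
  somatic signal the VAF bands destroy when purity pushes VAFs into
  them.
* **Nuisance calls.** `n_noise` low-VAF (≤ 0.05) artifact calls per call
  set, drawn independently for tumor and normal (tumor-private
  artifacts), plus `n_other` synonymous/noncoding decoys. A
  `qual_low_frac` share of all records (default 2%) receives quality
  below 10.

Per-sample counts default to 3,000 het + 1,500 hom + 300 other germline
records — a deliberately desk-scale representation of an exome's coding
germline load that preserves every ratio the filters act on. The
generator does **not** simulate reads, FFPE deamination damage,
copy-number-distorted VAFs, or subclonal phylogenies; passing tests
therefore demonstrate the correctness of the filtering logic under the
stated statistical model, not the field performance of the workflow on
real FFPE exomes.

One structural consequence worth knowing: tumor-private noise calls pass
matched subtraction (the normal has no record of them) but are removed
by the tumor-only VAF filter. With the default `n_noise = 200` this adds
a near-constant ≈ 6.6 mut/Mb offset to the matched-workflow estimate,
which leaves the Pearson correlation between the workflows essentially
untouched; with `n_noise = 0` the two workflows return *identical* key
sets under ideal parameters, and the tests assert exactly that.

## Cohort statistics

* **Percentiles.** One percentile definition — linear interpolation
  between order statistics (`stats::quantile` type 7) — is shared by
  every consumer: medians, percentile tables, and the bootstrap.
* **Bootstrap ninth decile.** `bootstrap_decile()` draws 1,000 phantom
  cohorts (resampled with replacement at full cohort size), takes the
  90th percentile of each, and averages. With constant data the result
  is exact; on 10,000 Uniform(0, 40) draws it recovers the closed-form
  36.0 within Monte-Carlo error (the acceptance suite checks both).
* **Two-cohort comparison.** For every cancer type with ≥ 30 samples in
  both cohorts, a two-group Kruskal-Wallis rank test (tie-corrected,
  asymptotic chi-square p) compares the TMB distributions. P-values are
  reported raw; no multiplicity adjustment is applied across cancer
  types, and the output column is labelled accordingly.

## Numerical and design choices

* **Boundary closure.** Stage-1 thresholds are inclusive (quality 10 and
  depth 30 survive). Level-2 removal bands are closed (VAF exactly 0.05,
  0.45, 0.50 or 0.55 is removed). Level 1 removes strictly above 1%.
* **Any-database rule.** Level 1 removes a variant polymorphic in *any*
  annotated database rather than requiring all databases to agree: the
  union removes more germline, and the level's tolerance refers to what
  it does to somatic variants (true somatic calls are almost never > 1%
  polymorphic), not to leniency toward germline.
* **Key normalization.** Variant identity is chrom:pos:ref:alt after
  shared-suffix then shared-prefix trimming (keeping at least one base
  each, advancing pos per trimmed prefix base), so equivalent indel
  spellings subtract correctly. Full left-alignment against a reference
  genome is out of scope; the generator emits minimal representations.
* **SNVs and indels** are filtered identically and count equally toward
  TMB; multi-allelic sites are split on read into per-alt records.
* **Seeding.** All randomness flows from one seed; per-sample streams
  are derived arithmetically from it, so sample *i*'s data is
  independent of cohort size and order, and every pipeline output is
  byte-identical across reruns (each output file carries the config hash
  and seed in a header comment).
* **Degenerate inputs.** Empty call sets flow through every filter and
  writer; empty scores, zero-variance correlation inputs, out-of-range
  metrics, and duplicate sample ids are hard errors rather than silent
  coercions.

## Problem sizes used in the checks

The validation suite uses a 20-pair cohort for the workflow-agreement
correlation, 200 samples (true TMB ~ Uniform(1, 40) mut/Mb, purity ~
Uniform(0.3, 0.7)) for parameter recovery, 100 random call sets of up to
500 records for the brute-force filter oracle, and 10,000 draws /
1,000 bootstrap iterations for the decile check — sizes chosen so the
whole suite exercises every code path on a laptop in well under a
minute per component while keeping Monte-Carlo error far below the
tolerances being asserted.

## A worked example

```{r example, eval = FALSE}
library(tmbflow)

pool  <- make_germline_pool(size = 20000, seed = 1)
panel <- generate_baseline_panel(pool, complete = TRUE)
pair  <- generate_matched_pair(sim_params(true_tmb = 12, seed = 5),
                               pool = pool, sample_id = "S1")

res <- tumor_only_somatic(pair$tumor, panel)
res$trace
#>     step    n
#> 1  input 5360
#> 2 stage1 4963
#> 3 level1 1849
#> 4 level2  834
#> 5 level3  352

tmb_for_sample(res$callset, 30, "tumor_only")$tmb   # 11.73 mut/Mb
pair$truth$true_tmb                                 # 12
```

The trace is the pipeline's primary debugging surface: stage 1 removes
low-quality and non-coding calls, level 1 the common polymorphisms,
level 2 the heterozygous band and noise tail, level 3 the residual rare
germline — leaving 352 of 5,360 input calls, an 11.73 mut/Mb estimate
against a true 12 (the gap is the 2% low-quality share of somatic
records).

## Known limitations

* The VAF bands assume diploid, copy-neutral sites; amplifications and
  LOH move germline VAFs out of the bands and somatic VAFs into them.
* Rare germline variants absent from both the population databases and
  the baseline panel are indistinguishable from somatic calls in this
  framework and inflate TMB; panel breadth is the only defense.
* The Kruskal-Wallis comparison tests location, not shape; strongly
  biphasic TMB distributions can agree in median while differing
  clinically.
* QC metric *computation* (from BAMs) is out of scope; metrics are
  consumed as a table.
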