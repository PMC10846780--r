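# Stage-1 filtration, three-level germline elimination, and matched
# tumor-normal subtraction.

test_that("stage 1 keeps exactly high-quality coding nonsynonymous records", {
  expect_equal(nrow(stage1_filter(
    one_record_callset(qual = 9.9, depth = 100)
  )$records), 0)
  expect_equal(nrow(stage1_filter(
    one_record_callset(qual = 50, depth = 30, consequence = "coding_synonymous")
  )$records), 0)
  expect_equal(nrow(stage1_filter(
    one_record_callset(qual = 50, depth = 100, consequence = "noncoding")
  )$records), 0)
  expect_equal(nrow(stage1_filter(
    one_record_callset(qual = 50, depth = 29)
  )$records), 0)
  # inclusive boundaries
  expect_equal(nrow(stage1_filter(
    one_record_callset(qual = 10, depth = 30)
  )$records), 1)
})

test_that("population filter removes a record polymorphic in ANY annotated database", {
  expect_equal(nrow(level1_population_filter(
    one_record_callset(af_global = 0.02)
  )$records), 0)
  # rare globally but common in the South Asian database -> removed
  expect_equal(nrow(level1_population_filter(
    one_record_callset(af_global = 0.001, af_sas = 0.03)
  )$records), 0)
  # no AF annotation: absence is not evidence of polymorphism
  expect_equal(nrow(level1_population_filter(one_record_callset())$records), 1)
  # at the 1% boundary: not above, retained
  expect_equal(nrow(level1_population_filter(
    one_record_callset(af_global = 0.01)
  )$records), 1)
  # a looser cutoff retains the same record
  expect_equal(nrow(level1_population_filter(
    one_record_callset(af_global = 0.02), filter_config(max_pop_af = 0.05)
  )$records), 1)
})

test_that("VAF filter removes the noise tail and the closed heterozygous band", {
  removed <- function(vaf, cfg = filter_config()) {
    nrow(level2_vaf_filter(one_record_callset(vaf = vaf), cfg)$records) == 0
  }
  expect_true(removed(0.05))
  expect_true(removed(0.01))
  expect_true(removed(0.45))
  expect_true(removed(0.50))
  expect_true(removed(0.55))
  expect_false(removed(0.0501))
  expect_false(removed(0.4499))
  expect_false(removed(0.5501))
  expect_false(removed(0.30))
  expect_false(removed(0.97))  # homozygous cut is off by default
  cfg_hom <- filter_config(hom_vaf_cut = 0.95)
  expect_true(removed(0.95, cfg_hom))
  expect_true(removed(1.0, cfg_hom))
  expect_false(removed(0.94, cfg_hom))
})

test_that("baseline filter removes exactly panel members", {
  panel <- baseline_panel(c("chr1:100:A:G", "chr2:5:C:T"))
  inside <- one_record_callset(chrom = "chr1", pos = 100L, ref = "A", alt = "G")
  outside <- one_record_callset(chrom = "chr1", pos = 101L, ref = "A", alt = "G")
  expect_equal(nrow(level3_baseline_filter(inside, panel)$records), 0)
  expect_equal(nrow(level3_baseline_filter(outside, panel)$records), 1)
  # trimmed indel spelling still matches the panel key
  indel <- one_record_callset(chrom = "chr1", pos = 100L, ref = "ATT",
                              alt = "GTT")
  expect_equal(nrow(level3_baseline_filter(indel, panel)$records), 0)
  expect_error(level3_baseline_filter(inside, baseline_panel(character())),
               "empty")
})

test_that("pipeline output equals the brute-force per-record predicate conjunction", {
  cfg <- filter_config()
  for (seed in 1:30) {
    panel <- random_panel(50, seed + 1000)
    cs <- random_callset(sample.int(500, 1), seed, panel_keys = panel$keys)
    got <- tumor_only_somatic(cs, panel, cfg)$callset
    expected <- oracle_tumor_only(cs, panel, cfg)
    expect_identical(variant_key(got), variant_key(expected),
                     info = sprintf("seed=%d", seed))
    expect_equal(got$records$vaf, expected$vaf)
  }
})

test_that("germline-elimination levels commute: any order gives the same set", {
  cfg <- filter_config()
  for (seed in 31:40) {
    panel <- random_panel(40, seed + 2000)
    cs <- random_callset(300, seed, panel_keys = panel$keys)
    levels <- list(
      l1 = function(x) level1_population_filter(x, cfg),
      l2 = function(x) level2_vaf_filter(x, cfg),
      l3 = function(x) level3_baseline_filter(x, panel)
    )
    base <- stage1_filter(cs, cfg)
    reference <- NULL
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
    for (ord in perms) {
      out <- base
      for (j in ord) out <- levels[[j]](out)
      keys <- sort(variant_key(out))
      if (is.null(reference)) reference <- keys
      expect_identical(keys, reference,
                       info = paste("order", paste(ord, collapse = "")))
    }
  }
})

test_that("each filter returns a subset and traces are non-increasing", {
  panel <- random_panel(40, 99)
  for (seed in 41:50) {
    cs <- random_callset(200, seed, panel_keys = panel$keys)
    res <- tumor_only_somatic(cs, panel)
    expect_true(all(diff(res$trace$n) <= 0))
    expect_equal(res$trace$n[1], nrow(cs$records))
    expect_equal(res$trace$n[5], nrow(res$callset$records))
    expect_true(all(variant_key(res$callset) %in% variant_key(cs)))
  }
})

test_that("empty input flows through with an all-zero trace", {
  panel <- baseline_panel("chr1:1:A:G")
  cs <- callset("E", tmbflow:::empty_records(), "tumor")
  res <- tumor_only_somatic(cs, panel)
  expect_equal(nrow(res$callset$records), 0)
  expect_true(all(res$trace$n == 0))
})

test_that("an all-germline callset with ideal VAFs and full panel coverage empties out", {
  pool <- make_germline_pool(size = 3000, seed = 60)
  panel <- generate_baseline_panel(pool, complete = TRUE)
  p <- sim_params(true_tmb = 0, n_germline_het = 1500, n_germline_hom = 800,
                  n_other = 200, n_noise = 0, seed = 61)
  pair <- generate_matched_pair(p, pool = pool)
  res <- tumor_only_somatic(pair$tumor, panel)
  expect_equal(nrow(res$callset$records), 0)
})

test_that("matched subtraction removes shared records and keeps tumor-private ones", {
  shared <- make_record(chrom = "chr1", pos = 10L)
  private <- make_record(chrom = "chr2", pos = 20L)
  tumor <- callset("S", rbind(shared, private), "tumor")
  normal <- callset("S", shared, "normal")
  out <- matched_subtraction(tumor, normal)
  expect_equal(nrow(out$records), 1)
  expect_equal(out$records$chrom, "chr2")
  # source contract
  expect_error(matched_subtraction(normal, normal), "tumor")
  expect_error(matched_subtraction(tumor, tumor), "normal")
})

test_that("on an ideal synthetic pair both workflows recover the exact somatic key set", {
  pool <- make_germline_pool(size = 4000, seed = 70)
  panel <- generate_baseline_panel(pool, complete = TRUE)
  p <- sim_params(true_tmb = 15, n_germline_het = 1200, n_germline_hom = 600,
                  n_other = 150, n_noise = 0, qual_low_frac = 0, seed = 71)
  pair <- generate_matched_pair(p, pool = pool)
  k_tumor_only <- sort(variant_key(tumor_only_somatic(pair$tumor, panel)$callset))
  k_matched <- sort(variant_key(matched_subtraction(pair$tumor, pair$normal)))
  expect_identical(k_tumor_only, k_matched)
  expect_setequal(k_matched, pair$truth$true_somatic_keys)
})

test_that("filter configuration invariants are enforced", {
  expect_error(filter_config(low_vaf_cut = 0.5), "germ_het_band")
  expect_error(filter_config(germ_het_band = c(0.55, 0.45)), "germ_het_band")
  expect_error(filter_config(hom_vaf_cut = 0.5), "hom_vaf_cut")
  expect_error(filter_config(max_pop_af = 2), "max_pop_af")
  expect_error(filter_config(min_depth = -1), "min_depth")
})
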