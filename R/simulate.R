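# Synthetic matched tumor/normal cohort generator with known ground truth.
#
# Emulates the statistical structure the germline filters rely on: shared
# germline variants with heterozygous VAF near 0.5 and homozygous VAF near
# 1, common polymorphisms carrying population AF annotations above 1%,
# purity-scaled somatic VAFs present only in the tumor, and low-VAF
# artifact ("noise") calls. Every sample draws its germline from a shared
# population pool so a healthy-donor baseline panel built from the same
# pool covers recurrent germline sites.

#' Simulation parameters for one matched pair
#'
#' @param true_tmb true somatic mutation rate, mutations per Mb (>= 0).
#' @param target_size_mb exome capture size in Mb (> 0); the TMB
#'   denominator.
#' @param purity tumor purity in (0, 1]; somatic VAFs scale with it.
#' @param n_germline_het,n_germline_hom counts of germline heterozygous /
#'   homozygous coding variants per sample.
#' @param frac_common fraction of germline variants that are common
#'   polymorphisms (population AF > 1\%); only used when the pair is
#'   generated without a shared pool.
#' @param het_vaf_sd standard deviation of germline heterozygous VAF
#'   around 0.5 (binomial-sampling approximation).
#' @param n_noise count of low-VAF (<= 0.05) artifact calls per call set,
#'   drawn independently for tumor and normal.
#' @param depth_mean mean site depth (Poisson, floored at 1).
#' @param qual_low_frac fraction of records assigned quality below 10.
#' @param recoverable_frac fraction of somatic VAFs kept outside the
#'   germline VAF-filter bands (strictly above 0.05, outside
#'   \[0.45, 0.55\], below 0.95); the remainder is left wherever purity and
#'   clonal fraction put it, so filter losses can be measured.
#' @param n_other count of extra germline-like records with synonymous or
#'   noncoding consequence (removed by coding filtration; not counted in
#'   the ground truth).
#' @param frac_indel fraction of variants generated as small
#'   insertions/deletions rather than SNVs.
#' @param seed RNG seed for this pair.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(true_tmb = 10, target_size_mb = 30, purity = 0.5,
                       n_germline_het = 3000, n_germline_hom = 1500,
                       frac_common = 0.7, het_vaf_sd = 0.03,
                       n_noise = 200, depth_mean = 150,
                       qual_low_frac = 0.02, recoverable_frac = 1.0,
                       n_other = 300, frac_indel = 0.1, seed = 1) {
  p <- list(
    true_tmb = true_tmb, target_size_mb = target_size_mb, purity = purity,
    n_germline_het = n_germline_het, n_germline_hom = n_germline_hom,
    frac_common = frac_common, het_vaf_sd = het_vaf_sd, n_noise = n_noise,
    depth_mean = depth_mean, qual_low_frac = qual_low_frac,
    recoverable_frac = recoverable_frac, n_other = n_other,
    frac_indel = frac_indel, seed = seed
  )
  if (!is_scalar_num(p$true_tmb) || p$true_tmb < 0) stopf("true_tmb must be >= 0")
  if (!is_scalar_num(p$target_size_mb) || p$target_size_mb <= 0) {
    stopf("target_size_mb must be > 0")
  }
  if (!is_scalar_num(p$purity) || p$purity <= 0 || p$purity > 1) {
    stopf("purity must be in (0, 1]")
  }
  for (f in c("n_germline_het", "n_germline_hom", "n_noise", "n_other")) {
    if (!is_count(p[[f]])) stopf("%s must be a non-negative count", f)
  }
  for (f in c("frac_common", "qual_low_frac", "recoverable_frac", "frac_indel")) {
    if (!is_prob(p[[f]])) stopf("%s must be in [0, 1]", f)
  }
  if (!is_scalar_num(p$het_vaf_sd) || p$het_vaf_sd < 0) {
    stopf("het_vaf_sd must be >= 0")
  }
  if (!is_scalar_num(p$depth_mean) || p$depth_mean <= 0) {
    stopf("depth_mean must be > 0")
  }
  if (!is_count(p$seed)) stopf("seed must be a non-negative integer")
  structure(p, class = "sim_params")
}

# Random variant alleles: SNVs plus anchored insertions/deletions already
# in minimal (trimmed) representation.
random_alleles <- function(n, frac_indel) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  is_indel <- stats::runif(n) < frac_indel
  idx <- which(is_indel)
  if (length(idx) > 0) {
    ins <- stats::runif(length(idx)) < 0.5
    tail_seq <- vapply(idx, function(i) {
      paste(sample(bases, sample(1:3, 1), replace = TRUE), collapse = "")
    }, character(1))
    long <- paste0(ref[idx], tail_seq)
    alt[idx] <- ifelse(ins, long, ref[idx])
    ref[idx] <- ifelse(ins, ref[idx], long)
  }
  list(ref = ref, alt = alt)
}

# Draw n unique variant sites avoiding keys already in `avoid`.
random_sites <- function(n, frac_indel, avoid = character()) {
  if (n == 0) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), key = character(),
                      stringsAsFactors = FALSE))
  }
  chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
  pos <- sample.int(200000000L, n)  # unique positions => unique keys
  al <- random_alleles(n, frac_indel)
  key <- paste(chrom, pos, al$ref, al$alt, sep = ":")
  clash <- key %in% avoid
  while (any(clash)) {
    k <- sum(clash)
    pos[clash] <- sample.int(200000000L, k)
    key <- paste(chrom, pos, al$ref, al$alt, sep = ":")
    clash <- key %in% avoid | duplicated(key)
  }
  data.frame(chrom = chrom, pos = pos, ref = al$ref, alt = al$alt, key = key,
             stringsAsFactors = FALSE)
}

#' Build a shared germline population pool
#'
#' A pool of germline variant sites from which both patient samples and
#' healthy baseline donors draw, so recurrent germline sites are shared
#' across the cohort and representable in a baseline panel. A
#' `frac_common` share carries a population allele frequency above 1\%
#' (log-uniform on (0.01, 0.5\], assigned to the global and/or South Asian
#' database); the remainder is rare, with AF at most 1\% or absent.
#'
#' @param size number of pool variants.
#' @param frac_common fraction of pool variants that are common
#'   polymorphisms.
#' @param frac_indel fraction generated as indels.
#' @param seed RNG seed.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `key`,
#'   `af_global`, `af_sas`, `common`.
#' @export
make_germline_pool <- function(size = 20000, frac_common = 0.7,
                               frac_indel = 0.1, seed = 1) {
  stopifnot(is_count(size), size >= 1, is_prob(frac_common),
            is_prob(frac_indel))
  with_seed(seed, {
    sites <- random_sites(size, frac_indel)
    common <- stats::runif(size) < frac_common
    log_unif <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))
    af_global <- rep(NA_real_, size)
    af_sas <- rep(NA_real_, size)
    n_c <- sum(common)
    if (n_c > 0) {
      # at least one database reports the common variant above 1%
      af_global[common] <- log_unif(n_c, 0.0101, 0.5)
      sas_too <- common & stats::runif(size) < 0.5
      af_sas[sas_too] <- log_unif(sum(sas_too), 0.0101, 0.5)
      global_drop <- common & !is.na(af_sas) & stats::runif(size) < 0.3
      af_global[global_drop] <- NA_real_
    }
    n_r <- sum(!common)
    if (n_r > 0) {
      seen_g <- !common & stats::runif(size) < 0.5
      af_global[seen_g] <- log_unif(sum(seen_g), 1e-5, 0.01)
      seen_s <- !common & stats::runif(size) < 0.3
      af_sas[seen_s] <- log_unif(sum(seen_s), 1e-5, 0.01)
    }
    cbind(sites, data.frame(af_global = af_global, af_sas = af_sas,
                            common = common))
  })
}

# Truncated-normal heterozygous VAF around 0.5 (clipped; sd is small enough
# that clipping and resampling are indistinguishable).
het_vaf <- function(n, sd) pmin(pmax(stats::rnorm(n, 0.5, sd), 0), 1)

# Push somatic VAFs out of the germline-filter removal zones: strictly
# above the 0.05 noise cut, outside the closed [0.45, 0.55] heterozygous
# band, below 0.95. Margins keep clipped values clear of the closed
# boundaries after 6-significant-digit VCF round trips.
clip_recoverable <- function(vaf) {
  vaf <- pmin(pmax(vaf, 0.06), 0.94)
  lo <- vaf >= 0.44 & vaf < 0.5
  hi <- vaf >= 0.5 & vaf <= 0.56
  vaf[lo] <- stats::runif(sum(lo), 0.06, 0.43)
  vaf[hi] <- stats::runif(sum(hi), 0.57, 0.94)
  vaf
}

assemble_records <- function(sites, vaf, consequence, af_global, af_sas,
                             depth_mean, qual_low_frac) {
  n <- nrow(sites)
  if (n == 0) return(empty_records())
  consequence <- rep_len(consequence, n)
  af_global <- rep_len(af_global, n)
  af_sas <- rep_len(af_sas, n)
  depth <- pmax(1L, stats::rpois(n, depth_mean))
  qual <- stats::runif(n, 10, 90)
  low <- stats::runif(n) < qual_low_frac
  qual[low] <- stats::runif(sum(low), 0, 9.9)
  data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    qual = qual, depth = depth, vaf = vaf, consequence = consequence,
    af_global = af_global, af_sas = af_sas, stringsAsFactors = FALSE
  )
}

#' Generate one matched tumor/normal pair with ground truth
#'
#' Germline variants (heterozygous, homozygous, and `n_other` non-coding /
#' synonymous decoys) appear in both call sets with independently drawn
#' VAF, depth, and quality; somatic variants appear only in the tumor with
#' VAF = purity x Beta(2, 2) clonal fraction (kept out of the germline
#' filter bands for a `recoverable_frac` share); noise calls (VAF <= 0.05)
#' are drawn independently per call set. Deterministic given
#' `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @param pool optional shared germline pool from [make_germline_pool()];
#'   when `NULL` a private pool of exactly the needed size is built from
#'   `params$frac_common`.
#' @param sample_id sample identifier for both call sets.
#' @return list with elements `tumor` (callset), `normal` (callset), and
#'   `truth` (list: `sample_id`, `true_somatic_keys`, `true_tmb`).
#' @export
generate_matched_pair <- function(params, pool = NULL, sample_id = "S1") {
  stopifnot(inherits(params, "sim_params"))
  n_germ <- params$n_germline_het + params$n_germline_hom + params$n_other
  with_seed(params$seed, {
    if (is.null(pool)) {
      pool <- make_germline_pool(
        size = max(n_germ, 1), frac_common = params$frac_common,
        frac_indel = params$frac_indel,
        seed = derive_seed(params$seed, 104729)
      )
    }
    if (nrow(pool) < n_germ) {
      stopf("germline pool too small: %d rows for %d germline draws",
            nrow(pool), n_germ)
    }
    germ <- pool[sample.int(nrow(pool), n_germ), , drop = FALSE]
    zyg <- rep(c("het", "hom", "other"),
               c(params$n_germline_het, params$n_germline_hom, params$n_other))
    csq <- ifelse(zyg == "other",
                  sample(c("coding_synonymous", "noncoding"), n_germ,
                         replace = TRUE),
                  "coding_nonsynonymous")

    germ_vaf <- function() {
      v <- het_vaf(n_germ, params$het_vaf_sd)
      v[zyg == "hom"] <- stats::runif(sum(zyg == "hom"), 0.95, 1)
      v
    }

    n_som <- round(params$true_tmb * params$target_size_mb)
    som <- random_sites(n_som, params$frac_indel, avoid = pool$key)
    som_vaf <- params$purity * stats::rbeta(n_som, 2, 2)
    recover <- stats::runif(n_som) < params$recoverable_frac
    som_vaf[recover] <- clip_recoverable(som_vaf[recover])
    som_vaf <- pmin(pmax(som_vaf, 0.001), 1)

    noise_records <- function(avoid) {
      sites <- random_sites(params$n_noise, params$frac_indel, avoid = avoid)
      assemble_records(
        sites, stats::runif(params$n_noise, 0.005, 0.05),
        "coding_nonsynonymous", NA_real_, NA_real_,
        params$depth_mean, params$qual_low_frac
      )
    }

    tumor_records <- rbind(
      assemble_records(germ, germ_vaf(), csq, germ$af_global, germ$af_sas,
                       params$depth_mean, params$qual_low_frac),
      assemble_records(som, som_vaf, "coding_nonsynonymous",
                       NA_real_, NA_real_,
                       params$depth_mean, params$qual_low_frac),
      noise_records(c(pool$key, som$key))
    )
    normal_records <- rbind(
      assemble_records(germ, germ_vaf(), csq, germ$af_global, germ$af_sas,
                       params$depth_mean, params$qual_low_frac),
      noise_records(c(pool$key, som$key))
    )
    tumor_records$key <- NULL
    normal_records$key <- NULL

    list(
      tumor = callset(sample_id, tumor_records, "tumor"),
      normal = callset(sample_id, normal_records, "normal"),
      truth = list(
        sample_id = sample_id,
        true_somatic_keys = som$key,
        true_tmb = params$true_tmb
      )
    )
  })
}

#' Default per-sample parameter sampler for cohort generation
#'
#' Draws true TMB from Uniform(1, 40) mut/Mb and tumor purity from
#' Uniform(0.3, 0.7); all other parameters take their [sim_params()]
#' defaults.
#'
#' @param i sample index (used to derive the per-sample seed).
#' @param seed cohort base seed.
#' @return a [sim_params()] object.
#' @export
default_params_sampler <- function(i, seed) {
  sim_params(
    true_tmb = stats::runif(1, 1, 40),
    purity = stats::runif(1, 0.3, 0.7),
    seed = derive_seed(seed, i)
  )
}

#' Generate a synthetic multi-cancer cohort of matched pairs
#'
#' @param n_samples number of matched pairs (>= 1).
#' @param cancer_labels non-empty character vector of cancer types;
#'   assigned round-robin, or sampled by `label_weights` when given.
#' @param params_sampler function `(i, seed)` returning a [sim_params()]
#'   for sample `i`; defaults to [default_params_sampler()].
#' @param seed cohort base seed; every per-sample stream derives from it,
#'   so sample `i`'s data does not depend on how many samples precede it.
#' @param pool optional shared germline pool (built with
#'   [make_germline_pool()] defaults when `NULL`).
#' @param label_weights optional sampling weights over `cancer_labels`.
#' @return list with `pairs` (list of matched-pair lists), `truth`
#'   (data.frame: sample_id, cancer_type, true_tmb, n_true_somatic), and
#'   `pool` (the shared germline pool used).
#' @export
generate_cohort <- function(n_samples, cancer_labels,
                            params_sampler = default_params_sampler,
                            seed = 1, pool = NULL, label_weights = NULL) {
  if (!is_count(n_samples) || n_samples < 1) stopf("n_samples must be >= 1")
  if (length(cancer_labels) == 0) stopf("cancer_labels must be non-empty")
  if (is.null(pool)) {
    pool <- make_germline_pool(seed = derive_seed(seed, 15485863))
  }
  labels <- with_seed(derive_seed(seed, 32452843), {
    if (is.null(label_weights)) {
      rep_len(cancer_labels, n_samples)
    } else {
      sample(cancer_labels, n_samples, replace = TRUE, prob = label_weights)
    }
  })
  ids <- sprintf("S%04d", seq_len(n_samples))
  pairs <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    p <- with_seed(derive_seed(seed, 2 * i), params_sampler(i, seed))
    pairs[[i]] <- generate_matched_pair(p, pool = pool, sample_id = ids[i])
  }
  truth <- data.frame(
    sample_id = ids,
    cancer_type = labels,
    true_tmb = vapply(pairs, function(x) x$truth$true_tmb, numeric(1)),
    n_true_somatic = vapply(pairs, function(x) length(x$truth$true_somatic_keys),
                            numeric(1)),
    stringsAsFactors = FALSE
  )
  list(pairs = pairs, truth = truth, pool = pool)
}

#' Build a healthy-donor baseline panel from a germline pool
#'
#' Each donor draws `donor_size` germline variants from the shared pool;
#' the panel is the union of donor keys, so recurrent germline sites enter
#' the panel with high probability. `complete = TRUE` returns the whole
#' pool as the panel (full coverage of the cohort's germline background).
#'
#' @param pool a germline pool from [make_germline_pool()].
#' @param n_donors number of healthy donors (>= 1).
#' @param donor_size germline variants per donor; defaults to half the
#'   pool.
#' @param seed RNG seed.
#' @param complete if `TRUE`, the panel contains every pool key.
#' @return an object of class `baseline_panel` with fields `keys`
#'   (character vector) and `n_donors`.
#' @export
generate_baseline_panel <- function(pool, n_donors = 30, donor_size = NULL,
                                    seed = 1, complete = FALSE) {
  stopifnot(is.data.frame(pool), "key" %in% names(pool))
  if (!is_count(n_donors) || n_donors < 1) stopf("n_donors must be >= 1")
  if (complete) {
    return(baseline_panel(pool$key, n_donors))
  }
  if (is.null(donor_size)) donor_size <- max(1L, nrow(pool) %/% 2L)
  donor_size <- min(donor_size, nrow(pool))
  keys <- with_seed(seed, {
    unique(unlist(lapply(seq_len(n_donors), function(d) {
      pool$key[sample.int(nrow(pool), donor_size)]
    })))
  })
  baseline_panel(keys, n_donors)
}

#' Construct a baseline panel from variant keys
#'
#' @param keys character vector of canonical variant keys (deduplicated).
#' @param n_donors number of donors the panel was pooled from.
#' @return an object of class `baseline_panel`.
#' @export
baseline_panel <- function(keys, n_donors = 1) {
  if (!is_count(n_donors) || n_donors < 1) stopf("n_donors must be >= 1")
  structure(list(keys = unique(as.character(keys)),
                 n_donors = as.integer(n_donors)),
            class = "baseline_panel")
}

#' @export
print.baseline_panel <- function(x, ...) {
  cat(sprintf("<baseline_panel> %d key(s) pooled from %d donor(s)\n",
              length(x$keys), x$n_donors))
  invisible(x)
}

#' Generate QC metrics landing in a requested category
#'
#' Draws the four sequencing-QC metrics from bands chosen so that scoring
#' with the given thresholds produces a cumulative score in the requested
#' category (good 6-8, intermediate 3-5, poor 0-2).
#'
#' @param tier `"good"`, `"intermediate"`, or `"poor"`.
#' @param seed RNG seed.
#' @param thresholds a [qc_thresholds()] object.
#' @return named list of the four metric values.
#' @export
generate_qc_metrics <- function(tier = c("good", "intermediate", "poor"),
                                seed = 1, thresholds = qc_thresholds()) {
  tier <- match.arg(tier)
  lo_hi <- switch(tier, good = c(6, 8), intermediate = c(3, 5), poor = c(0, 2))
  combos <- expand.grid(0:2, 0:2, 0:2, 0:2)
  combos <- combos[rowSums(combos) >= lo_hi[1] & rowSums(combos) <= lo_hi[2], ]
  with_seed(seed, {
    per <- as.integer(combos[sample.int(nrow(combos), 1), ])
    out <- lapply(seq_along(QC_METRICS), function(j) {
      draw_metric_in_band(QC_METRICS[j], per[j], thresholds)
    })
    names(out) <- QC_METRICS
    out
  })
}

# Draw a metric value strictly inside the band that scores `score`.
draw_metric_in_band <- function(metric, score, thresholds) {
  t <- thresholds[[metric]]
  c1 <- t$cuts[1]; c2 <- t$cuts[2]
  hi_cap <- if (is.finite(t$range[2])) t$range[2] else 2 * c2
  eps <- 1e-3
  band <- if (t$higher_is_better) {
    switch(score + 1L,
           c(t$range[1], c1 - eps),
           c(c1, c2 - eps),
           c(c2, hi_cap))
  } else {
    switch(score + 1L,
           c(c1 + eps, t$range[2]),
           c(c2 + eps, c1),
           c(t$range[1], c2))
  }
  stats::runif(1, band[1], band[2])
}
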