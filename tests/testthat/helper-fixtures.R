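# Shared fixtures: naive oracles and random-callset generators, kept
# deliberately independent of the package's vectorised implementations.

# Random callset spanning the filter boundaries: qual/depth near the
# cut-points, VAF across all bands, mixed consequences, AF annotations
# present/absent, and a share of keys planted in `panel_keys`.
random_callset <- function(n, seed, panel_keys = character(),
                           source = "tumor", planted_frac = 0.2) {
  set.seed(seed)
  chrom <- paste0("chr", sample(1:5, n, replace = TRUE))
  pos <- sample.int(1e6, n)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  r <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    qual = sample(c(0, 5, 9.99, 10, 10.01, 35, 80), n, replace = TRUE),
    depth = sample(c(5L, 29L, 30L, 31L, 100L, 400L), n, replace = TRUE),
    vaf = sample(c(0.01, 0.05, 0.0501, 0.2, 0.449, 0.45, 0.5, 0.55, 0.551,
                   0.7, 0.95, 1.0), n, replace = TRUE),
    consequence = sample(c("coding_nonsynonymous", "coding_synonymous",
                           "noncoding"), n, replace = TRUE,
                         prob = c(0.7, 0.15, 0.15)),
    af_global = sample(c(NA, 0.001, 0.01, 0.0101, 0.2), n, replace = TRUE),
    af_sas = sample(c(NA, 0.005, 0.03), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  cs <- callset(sprintf("R%d", seed), r, source)
  if (length(panel_keys) > 0 && n > 0) {
    # overwrite some rows so their keys land in the panel
    k <- variant_key(cs)
    take <- which(runif(n) < planted_frac)
    if (length(take) > 0) {
      planted <- sample(panel_keys, length(take), replace = TRUE)
      parts <- strsplit(planted, ":", fixed = TRUE)
      cs$records$chrom[take] <- vapply(parts, `[`, character(1), 1)
      cs$records$pos[take] <- as.integer(vapply(parts, `[`, character(1), 2))
      cs$records$ref[take] <- vapply(parts, `[`, character(1), 3)
      cs$records$alt[take] <- vapply(parts, `[`, character(1), 4)
      cs <- callset(cs$sample_id, cs$records, source)
    }
  }
  cs
}

random_panel <- function(n, seed) {
  set.seed(seed)
  baseline_panel(
    paste0("chr", sample(1:5, n, replace = TRUE), ":",
           sample.int(1e6, n), ":A:G"),
    n_donors = 5
  )
}

# Naive per-record retain predicate: the full tumor-only filter evaluated
# one record at a time, straight from the filtering rules.
oracle_retain <- function(rec, panel_keys, cfg = filter_config()) {
  if (rec$qual < cfg$min_qual) return(FALSE)
  if (rec$depth < cfg$min_depth) return(FALSE)
  if (cfg$drop_synonymous && rec$consequence == "coding_synonymous") return(FALSE)
  if (cfg$drop_noncoding && rec$consequence == "noncoding") return(FALSE)
  for (af in c(rec$af_global, rec$af_sas)) {
    if (!is.na(af) && af > cfg$max_pop_af) return(FALSE)
  }
  if (rec$vaf <= cfg$low_vaf_cut) return(FALSE)
  if (rec$vaf >= cfg$germ_het_band[1] && rec$vaf <= cfg$germ_het_band[2]) {
    return(FALSE)
  }
  if (!is.null(cfg$hom_vaf_cut) && rec$vaf >= cfg$hom_vaf_cut) return(FALSE)
  key <- variant_key(rec)
  if (key %in% panel_keys) return(FALSE)
  TRUE
}

oracle_tumor_only <- function(cs, panel, cfg = filter_config()) {
  keep <- vapply(seq_len(nrow(cs$records)), function(i) {
    oracle_retain(cs$records[i, , drop = FALSE], panel$keys, cfg)
  }, logical(1))
  cs$records[keep, , drop = FALSE]
}

# Naive allele normalization: enumerate every possible trim of the shared
# suffix then shared prefix, one character at a time.
oracle_trim <- function(pos, ref, alt) {
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 1 && na > 1 && substr(ref, nr, nr) == substr(alt, na, na)) {
      ref <- substr(ref, 1, nr - 1); alt <- substr(alt, 1, na - 1)
    } else break
  }
  repeat {
    if (nchar(ref) > 1 && nchar(alt) > 1 &&
        substr(ref, 1, 1) == substr(alt, 1, 1)) {
      ref <- substring(ref, 2); alt <- substring(alt, 2); pos <- pos + 1
    } else break
  }
  list(pos = pos, ref = ref, alt = alt)
}

# independent per-sample seed derivation for test samplers
derive_seed_for_test <- function(seed, i) (seed * 131 + i * 7919) %% 2000000011

make_record <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                        qual = 50, depth = 100L, vaf = 0.3,
                        consequence = "coding_nonsynonymous",
                        af_global = NA_real_, af_sas = NA_real_) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, qual = qual,
             depth = depth, vaf = vaf, consequence = consequence,
             af_global = af_global, af_sas = af_sas,
             stringsAsFactors = FALSE)
}

one_record_callset <- function(..., source = "tumor", sample_id = "T1") {
  callset(sample_id, make_record(...), source)
}
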