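# Variant and sample containers plus VCF/TSV I/O.
#
# A call set is stored as a plain data.frame of per-variant records; every
# downstream filter is a vectorised predicate over its columns. Population
# allele frequencies live in columns named "af_<label>" (NA = not observed
# in that database), so additional databases extend the schema without code
# changes.

CONSEQUENCE_LEVELS <- c("coding_nonsynonymous", "coding_synonymous", "noncoding")

record_columns <- c(
  "chrom", "pos", "ref", "alt", "qual", "depth", "vaf", "consequence"
)

#' Construct a sample call set
#'
#' Bundles a sample identifier, a source label, and a data.frame of variant
#' records. Records are validated and sorted by (chrom, pos).
#'
#' Required record columns: `chrom` (character), `pos` (1-based integer),
#' `ref`, `alt` (single alternate allele per row; multi-allelic sites must
#' already be split), `qual` (Phred-like, >= 0), `depth` (integer >= 0),
#' `vaf` (in \[0, 1\]), `consequence` (one of `coding_nonsynonymous`,
#' `coding_synonymous`, `noncoding`). Optional columns `af_global`,
#' `af_sas`, or any other `af_*` column carry population allele frequencies
#' in \[0, 1\], with `NA` meaning the variant is not observed in that
#' database.
#'
#' @param sample_id non-empty sample identifier.
#' @param records data.frame of variant records (may have zero rows).
#' @param source `"tumor"` or `"normal"`.
#' @return an object of class `callset`.
#' @examples
#' recs <- data.frame(
#'   chrom = "chr1", pos = 100L, ref = "A", alt = "G",
#'   qual = 50, depth = 120L, vaf = 0.32,
#'   consequence = "coding_nonsynonymous", af_global = NA_real_
#' )
#' callset("S1", recs, "tumor")
#' @export
callset <- function(sample_id, records, source = c("tumor", "normal")) {
  source <- match.arg(source)
  if (!is.character(sample_id) || length(sample_id) != 1 || !nzchar(sample_id)) {
    stopf("sample_id must be a non-empty string")
  }
  if (!is.data.frame(records)) stopf("records must be a data.frame")
  if (nrow(records) == 0 && !all(record_columns %in% names(records))) {
    records <- empty_records()
  }
  missing_cols <- setdiff(record_columns, names(records))
  if (length(missing_cols) > 0) {
    stopf("records is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  records$chrom <- as.character(records$chrom)
  records$pos <- as.integer(records$pos)
  records$ref <- as.character(records$ref)
  records$alt <- as.character(records$alt)
  records$depth <- as.integer(records$depth)
  validate_records(records, sample_id)
  if (nrow(records) > 1) {
    records <- records[order(records$chrom, records$pos), , drop = FALSE]
    rownames(records) <- NULL
  }
  structure(
    list(sample_id = sample_id, records = records, source = source),
    class = "callset"
  )
}

empty_records <- function() {
  data.frame(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    qual = numeric(), depth = integer(), vaf = numeric(),
    consequence = character(),
    af_global = numeric(), af_sas = numeric(),
    stringsAsFactors = FALSE
  )
}

validate_records <- function(records, sample_id) {
  n <- nrow(records)
  if (n == 0) return(invisible(TRUE))
  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE) || anyNA(cond)) {
      stopf("sample %s: invalid records (%s)", sample_id, what)
    }
  }
  bad(records$pos < 1, "pos must be >= 1")
  bad(records$qual < 0, "qual must be >= 0")
  bad(records$depth < 0, "depth must be >= 0")
  bad(records$vaf < 0 | records$vaf > 1, "vaf must be in [0, 1]")
  bad(!records$consequence %in% CONSEQUENCE_LEVELS,
      paste("consequence must be one of", paste(CONSEQUENCE_LEVELS, collapse = "/")))
  bad(grepl(",", records$alt, fixed = TRUE),
      "one alternate allele per record; split multi-allelic sites first")
  invisible(TRUE)
}

af_columns <- function(records) grep("^af_", names(records), value = TRUE)

#' @export
print.callset <- function(x, ...) {
  cat(sprintf(
    "<callset> sample %s (%s): %d record(s)\n",
    x$sample_id, x$source, nrow(x$records)
  ))
  if (nrow(x$records) > 0) {
    print(utils::head(x$records, 6))
    if (nrow(x$records) > 6) cat(sprintf("... %d more\n", nrow(x$records) - 6))
  }
  invisible(x)
}

#' Canonical variant keys
#'
#' Maps each record to a canonical `chrom:pos:ref:alt` string after allele
#' normalization (shared-suffix then shared-prefix trimming, keeping at
#' least one base of each allele and advancing `pos` for every trimmed
#' prefix base), so equivalent indel spellings compare equal. Keys are the
#' identity used for matched-normal subtraction and baseline-panel
#' membership.
#'
#' @param x a `callset`, or a data.frame of records with columns
#'   `chrom`, `pos`, `ref`, `alt`.
#' @return character vector of keys, one per record.
#' @examples
#' variant_key(data.frame(chrom = "chr1", pos = 100, ref = "ATT", alt = "AT"))
#' # same key as (chr1, 100, AT, A)
#' @export
variant_key <- function(x) {
  records <- if (inherits(x, "callset")) x$records else x
  if (nrow(records) == 0) return(character())
  norm <- normalize_alleles(records$pos, records$ref, records$alt)
  paste(records$chrom, norm$pos, norm$ref, norm$alt, sep = ":")
}

# Trim shared suffix then shared prefix from ref/alt pairs, keeping >= 1
# base each; prefix trimming advances pos. SNVs (the bulk) short-circuit.
normalize_alleles <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  needs <- nchar(ref) > 1 & nchar(alt) > 1
  idx <- which(needs)
  for (i in idx) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1)
      a <- substr(a, 1, nchar(a) - 1)
    }
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r))
      a <- substr(a, 2, nchar(a))
      p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Read a VCF file into a call set
#'
#' Parses a VCF 4.2 file via \pkg{vcfR}. Each data line yields one record
#' per alternate allele (multi-allelic lines are split, with allele-specific
#' `AF` values). The variant allele fraction is taken from the per-allele
#' FORMAT `AF` field when present, otherwise computed as allele depth over
#' site depth from `AD`/`DP`. Consequence class is read from the INFO
#' `CSQCLASS` field; population frequencies from INFO `AF_GLOBAL` and
#' `AF_SAS` (absent annotations become `NA`).
#'
#' @param path path to a VCF file.
#' @param source `"tumor"` or `"normal"`.
#' @param sample_id sample identifier; defaults to the VCF genotype column
#'   name.
#' @return a `callset`.
#' @export
read_vcf <- function(path, source = c("tumor", "normal"), sample_id = NULL) {
  source <- match.arg(source)
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- v@gt
  vcf_sample <- if (!is.null(gt) && ncol(gt) >= 2) colnames(gt)[2] else NA_character_
  if (is.null(sample_id)) {
    sample_id <- if (!is.na(vcf_sample)) vcf_sample else {
      sub("\\.vcf(\\.gz)?$", "", basename(path))
    }
  }
  n <- nrow(fix)
  if (n == 0) return(callset(sample_id, empty_records(), source))

  info <- fix[, "INFO"]
  fmt_keys <- if (!is.null(gt)) strsplit(gt[, 1], ":", fixed = TRUE) else rep(list(character()), n)
  fmt_vals <- if (!is.null(gt) && ncol(gt) >= 2) {
    strsplit(gt[, 2], ":", fixed = TRUE)
  } else {
    rep(list(character()), n)
  }
  fmt_field <- function(i, key) {
    j <- match(key, fmt_keys[[i]])
    if (is.na(j) || j > length(fmt_vals[[i]])) NA_character_ else fmt_vals[[i]][j]
  }
  info_field <- function(i, key) {
    m <- regmatches(info[i], regexec(paste0("(?:^|;)", key, "=([^;]*)"), info[i]))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  num_or_stop <- function(x, what, i) {
    out <- suppressWarnings(as.numeric(x))
    if (any(is.na(out) & !is.na(x))) {
      stopf("sample %s: unparseable %s at VCF record %d", sample_id, what, i)
    }
    out
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    k <- length(alts)
    dp_raw <- fmt_field(i, "DP")
    af_raw <- fmt_field(i, "AF")
    ad_raw <- fmt_field(i, "AD")
    if (is.na(dp_raw) && is.na(ad_raw)) {
      stopf("sample %s: VCF record %d has neither FORMAT DP nor AD", sample_id, i)
    }
    ad <- if (!is.na(ad_raw)) {
      num_or_stop(strsplit(ad_raw, ",", fixed = TRUE)[[1]], "AD", i)
    } else NULL
    depth <- if (!is.na(dp_raw)) {
      num_or_stop(dp_raw, "DP", i)
    } else {
      sum(ad)
    }
    vaf <- if (!is.na(af_raw)) {
      afs <- num_or_stop(strsplit(af_raw, ",", fixed = TRUE)[[1]], "FORMAT AF", i)
      if (length(afs) != k) {
        stopf("sample %s: VCF record %d has %d AF value(s) for %d alt allele(s)",
              sample_id, i, length(afs), k)
      }
      afs
    } else if (!is.null(ad) && length(ad) >= k + 1) {
      if (depth <= 0) rep(0, k) else ad[-1][seq_len(k)] / depth
    } else {
      stopf("sample %s: VCF record %d has no FORMAT AF and unusable AD", sample_id, i)
    }
    csq <- info_field(i, "CSQCLASS")
    if (is.na(csq)) {
      stopf("sample %s: VCF record %d lacks required INFO CSQCLASS", sample_id, i)
    }
    rows[[i]] <- data.frame(
      chrom = fix[i, "CHROM"],
      pos = as.integer(fix[i, "POS"]),
      ref = fix[i, "REF"],
      alt = alts,
      qual = num_or_stop(fix[i, "QUAL"], "QUAL", i),
      depth = as.integer(round(depth)),
      vaf = pmin(pmax(vaf, 0), 1),
      consequence = csq,
      af_global = num_or_stop(info_field(i, "AF_GLOBAL"), "AF_GLOBAL", i),
      af_sas = num_or_stop(info_field(i, "AF_SAS"), "AF_SAS", i),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  callset(sample_id, do.call(rbind, rows), source)
}

#' Write a call set as a plain-text VCF 4.2 file
#'
#' Emits one data line per record with INFO `CSQCLASS`, `AF_GLOBAL`,
#' `AF_SAS` and FORMAT `DP:AF`, the schema [read_vcf()] consumes. Reals are
#' written to 6 significant digits, so a write/read round trip preserves
#' qual, depth, VAF and population frequencies to that precision.
#'
#' @param cs a `callset`.
#' @param path output path.
#' @param meta optional character vector of extra `##`-prefixed header
#'   lines (provenance stamps).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cs, path, meta = NULL) {
  stopifnot(inherits(cs, "callset"))
  r <- cs$records
  fmt_num <- function(x) {
    vapply(x, function(v) {
      if (is.na(v)) NA_character_
      else format(signif(v, 6), scientific = FALSE, trim = TRUE, digits = 15)
    }, character(1))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=tmbflow %s", as.character(utils::packageVersion("tmbflow"))),
    if (!is.null(meta)) paste0("##", meta),
    "##INFO=<ID=CSQCLASS,Number=1,Type=String,Description=\"Collapsed consequence class\">",
    "##INFO=<ID=AF_GLOBAL,Number=1,Type=Float,Description=\"Global population allele frequency\">",
    "##INFO=<ID=AF_SAS,Number=1,Type=Float,Description=\"South Asian population allele frequency\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth at site\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Variant allele fraction\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", cs$sample_id, sep = "\t")
  )
  body <- character(0)
  if (nrow(r) > 0) {
    info <- paste0("CSQCLASS=", r$consequence)
    for (col in af_columns(r)) {
      tag <- toupper(col)
      has <- !is.na(r[[col]])
      info[has] <- paste0(info[has], ";", tag, "=", fmt_num(r[[col]][has]))
    }
    body <- paste(
      r$chrom, r$pos, ".", r$ref, r$alt, fmt_num(r$qual), "PASS", info,
      "DP:AF", paste0(r$depth, ":", fmt_num(r$vaf)),
      sep = "\t"
    )
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a table as TSV
#'
#' Tab-separated, UTF-8, header row, `NA` rendered as `"."`. Optional
#' `comment` lines are prefixed with `#` above the header; [read_tsv()]
#' skips them.
#'
#' @param rows a data.frame.
#' @param path output path.
#' @param comment optional character vector of provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(rows, path, comment = NULL) {
  stopifnot(is.data.frame(rows))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path input path.
#' @return a data.frame; `"."` fields become `NA`.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stopf("TSV file not found: %s", path)
  utils::read.delim(path, sep = "\t", na.strings = ".", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
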