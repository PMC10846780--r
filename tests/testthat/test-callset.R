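# Variant containers, key normalization, and VCF/TSV round trips.

vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##INFO=<ID=CSQCLASS,Number=1,Type=String,Description=\"class\">",
  "##INFO=<ID=AF_GLOBAL,Number=1,Type=Float,Description=\"gaf\">",
  "##INFO=<ID=AF_SAS,Number=1,Type=Float,Description=\"saf\">",
  "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
  "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"af\">",
  "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
  paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
        "FORMAT", "S1", sep = "\t")
)

write_vcf_lines <- function(body) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c(vcf_header, body), path)
  path
}

test_that("read_vcf passes fields through and derives VAF from AD when AF is absent", {
  path <- write_vcf_lines(c(
    "chr1\t100\t.\tA\tG\t50\tPASS\tCSQCLASS=coding_nonsynonymous;AF_GLOBAL=0.02\tDP:AF\t120:0.32",
    "chr2\t200\t.\tT\tC\t17.5\tPASS\tCSQCLASS=coding_synonymous\tDP:AD\t100:75,25"
  ))
  cs <- read_vcf(path, "tumor")
  expect_s3_class(cs, "callset")
  expect_equal(cs$sample_id, "S1")
  expect_equal(nrow(cs$records), 2)
  r1 <- cs$records[cs$records$chrom == "chr1", ]
  expect_equal(r1$depth, 120L)
  expect_equal(r1$vaf, 0.32)
  expect_equal(r1$qual, 50)
  expect_equal(r1$af_global, 0.02)
  expect_true(is.na(r1$af_sas))
  r2 <- cs$records[cs$records$chrom == "chr2", ]
  expect_equal(r2$vaf, 0.25)  # AD alt / DP
  expect_equal(r2$consequence, "coding_synonymous")
})

test_that("multi-allelic lines split into one record per alt with allele-specific VAF", {
  path <- write_vcf_lines(
    "chr1\t100\t.\tA\tG,T\t60\tPASS\tCSQCLASS=coding_nonsynonymous\tDP:AF\t200:0.30,0.10"
  )
  cs <- read_vcf(path, "tumor")
  expect_equal(nrow(cs$records), 2)
  expect_equal(cs$records$alt, c("G", "T"))
  expect_equal(cs$records$vaf, c(0.30, 0.10))
  expect_equal(cs$records$depth, c(200L, 200L))
})

test_that("a header-only VCF yields an empty callset", {
  path <- write_vcf_lines(character(0))
  cs <- read_vcf(path, "normal")
  expect_equal(nrow(cs$records), 0)
  expect_equal(cs$source, "normal")
})

test_that("read_vcf fails hard on missing depth fields or bad annotations", {
  no_depth <- write_vcf_lines(
    "chr1\t100\t.\tA\tG\t50\tPASS\tCSQCLASS=coding_nonsynonymous\tGT\t0/1"
  )
  expect_error(read_vcf(no_depth, "tumor"), "neither FORMAT DP nor AD")
  bad_af <- write_vcf_lines(
    "chr1\t100\t.\tA\tG\t50\tPASS\tCSQCLASS=coding_nonsynonymous;AF_GLOBAL=oops\tDP:AF\t100:0.2"
  )
  expect_error(read_vcf(bad_af, "tumor"), "AF_GLOBAL")
  no_csq <- write_vcf_lines(
    "chr1\t100\t.\tA\tG\t50\tPASS\tAF_GLOBAL=0.2\tDP:AF\t100:0.2"
  )
  expect_error(read_vcf(no_csq, "tumor"), "CSQCLASS")
})

test_that("equivalent indel spellings map to one key; distinct variants do not", {
  k1 <- variant_key(make_record(pos = 100L, ref = "AT", alt = "A"))
  k2 <- variant_key(make_record(pos = 100L, ref = "ATT", alt = "AT"))
  expect_identical(k1, k2)
  expect_identical(
    variant_key(make_record()),
    variant_key(make_record())
  )
  expect_false(variant_key(make_record(alt = "G")) ==
                 variant_key(make_record(alt = "C")))
})

test_that("key normalization matches the exhaustive trim oracle on enumerated allele pairs", {
  bases <- c("A", "C", "G", "T")
  set.seed(42)
  for (i in 1:200) {
    ref <- paste(sample(bases, sample(1:4, 1), replace = TRUE), collapse = "")
    alt <- paste(sample(bases, sample(1:4, 1), replace = TRUE), collapse = "")
    pos <- sample.int(1000, 1)
    expected <- oracle_trim(pos, ref, alt)
    got <- variant_key(make_record(pos = pos, ref = ref, alt = alt))
    expect_identical(
      got,
      paste("chr1", expected$pos, expected$ref, expected$alt, sep = ":"),
      info = sprintf("pos=%d ref=%s alt=%s", pos, ref, alt)
    )
  }
})

test_that("VCF write/read round trip preserves records to 6 significant digits", {
  pair <- generate_matched_pair(
    sim_params(true_tmb = 4, n_germline_het = 150, n_germline_hom = 60,
               n_other = 40, n_noise = 20, seed = 9)
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(pair$tumor, path)
  back <- read_vcf(path, "tumor")
  a <- pair$tumor$records
  b <- back$records
  expect_equal(nrow(a), nrow(b))
  expect_identical(variant_key(a), variant_key(b))
  expect_identical(a$consequence, b$consequence)
  expect_equal(a$depth, b$depth)
  expect_equal(a$vaf, b$vaf, tolerance = 1e-5)
  expect_equal(a$qual, b$qual, tolerance = 1e-5)
  expect_identical(is.na(a$af_global), is.na(b$af_global))
  expect_equal(a$af_global, b$af_global, tolerance = 1e-5)
  expect_equal(a$af_sas, b$af_sas, tolerance = 1e-5)
})

test_that("splitting multi-allelics conserves the number of (site, alt) pairs", {
  body <- c(
    "chr1\t10\t.\tA\tG\t50\tPASS\tCSQCLASS=coding_nonsynonymous\tDP:AF\t100:0.2",
    "chr1\t20\t.\tC\tA,G,T\t50\tPASS\tCSQCLASS=coding_nonsynonymous\tDP:AF\t100:0.1,0.1,0.1",
    "chr2\t30\t.\tT\tC,G\t50\tPASS\tCSQCLASS=noncoding\tDP:AF\t100:0.3,0.2"
  )
  path <- write_vcf_lines(body)
  cs <- read_vcf(path, "tumor")
  n_pairs <- sum(lengths(strsplit(vapply(strsplit(body, "\t"), `[`,
                                         character(1), 5), ",")))
  expect_equal(nrow(cs$records), n_pairs)
})

test_that("callset rejects malformed records and multi-allelic alts", {
  expect_error(callset("", make_record(), "tumor"), "sample_id")
  expect_error(callset("S", make_record(vaf = 1.2), "tumor"), "vaf")
  expect_error(callset("S", make_record(pos = 0L), "tumor"), "pos")
  expect_error(callset("S", make_record(alt = "G,T"), "tumor"),
               "multi-allelic")
  expect_error(callset("S", make_record(consequence = "missense"), "tumor"),
               "consequence")
})

test_that("TSV tables round trip with '.' for missing values", {
  t <- data.frame(
    sample_id = c("A", "B"), cancer_type = c("lung", NA),
    tmb = c(7.58, 0.123456), n = c(10L, 3L), stringsAsFactors = FALSE
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(t, path, comment = "provenance line")
  lines <- readLines(path)
  expect_match(lines[1], "^# provenance")
  expect_match(lines[3], "\t7.58\t", fixed = TRUE)
  expect_match(lines[4], "\\.\t")
  back <- read_tsv(path)
  expect_equal(back$sample_id, t$sample_id)
  expect_true(is.na(back$cancer_type[2]))
  expect_equal(back$tmb, t$tmb, tolerance = 1e-6)
  expect_equal(back$n, t$n)

  empty <- data.frame(x = character(), y = numeric())
  write_tsv(empty, path)
  expect_equal(nrow(read_tsv(path)), 0)
  expect_equal(length(readLines(path)), 1)  # header only
})
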