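test_that("VCF round trip preserves calls and converts coordinates", {
  # single record at 1-based position 100 lands at internal pos 99
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "s", sep = "\t"),
               "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/1"), path)
  cs <- read_variant_calls(path, "vcf", platform_id = "p1")
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$pos, 99L)
  expect_equal(cs$genotype, "het")
  expect_equal(cs$kind, "substitution")

  # 50-call synthetic callset round-trips identically, field by field
  set.seed(11)
  n <- 50L
  pos <- sort(sample.int(100000L, n)) - 1L
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  cs <- callset(rep("chr1", n), pos, ref, alt,
                sample(c("hom", "het"), n, TRUE), round(runif(n, 1, 99), 1),
                platform_id = "px")
  for (dialect in c("vcf", "tsv")) {
    f <- tempfile(fileext = paste0(".", dialect))
    write_variant_calls(cs, f, dialect)
    back <- read_variant_calls(f, dialect, platform_id = "px")
    expect_equal(as.data.frame(back), as.data.frame(cs))
  }
})

test_that("empty and unsorted VCF inputs are handled", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "s", sep = "\t")), path)
  expect_equal(nrow(read_variant_calls(path, "vcf")), 0L)

  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "s", sep = "\t"),
               "chr1\t200\t.\tA\tG\t50\tPASS\t.\tGT\t0/1",
               "chr1\t100\t.\tT\tC\t50\tPASS\t.\tGT\t1/1"), path)
  expect_message(cs <- read_variant_calls(path, "vcf"), "re-sorting")
  expect_equal(cs$pos, c(99L, 199L))
})

test_that("malformed TSV records are reported with a line number", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tgenotype\tqual",
               "chr1\t100\tA\tG\thet\t50",
               "chr1\tnope\tT\tC\thom\t50"), path)
  expect_error(read_variant_calls(path, "tsv"), "line 3")
})

test_that("callset invariants are enforced", {
  expect_error(callset("chr1", -1L, "A", "G", "het", 10), "negative")
  expect_error(callset("chr1", 5L, "A", "A", "het", 10), "differ")
  expect_error(callset(c("chr1", "chr1"), c(5L, 5L), c("A", "A"),
                       c("G", "C"), c("het", "het"), c(10, 10)), "duplicated")
  expect_error(callset("chr1", 5L, "A", "G", "het", -2), "quality")
})

test_that("BED round trip is the identity and follows the BED convention", {
  f <- tempfile(fileext = ".bed")
  write_bed(intervals(), f)
  expect_equal(nrow(read_bed(f)), 0L)

  write_bed(intervals("chr1", 0L, 100L), f)
  expect_equal(strsplit(readLines(f)[1], "\t")[[1]][1:3],
               c("chr1", "0", "100"))

  iv <- random_intervals(1000L, seed = 3)
  write_bed(iv, f)
  back <- read_bed(f)
  o <- order(iv$chrom, iv$start, iv$end)
  ob <- order(back$chrom, back$start, back$end)
  expect_equal(back[ob, ], iv[o, ], ignore_attr = TRUE)

  expect_error(intervals("chr1", -5L, 10L), "negative")
})

test_that("evidence tables round trip through TSV", {
  ev <- evidence_table(rep("chr1", 3), c(10L, 20L, 30L), c(5L, 0L, 12L),
                       c(2L, 0L, 12L), c(60, NA, 25), c(80, NA, 19),
                       c(0L, 1L, 4L), c(NA, 2L, NA), c(TRUE, TRUE, FALSE))
  f <- tempfile(fileext = ".tsv")
  write_evidence(ev, f)
  expect_equal(as.data.frame(read_evidence(f)), as.data.frame(ev))
})

test_that("default configuration carries the standard thresholds", {
  cfg <- load_config(NULL)
  expect_equal(cfg$platforms$illumina$max_depth_autosome, 60L)
  expect_equal(cfg$platforms$illumina$min_depth, 4L)
  expect_equal(cfg$platforms$illumina$min_qual, 20)
  expect_equal(cfg$platforms$illumina$max_depth_sex, 45L)
  expect_equal(cfg$platforms$illumina$max_depth_mito, 10000L)
  expect_equal(cfg$platforms$`454`$min_depth, 2L)
  expect_equal(cfg$platforms$`454`$max_depth_autosome, 30L)
  expect_true(is.na(cfg$platforms$`454`$min_qual))
  expect_equal(cfg$platforms$solid$max_depth_autosome, 100L)
  expect_equal(cfg$gc_window_bp, 50000L)
  expect_equal(cfg$indel_slop_bp, 10L)
})

test_that("config overrides apply and unknown keys are rejected", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(indel_slop_bp = 0L,
                        platforms = list(illumina = list(min_qual = 30))), f)
  cfg <- load_config(f)
  expect_equal(cfg$indel_slop_bp, 0L)
  expect_equal(cfg$platforms$illumina$min_qual, 30)
  expect_equal(cfg$platforms$illumina$max_depth_autosome, 60L)

  yaml::write_yaml(list(bogus_key = 1), f)
  expect_error(load_config(f), "valid keys")
  yaml::write_yaml(list(platforms = list(illumina = list(bogus = 1))), f)
  expect_error(load_config(f), "valid keys")
})

test_that("chromosome classes come from configuration, not name heuristics", {
  cfg <- analysis_config(chrom_classes = c(scaffold_7 = "sex", mt = "mito"))
  expect_equal(chrom_class(c("mt", "scaffold_7"), cfg), c("mito", "sex"))
  expect_error(chrom_class("chrUnknown", cfg), "chrUnknown")
})
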