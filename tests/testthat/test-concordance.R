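mk_sites <- function(pos, id) {
  n <- length(pos)
  callset(rep("chr1", n), sort(pos), rep("A", n), rep("G", n),
          rep("het", n), rep(50, n), platform_id = id)
}

test_that("venn partition assigns sites to exactly-who-called-it cells", {
  a <- mk_sites(c(1L, 2L), "A"); b <- mk_sites(c(2L, 3L), "B")
  c_ <- mk_sites(2L, "C")
  part <- venn_partition(list(a, b, c_))
  cells <- venn_cell_sizes(part)
  expect_equal(unname(cells[c("A", "B", "C", "A+B", "A+C", "B+C", "A+B+C")]),
               c(1L, 1L, 0L, 0L, 0L, 0L, 1L))

  p3 <- venn_partition(list(mk_sites(5L, "A"), mk_sites(5L, "B"),
                            mk_sites(5L, "C")))
  expect_equal(unname(venn_cell_sizes(p3)["A+B+C"]), 1L)
  expect_equal(sum(venn_cell_sizes(p3)), 1L)

  expect_error(venn_partition(list(a, mk_sites(1L, "A"))), "duplicate")
})

test_that("venn cells equal brute-force membership enumeration", {
  set.seed(61)
  sets <- lapply(c("A", "B", "C"), function(id)
    mk_sites(sample.int(3000L, 1000L) - 1L, id))
  part <- venn_partition(sets)
  cells <- venn_cell_sizes(part)
  # oracle: per-position membership flags
  all_pos <- sort(unique(unlist(lapply(sets, function(s) s$pos))))
  member <- vapply(sets, function(s) all_pos %in% s$pos, logical(length(all_pos)))
  key <- apply(member, 1, function(m) paste(c("A", "B", "C")[m], collapse = "+"))
  oracle <- table(key)
  expect_equal(cells[names(oracle)], unclass(oracle), ignore_attr = TRUE)
  # cells are disjoint and exhaustive: totals reproduce callset sizes
  tot <- aggregate_platform_totals(part)
  expect_equal(unname(tot$platform_totals), rep(1000, 3))
  expect_equal(tot$union, length(all_pos))
})

test_that("aggregation reproduces per-platform totals from disjoint cells", {
  cells <- c(`A+B+C` = 3401954, `A+B` = 439122, `A+C` = 47381,
             `B+C` = 624306, A = 442674, B = 225981, C = 71567)
  tot <- aggregate_platform_totals(cells)
  expect_equal(unname(tot$platform_totals["A"]), 4331131)
  expect_equal(unname(tot$platform_totals["B"]), 4691363)
  expect_equal(unname(tot$platform_totals["C"]), 4145208)
  expect_equal(tot$union, 5252985)
  expect_equal(tot$discordant, 1851031)

  expect_equal(aggregate_platform_totals(c(A = 7))$union, 7)
})

test_that("a shared location with differing alt alleles stays concordant but flagged", {
  a <- callset("chr1", 10L, "A", "G", "het", 50, platform_id = "A")
  b <- callset("chr1", 10L, "A", "T", "het", 50, platform_id = "B")
  part <- venn_partition(list(a, b))
  expect_equal(part$sites$cell, "A+B")
  expect_true(part$sites$allele_mismatch)
})

test_that("miss classification follows the documented precedence", {
  pcfg <- default_platform_configs()$illumina
  ev <- function(...) evidence_table("chr1", 0L, ...)
  expect_equal(classify_missed_site(ev(0L, 0L), pcfg), "NO_COVERAGE")
  expect_equal(classify_missed_site(ev(2L, 1L), pcfg), "LOW_COVERAGE")
  expect_equal(classify_missed_site(ev(90L, 45L), pcfg), "EXCESS_COVERAGE")
  expect_equal(classify_missed_site(ev(10L, 0L), pcfg), "ALT_NOT_SEEN")
  expect_equal(classify_missed_site(ev(10L, 1L), pcfg), "ALT_SEEN_ONCE")
  expect_equal(classify_missed_site(ev(10L, 5L, nearby_snp_count = 3L), pcfg),
               "SNP_CLUSTER")
  expect_equal(classify_missed_site(ev(10L, 5L, nearest_indel_distance = 3L),
                                    pcfg), "NEAR_INDEL")
  expect_equal(classify_missed_site(ev(10L, 5L, rms_mapq = 10), pcfg),
               "LOW_RMS_MAPQ")
  expect_equal(classify_missed_site(ev(10L, 5L, rms_mapq = 60, snp_qual = 10),
                                    pcfg), "LOW_SNP_QUAL")
  expect_equal(classify_missed_site(ev(10L, 5L, rms_mapq = 60, snp_qual = 80),
                                    pcfg), "UNEXPLAINED")
  # precedence: mapping quality beats SNP quality when both are low
  expect_equal(classify_missed_site(ev(30L, 6L, rms_mapq = 10, snp_qual = 50),
                                    pcfg), "LOW_RMS_MAPQ")
  # platforms without mapping quality use the uniqueness flag in slot 8
  p454 <- default_platform_configs()$`454`
  expect_equal(classify_missed_site(ev(10L, 5L, in_unique_region = FALSE),
                                    p454), "NON_UNIQUE")
  expect_equal(classify_missed_site(ev(10L, 5L, rms_mapq = 5), p454),
               "UNEXPLAINED")
  # classifier is total: every record gets exactly one known category
  set.seed(3)
  ev_many <- evidence_table(rep("chr1", 50), 1:50,
                            depth <- sample(0:80, 50, TRUE),
                            pmin(sample(0:5, 50, TRUE), depth),
                            sample(c(NA, 10, 60), 50, TRUE),
                            sample(c(NA, 10, 80), 50, TRUE),
                            sample(0:4, 50, TRUE),
                            sample(c(NA_integer_, 1L, 50L), 50, TRUE))
  cats <- classify_missed_sites(ev_many, pcfg)
  expect_length(cats, 50L)
  expect_true(all(cats %in% MISS_CATEGORIES))
  # permuting input order never changes any assignment
  perm <- sample(50)
  expect_equal(classify_missed_sites(ev_many[perm, ], pcfg), cats[perm])
})

test_that("category summaries count and normalize per comparison", {
  one <- data.frame(comparison = "A+B vs C", category = "NO_COVERAGE")
  s <- summarize_categories(one)
  expect_equal(s$fraction, 1)
  expect_equal(nrow(summarize_categories(one[0, , drop = FALSE])), 0L)

  cl <- data.frame(
    comparison = rep(c("A+B vs C", "A vs B"), c(4, 2)),
    category = c("NO_COVERAGE", "NO_COVERAGE", "ALT_NOT_SEEN", "LOW_SNP_QUAL",
                 "ALT_SEEN_ONCE", "ALT_SEEN_ONCE"))
  s <- summarize_categories(cl)
  expect_equal(sum(s$fraction[s$comparison == "A+B vs C"]), 1)
  expect_equal(s$count[s$comparison == "A vs B"], 2L)
})

test_that("false-positive estimation applies the excusing conditions per platform", {
  cfg <- analysis_config(chrom_classes = c(chr1 = "autosome"))
  pcfgs <- default_platform_configs()[c("454", "illumina")]
  singles <- data.frame(chrom = "chr1", pos = c(10L, 20L))
  # site 10: both others have zero coverage -> plausible true
  # site 20: both others in-bounds with alt 0 -> putative FP
  ev454 <- evidence_table("chr1", c(10L, 20L), c(0L, 10L), c(0L, 0L))
  evIll <- evidence_table("chr1", c(10L, 20L), c(0L, 30L), c(0L, 0L))
  est <- estimate_false_positives(singles, list(`454` = ev454, illumina = evIll),
                                  pcfgs, cfg)
  expect_equal(est$plausible_true, 1L)
  expect_equal(est$putative_fp, 1L)
  expect_equal(est$per_site, c(TRUE, FALSE))
  # alt seen once on every other platform also excuses
  ev454$alt_count <- c(1L, 1L); evIll$alt_count <- c(1L, 1L)
  est <- estimate_false_positives(singles, list(`454` = ev454, illumina = evIll),
                                  pcfgs, cfg)
  expect_equal(est$putative_fp, 0L)
  # bounds: 0 <= putative_fp <= singletons
  expect_error(estimate_false_positives(
    data.frame(chrom = "chr1", pos = 99L),
    list(`454` = ev454), pcfgs["454"], cfg), "evidence")
})

test_that("indel matching distinguishes exact, slop-only and unmatched", {
  a <- intervals("chr1", 100L, 105L)
  expect_equal(indel_overlap(a, a, 10L)$n_exact, 1L)

  b <- intervals("chr1", 112L, 113L)
  ov <- indel_overlap(a, b, 10L)                 # gap 7 <= 10
  expect_equal(ov$n_slop_only, 1L)
  expect_equal(ov$matches$gap, 7L)

  far <- intervals("chr1", 155L, 156L)           # 50 bp away
  expect_equal(indel_overlap(a, far, 10L)$n_unmatched, 1L)

  # slop 0 leaves no slop-only matches
  ov <- indel_overlap(a, b, 0L)
  expect_equal(ov$n_slop_only, 0L)
  expect_equal(ov$n_unmatched, 1L)

  # nearest wins; leftmost on tie
  a <- intervals("chr1", 100L, 101L)
  b <- intervals(c("chr1", "chr1"), c(95L, 105L), c(96L, 106L))
  ov <- indel_overlap(a, b, 10L)
  expect_equal(ov$matches$b_index, 1L)

  # identical sets are symmetric in counts
  set.seed(71)
  iv <- random_intervals(50, seed = 72, chroms = "chr1")
  expect_equal(indel_overlap(iv, iv, 10L)$n_exact, 50L)
})

test_that("indel matching equals a brute-force oracle on large fixtures", {
  set.seed(81)
  a <- random_intervals(1000, seed = 82, chroms = c("chr1", "chr2"),
                        max_pos = 100000L)
  b <- random_intervals(1000, seed = 83, chroms = c("chr1", "chr2"),
                        max_pos = 100000L)
  slop <- 10L
  ov <- indel_overlap(a, b, slop)
  oracle_type <- vapply(seq_len(nrow(a)), function(i) {
    same <- b$chrom == a$chrom[i]
    if (!any(same)) return("unmatched")
    exact <- same & b$start < a$end[i] & b$end > a$start[i]
    slopm <- same & b$start < a$end[i] + slop & b$end > a$start[i] - slop
    gap <- pmax(b$start - a$end[i], a$start[i] - b$end, 0L)
    gap[!same] <- NA
    j <- which(same)[order(gap[same], b$start[same])][1L]
    if (exact[j]) "exact" else if (slopm[j]) "slop_only" else "unmatched"
  }, character(1))
  expect_equal(ov$matches$type, oracle_type)
  expect_equal(ov$n_exact + ov$n_slop_only + ov$n_unmatched, 1000L)
})
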