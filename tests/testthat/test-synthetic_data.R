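test_that("reference generation is seed-deterministic and hits the GC target", {
  r1 <- generate_reference(10000, 0.5, seed = 1)
  r2 <- generate_reference(10000, 0.5, seed = 1)
  expect_identical(r1$sequence, r2$sequence)
  expect_false(identical(r1$sequence,
                         generate_reference(10000, 0.5, seed = 2)$sequence))

  expect_error(generate_reference(10000, 1.0, seed = 1), "between 0 and 1")
  expect_error(generate_reference(500, 0.5, seed = 1), ">= 1000")
  expect_error(generate_reference(2000, 0.5,
                                  repeat_spec = list(c(1500, 2)), seed = 1),
               "exceed")

  ref <- generate_reference(100000, 0.4, seed = 7)
  gc <- Biostrings::letterFrequency(
    Biostrings::DNAString(ref$sequence[[1]]), "CG", as.prob = TRUE)
  expect_gte(unname(gc), 0.38)
  expect_lte(unname(gc), 0.42)
})

test_that("planted repeats are exact copies at the recorded coordinates", {
  ref <- generate_reference(20000, 0.5, repeat_spec = list(c(800, 2)), seed = 5)
  expect_equal(nrow(ref$repeats), 2L)
  seg <- function(i) substring(ref$sequence[[1]], ref$repeats$start[i] + 1L,
                               ref$repeats$end[i])
  expect_identical(seg(1), seg(2))
})

test_that("truth planting respects rates, spacing and determinism", {
  ref <- generate_reference(1e6, 0.5, seed = 3)
  expect_equal(nrow(plant_truth_variants(ref, 0, 0, seed = 4)), 0L)

  t1 <- plant_truth_variants(ref, 1e-3, 0, seed = 4)
  t2 <- plant_truth_variants(ref, 1e-3, 0, seed = 4)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # binomial oracle: within 4 sd of n * rate (thinning removes only a hair)
  expect_lt(abs(nrow(t1) - 1000), 4 * sqrt(1e6 * 1e-3) + 10)
  # no two variants within 1 bp
  expect_true(all(diff(t1$pos) >= 2L))
  # substitutions have proper alleles
  expect_true(all(t1$ref != t1$alt))
  ref_bases <- substring(ref$sequence[[1]], t1$pos + 1L, t1$pos + 1L)
  expect_equal(substr(t1$ref, 1, 1), ref_bases)

  # het:hom ratio near the default 2:1
  frac_het <- mean(t1$genotype == "het")
  expect_lt(abs(frac_het - 2 / 3), 4 * sqrt(2 / 9 / nrow(t1)))

  # indels are VCF-anchored
  t3 <- plant_truth_variants(ref, 5e-4, 5e-4, seed = 9)
  ind <- t3[t3$kind != "substitution", ]
  expect_gt(nrow(ind), 0)
  expect_true(all(substr(ind$ref, 1, 1) == substr(ind$alt, 1, 1)))
})

test_that("simulated depth recovers the planted GC-bias coefficient", {
  ref <- generate_reference(200000, 0.5, seed = 13, gc_sd = 0.12)
  model <- platform_model(mean_depth = 30, gc_beta = -2)
  depths <- simulate_depth(ref, model, 1000L, seed = 14)
  win <- gc_coverage_windows(ref$sequence, depths, 1000L)
  fit <- fit_gc_bias(win)
  expect_lt(abs(fit$slope - (-2)), 2 * fit$se)

  # gc_beta = 0: slope not significantly different from 0
  depths0 <- simulate_depth(ref, platform_model(30, gc_beta = 0), 1000L,
                            seed = 15)
  fit0 <- fit_gc_bias(gc_coverage_windows(ref$sequence, depths0, 1000L))
  expect_lt(abs(fit0$slope), 2 * fit0$se)
})

test_that("unbiased simulated depth matches the Poisson marginal", {
  ref <- generate_reference(1e6, 0.5, seed = 19)
  depths <- simulate_depth(ref, platform_model(mean_depth = 10, gc_beta = 0),
                           50000L, seed = 20)
  h <- depth_histogram(depths)
  pmf <- poisson_expected(10, max(h$depth))
  obs <- numeric(max(h$depth) + 1L)
  obs[h$depth + 1L] <- h$fraction
  tv <- 0.5 * (sum(abs(obs - pmf)) + (1 - sum(pmf)))
  expect_lt(tv, 0.02)
})

test_that("platform simulation is deterministic and labels are sound", {
  cfg <- analysis_config(chrom_classes = c(chr1 = "autosome"),
                         gc_window_bp = 1000L)
  ref <- generate_reference(60000, 0.45, seed = 31, gc_sd = 0.1)
  truth <- plant_truth_variants(ref, 2e-3, 5e-4, seed = 32)
  model <- default_platform_models()$illumina
  s1 <- simulate_platform(truth, ref, model, cfg, seed = 33,
                          platform_name = "illumina")
  s2 <- simulate_platform(truth, ref, model, cfg, seed = 33,
                          platform_name = "illumina")
  expect_identical(s1, s2)

  # every planted miss-label is recovered by the classifier
  lab <- s1$labels
  missed <- lab[!lab$label %in% c("called", "false_positive"), ]
  expect_gt(nrow(missed), 0)
  ev <- s1$evidence
  idx <- match(paste(missed$chrom, missed$pos),
               paste(ev$chrom, ev$pos))
  got <- classify_missed_sites(ev[idx, ], cfg$platforms$illumina)
  expect_equal(got, missed$label)

  # sites labelled called are present in the callset and pass the filter
  called <- lab[lab$label == "called", ]
  expect_true(all(called$pos %in% s1$callset$pos))
  res <- apply_platform_filter(s1$callset, s1$evidence,
                               cfg$platforms$illumina, cfg)
  expect_equal(nrow(res$rejections), 0L)

  # a site planted with no coverage is labelled NO_COVERAGE
  nc <- missed[missed$label == "NO_COVERAGE", ]
  expect_gt(nrow(nc), 0)
  expect_true(all(ev$depth[match(nc$pos, ev$pos)] == 0L))
})

test_that("coordinated study plants singleton structure for FP estimation", {
  cfg <- analysis_config(chrom_classes = c(chr1 = "autosome"),
                         gc_window_bp = 1000L)
  ref <- generate_reference(100000, 0.45, seed = 41, gc_sd = 0.1)
  truth <- plant_truth_variants(ref, 2e-3, 5e-4, seed = 42)
  models <- default_platform_models()
  study <- simulate_study(truth, ref, models, cfg, seed = 43,
                          solo_miss_per_platform = 15L,
                          exclusive_per_platform = 4L)
  planted <- attr(study, "planted")

  css <- lapply(study, `[[`, "callset")
  subs <- lapply(css, function(cs) {
    df <- as.data.frame(cs)[cs$kind == "substitution", ]
    callset(df$chrom, df$pos, df$ref, df$alt, df$genotype, df$qual,
            platform_id = platform_id(cs))
  })
  part <- venn_partition(subs)

  for (p in names(models)) {
    single <- part$sites[part$sites$cell == p, , drop = FALSE]
    expect_setequal(single$pos,
                    c(planted$exclusive[[p]], planted$fp_sites[[p]]))
    others <- setdiff(names(models), p)
    est <- estimate_false_positives(
      single[, c("chrom", "pos")],
      lapply(stats::setNames(others, others), function(q) study[[q]]$evidence),
      cfg$platforms[others], cfg)
    expect_equal(est$plausible_true, length(planted$exclusive[[p]]))
    expect_equal(est$putative_fp, length(planted$fp_sites[[p]]))
  }
})
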