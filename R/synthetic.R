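#' Platform behaviour model for the synthetic generator
#'
#' Captures the statistical structure the analysis assumes about a
#' sequencing platform: mean post-deduplication depth, a log-linear GC-bias
#' coefficient (per-window depth is Poisson with rate
#' `mean_depth * exp(gc_beta * (gc - 0.5))`), a background substitution error
#' rate, a rate of false calls adjacent to homopolymer runs (pyrosequencing
#' style indel miscalls surfacing as spurious variants), a PCR duplicate
#' fraction, a mapping-quality penalty inside planted repeats, and whether
#' the aligner reports mapping qualities at all.
#'
#' @param mean_depth mean depth (> 0).
#' @param gc_beta log-linear GC-bias coefficient (0 = unbiased).
#' @param substitution_error_rate per-read substitution error rate in [0, 1).
#' @param homopolymer_fp_rate per-adjacent-site false-call rate in [0, 1).
#' @param duplicate_fraction fraction of reads re-emitted at identical
#'   coordinates in [0, 1).
#' @param repeat_mapq_penalty RMS-mapping-quality reduction inside repeats.
#' @param has_mapq does the platform report mapping qualities?
#' @return list of class `platform_model`.
#' @export
platform_model <- function(mean_depth, gc_beta = 0,
                           substitution_error_rate = 0.002,
                           homopolymer_fp_rate = 0,
                           duplicate_fraction = 0.05,
                           repeat_mapq_penalty = 40, has_mapq = TRUE) {
  stopifnot(mean_depth > 0,
            substitution_error_rate >= 0, substitution_error_rate < 1,
            homopolymer_fp_rate >= 0, homopolymer_fp_rate < 1,
            duplicate_fraction >= 0, duplicate_fraction < 1)
  structure(list(mean_depth = mean_depth, gc_beta = gc_beta,
                 substitution_error_rate = substitution_error_rate,
                 homopolymer_fp_rate = homopolymer_fp_rate,
                 duplicate_fraction = duplicate_fraction,
                 repeat_mapq_penalty = repeat_mapq_penalty,
                 has_mapq = isTRUE(has_mapq)),
            class = "platform_model")
}

#' Default platform models
#'
#' Three archetypes mirroring the study conditions: a long-read
#' pyrosequencing-like platform (mean depth 10, nearly GC-neutral, prone to
#' homopolymer-adjacent false calls, no mapping qualities) and two short-read
#' platforms (mean depths 55 and 53 after duplicate removal, marked GC bias,
#' mapping-quality degradation in repeats). Duplicate fractions follow the
#' study's per-platform duplicate-read proportions. The GC-bias magnitudes
#' are illustrative: the source data shows the bias only graphically.
#'
#' @return named list of [platform_model()]: `"454"`, `"illumina"`, `"solid"`.
#' @export
default_platform_models <- function() {
  list(
    `454` = platform_model(mean_depth = 10, gc_beta = -0.2,
                           substitution_error_rate = 0.002,
                           homopolymer_fp_rate = 0.02,
                           duplicate_fraction = 0.027,
                           repeat_mapq_penalty = 0, has_mapq = FALSE),
    illumina = platform_model(mean_depth = 55, gc_beta = -2,
                              substitution_error_rate = 0.005,
                              homopolymer_fp_rate = 0,
                              duplicate_fraction = 0.062,
                              repeat_mapq_penalty = 40, has_mapq = TRUE),
    solid = platform_model(mean_depth = 53, gc_beta = -2,
                           substitution_error_rate = 0.01,
                           homopolymer_fp_rate = 0,
                           duplicate_fraction = 0.176,
                           repeat_mapq_penalty = 40, has_mapq = TRUE)
  )
}

#' Generate a synthetic reference sequence
#'
#' Draws an i.i.d. sequence over A, C, G, T at the requested GC fraction and
#' plants exact duplications at recorded coordinates. With `gc_sd > 0` the GC
#' probability varies per 1-kb block (clipped normal around `gc_target`),
#' giving the window-level GC spread needed to exercise GC-bias profiling;
#' at the default `gc_sd = 0` the whole-sequence GC fraction is within 2
#' percentage points of the target for sequences of 10 kb and longer.
#'
#' @param length sequence length in bp (>= 1000).
#' @param gc_target GC fraction strictly inside (0, 1).
#' @param repeat_spec list of `c(copy_length, copy_count)` duplications to
#'   plant; each spec places one source segment and `copy_count - 1` exact
#'   copies at non-overlapping positions.
#' @param seed integer seed; output is deterministic per seed.
#' @param name chromosome name.
#' @param gc_sd per-block standard deviation of the GC probability.
#' @return list of class `synthetic_reference`: `sequence` (named character
#'   vector of length 1) and `repeats` (an [intervals()] data frame covering
#'   every planted copy, source included).
#' @export
generate_reference <- function(length, gc_target, repeat_spec = list(),
                               seed = 1L, name = "chr1", gc_sd = 0) {
  if (length < 1000L) stop("length must be >= 1000")
  if (gc_target <= 0 || gc_target >= 1)
    stop("gc_target must be strictly between 0 and 1")
  set.seed(seed)
  block <- 1000L
  nblock <- ceiling(length / block)
  p <- if (gc_sd > 0) pmin(0.95, pmax(0.05, stats::rnorm(nblock, gc_target, gc_sd)))
       else rep(gc_target, nblock)
  p_base <- rep(p, each = block)[seq_len(length)]
  is_gc <- stats::runif(length) < p_base
  half <- stats::runif(length) < 0.5
  bases <- ifelse(is_gc, ifelse(half, "G", "C"), ifelse(half, "A", "T"))

  reps <- intervals()
  occupied <- intervals()
  for (spec in repeat_spec) {
    len <- as.integer(spec[1]); copies <- as.integer(spec[2])
    if (len * copies > length)
      stop("repeat copies exceed the sequence length")
    placed <- 0L
    starts <- integer(0)
    guard <- 0L
    while (placed < copies) {
      guard <- guard + 1L
      if (guard > 10000L) stop("could not place repeat copies")
      s <- sample.int(length - len + 1L, 1L) - 1L
      if (any(s < c(starts + len, occupied$end) &
              s + len > c(starts, occupied$start))) next
      starts <- c(starts, s)
      placed <- placed + 1L
    }
    src <- starts[1L]
    for (s in starts[-1L])
      bases[(s + 1L):(s + len)] <- bases[(src + 1L):(src + len)]
    reps <- rbind(reps, intervals(name, starts, starts + len))
    occupied <- rbind(occupied, intervals(name, starts, starts + len))
  }
  structure(list(sequence = stats::setNames(paste(bases, collapse = ""), name),
                 repeats = reps, gc_target = gc_target, seed = seed),
            class = "synthetic_reference")
}

#' Plant truth variants on a reference
#'
#' Substitutions and short (1-3 bp) VCF-anchored indels are placed by
#' independent per-base Bernoulli draws, then thinned so that no two
#' variants are within 1 bp of each other. Genotypes are heterozygous or
#' homozygous at the configured ratio (default 2:1 het:hom).
#'
#' @param reference a `synthetic_reference`.
#' @param snp_rate,indel_rate per-bp probabilities, `snp_rate + indel_rate <
#'   0.1`.
#' @param seed integer seed.
#' @param het_hom_ratio expected het:hom ratio.
#' @return a [callset()] with platform id `"truth"`.
#' @export
plant_truth_variants <- function(reference, snp_rate, indel_rate = 0,
                                 seed = 1L, het_hom_ratio = 2) {
  stopifnot(snp_rate >= 0, indel_rate >= 0, snp_rate + indel_rate < 0.1)
  set.seed(seed)
  seqstr <- reference$sequence[[1L]]
  name <- names(reference$sequence)[1L]
  n <- nchar(seqstr)
  u <- stats::runif(n)
  pos <- which(u < snp_rate + indel_rate) - 1L         # 0-based
  is_indel <- u[pos + 1L] >= snp_rate
  # enforce minimum spacing of 2 bp
  keep <- rep(TRUE, length(pos))
  last <- -10L
  for (i in seq_along(pos)) {
    if (pos[i] - last < 2L) keep[i] <- FALSE else last <- pos[i]
  }
  pos <- pos[keep]; is_indel <- is_indel[keep]
  drop <- is_indel & pos >= n - 4L                      # room for indel allele
  pos <- pos[!drop]; is_indel <- is_indel[!drop]
  if (length(pos) == 0L) return(callset(platform_id = "truth"))

  base_at <- function(p, len = 1L) substring(seqstr, p + 1L, p + len)
  others <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
  ref <- alt <- character(length(pos))
  snp <- !is_indel
  ref[snp] <- base_at(pos[snp])
  alt[snp] <- vapply(ref[snp], function(b) {
    k <- sample.int(3L, 1L); substring(others[[b]], k, k)
  }, character(1))
  for (i in which(is_indel)) {
    anchor <- base_at(pos[i])
    len <- sample.int(3L, 1L)
    if (stats::runif(1) < 0.5) {                        # insertion
      ins <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
      ref[i] <- anchor
      alt[i] <- paste0(anchor, ins)
    } else {                                            # deletion
      ref[i] <- base_at(pos[i], len + 1L)
      alt[i] <- anchor
    }
  }
  genotype <- ifelse(stats::runif(length(pos)) <
                       het_hom_ratio / (het_hom_ratio + 1), "het", "hom")
  callset(rep(name, length(pos)), pos, ref, alt, genotype,
          qual = rep(60, length(pos)), platform_id = "truth")
}

hp_adjacent_positions <- function(seqstr, min_run = 4L) {
  r <- rle(strsplit(seqstr, "", fixed = TRUE)[[1L]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths            # 0-based run starts
  long <- r$lengths >= min_run
  pos <- c(starts[long] - 1L, ends[long])
  sort(unique(pos[pos >= 0L & pos < nchar(seqstr)]))
}

# fraction of the per-read substitution error rate that survives as a
# spurious variant call at a random position
SPURIOUS_CALL_SCALE <- 0.02

planted_fp_sites <- function(reference, model, seed, exclude = integer(0)) {
  set.seed(seed)
  seqstr <- reference$sequence[[1L]]
  hp <- integer(0)
  if (model$homopolymer_fp_rate > 0) {
    cand <- hp_adjacent_positions(seqstr)
    hp <- cand[stats::runif(length(cand)) < model$homopolymer_fp_rate]
  }
  sub <- integer(0)
  rate <- model$substitution_error_rate * SPURIOUS_CALL_SCALE
  if (rate > 0) {
    n <- nchar(seqstr)
    sub <- which(stats::runif(n) < rate) - 1L
  }
  sort(setdiff(unique(c(hp, sub)), exclude))
}

in_intervals <- function(pos, iv) {
  if (nrow(iv) == 0L) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(p >= iv$start & p < iv$end), logical(1))
}

applicable_categories <- function(pcfg) {
  cats <- c("NO_COVERAGE",
            if (pcfg$min_depth >= 3L) "LOW_COVERAGE",
            "EXCESS_COVERAGE", "ALT_NOT_SEEN", "ALT_SEEN_ONCE",
            "SNP_CLUSTER", "NEAR_INDEL",
            if (pcfg$has_mapq) "LOW_RMS_MAPQ" else "NON_UNIQUE",
            if (!is.na(pcfg$min_qual)) "LOW_SNP_QUAL",
            "UNEXPLAINED")
  cats
}

engineer_evidence <- function(category, pcfg, max_depth) {
  mid <- as.integer(floor((pcfg$min_depth + max_depth) / 2))
  e <- list(depth = mid, alt_count = max(2L, mid %/% 2L),
            rms_mapq = if (pcfg$has_mapq) 60 else NA_real_,
            snp_qual = 80, nearby_snp_count = 0L,
            nearest_indel_distance = NA_integer_, in_unique_region = TRUE)
  switch(category,
    NO_COVERAGE = { e$depth <- 0L; e$alt_count <- 0L },
    LOW_COVERAGE = { e$depth <- pcfg$min_depth - 2L
                     e$alt_count <- min(e$alt_count, e$depth) },
    EXCESS_COVERAGE = { e$depth <- max_depth + 10L
                        e$alt_count <- e$depth %/% 2L },
    ALT_NOT_SEEN = { e$alt_count <- 0L },
    ALT_SEEN_ONCE = { e$alt_count <- 1L },
    SNP_CLUSTER = { e$nearby_snp_count <- pcfg$cluster_max_snps + 3L },
    NEAR_INDEL = { e$nearest_indel_distance <-
                     max(0L, pcfg$indel_distance_bp - 2L) },
    LOW_RMS_MAPQ = { e$rms_mapq <- pcfg$min_rms_mapq - 10 },
    NON_UNIQUE = { e$in_unique_region <- FALSE },
    LOW_SNP_QUAL = { e$snp_qual <- pcfg$min_qual - 5 },
    UNEXPLAINED = { })
  e
}

#' Simulate one platform's callset, evidence and labels
#'
#' Per-window depth is Poisson with rate
#' `mean_depth * exp(gc_beta * (gc(w) - 0.5))`. Alternate-allele counts at
#' truth sites are binomial (p = 0.5 heterozygous, 0.95 homozygous), clamped
#' away from the retention thresholds for sites meant to be called so that
#' every planted label survives filtering with a margin of at least 2 units.
#' RMS mapping quality is reduced by `repeat_mapq_penalty` inside planted
#' repeats when the platform has mapping qualities. Homopolymer-adjacent
#' false calls are injected at `homopolymer_fp_rate`. Each evidence record is
#' labelled with the miss-cause the generator engineered (or `"called"` /
#' `"false_positive"`). Output is deterministic per seed.
#'
#' @param truth a truth [callset()] from [plant_truth_variants()].
#' @param reference the `synthetic_reference` the truth lies on.
#' @param model a [platform_model()].
#' @param config an [analysis_config()]; the platform's thresholds are taken
#'   from `config$platforms[[platform_name]]`.
#' @param seed integer seed.
#' @param platform_name name of the platform (and its config entry).
#' @param extra_sites optional data frame (chrom, pos) of additional sites
#'   (other platforms' candidate calls) to cover with evidence.
#' @param planned_misses optional data frame (pos, category) pre-assigning
#'   engineered miss-causes; when NULL roughly 10% of truth substitution
#'   sites are missed, cycling through the categories applicable to the
#'   platform.
#' @param miss_fraction fraction of truth substitution sites to miss when
#'   planning internally.
#' @return list with `callset`, `evidence`, `labels` (chrom, pos, label),
#'   `alignments` (coordinate table with PCR duplicates) and `platform`.
#' @export
simulate_platform <- function(truth, reference, model, config, seed,
                              platform_name, extra_sites = NULL,
                              planned_misses = NULL, miss_fraction = 0.1) {
  pcfg <- config$platforms[[platform_name]]
  if (is.null(pcfg)) stop("no platform config named '", platform_name, "'")
  set.seed(seed)
  seqstr <- reference$sequence[[1L]]
  name <- names(reference$sequence)[1L]
  n <- nchar(seqstr)
  cls <- chrom_class(name, config)
  max_depth <- max_depth_for_class(pcfg, cls)

  # window rates
  win <- gc_coverage_windows(reference$sequence, integer(n),
                             config$gc_window_bp)
  lambda_w <- model$mean_depth * exp(model$gc_beta * (win$gc_fraction - 0.5))
  lambda_at <- function(pos) lambda_w[findInterval(pos, win$start)]

  truth_df <- as.data.frame(truth)
  truth_df <- truth_df[truth_df$chrom == name, , drop = FALSE]
  snp_idx <- which(truth_df$kind == "substitution")

  fp_pos <- planted_fp_sites(reference, model, seed + 1L,
                             exclude = c(truth_df$pos,
                                         if (!is.null(extra_sites)) extra_sites$pos))

  if (is.null(planned_misses)) {
    n_miss <- round(miss_fraction * length(snp_idx))
    miss_sites <- truth_df$pos[utils::head(snp_idx, n_miss)]
    cats <- applicable_categories(pcfg)
    planned_misses <- data.frame(
      pos = miss_sites,
      category = rep_len(cats, length(miss_sites)),
      stringsAsFactors = FALSE)
  }

  extra_pos <- if (is.null(extra_sites)) integer(0)
               else setdiff(extra_sites$pos, c(truth_df$pos, fp_pos))
  all_pos <- sort(unique(c(truth_df$pos, fp_pos, extra_pos)))
  k <- length(all_pos)

  depth <- stats::rpois(k, lambda_at(all_pos))
  in_rep <- in_intervals(all_pos, reference$repeats)
  rms <- if (model$has_mapq)
    ifelse(in_rep, 60 - model$repeat_mapq_penalty, 60) else rep(NA_real_, k)
  nearby <- vapply(seq_len(k), function(i)
    sum(abs(all_pos - all_pos[i]) <= pcfg$cluster_window_bp) - 1L, integer(1))
  indel_pos <- truth_df$pos[truth_df$kind != "substitution" & truth_df$qual >= 50]
  nearest_indel <- if (length(indel_pos))
    vapply(all_pos, function(p) min(abs(indel_pos - p)), numeric(1))
    else rep(Inf, k)
  nearest_indel <- ifelse(is.finite(nearest_indel) & nearest_indel <= 100,
                          as.integer(nearest_indel), NA_integer_)

  ti <- match(truth_df$pos, all_pos)
  is_truth <- seq_len(k) %in% ti
  miss_i <- match(planned_misses$pos, all_pos)
  is_missed <- seq_len(k) %in% miss_i

  alt <- integer(k)
  snp_qual <- rep(NA_real_, k)
  genotype_at <- rep(NA_character_, k)
  genotype_at[ti] <- truth_df$genotype

  # called truth sites: clamp into the retained region with margin >= 2
  called <- is_truth & !is_missed
  d <- pmax(pcfg$min_depth + 2L, pmin(depth[called], max_depth - 2L))
  depth[called] <- d
  het <- genotype_at[called] == "het"
  a <- stats::rbinom(sum(called), d, ifelse(het, 0.5, 0.95))
  a <- ifelse(het, pmax(2L, pmin(a, as.integer(floor(0.75 * d)))),
              pmax(as.integer(ceiling(0.9 * d)), 2L))
  alt[called] <- pmin(a, d)
  snp_qual[called] <- pmax(25, 30 + stats::rpois(sum(called), 20))

  # uncalled extra sites: background error only
  bg <- !is_truth & !(all_pos %in% fp_pos)
  depth[bg] <- pmax(pcfg$min_depth + 2L, pmin(depth[bg], max_depth - 2L))
  alt[bg] <- 0L
  snp_qual[bg] <- NA_real_

  # own false-positive calls: pass the filter comfortably
  fp_i <- match(fp_pos, all_pos)
  if (length(fp_i)) {
    d <- pmax(pcfg$min_depth + 2L, pmin(depth[fp_i], max_depth - 2L))
    depth[fp_i] <- d
    alt[fp_i] <- pmax(2L, as.integer(round(d * 0.4)))
    snp_qual[fp_i] <- 45
    genotype_at[fp_i] <- "het"
  }

  in_unique <- !in_rep

  # engineered misses override every field with margin-respecting values
  if (length(miss_i)) {
    for (j in seq_along(miss_i)) {
      i <- miss_i[j]
      e <- engineer_evidence(planned_misses$category[j], pcfg, max_depth)
      depth[i] <- e$depth; alt[i] <- e$alt_count; rms[i] <- e$rms_mapq
      snp_qual[i] <- e$snp_qual; nearby[i] <- e$nearby_snp_count
      nearest_indel[i] <- e$nearest_indel_distance
      in_unique[i] <- e$in_unique_region
    }
  }

  evidence <- evidence_table(rep(name, k), all_pos, depth, alt, rms, snp_qual,
                             nearby, nearest_indel, in_unique)

  # callset: called truth variants (subs + indels) plus false positives
  keep <- !(truth_df$pos %in% planned_misses$pos)
  cs_df <- truth_df[keep, , drop = FALSE]
  cs_qual <- snp_qual[match(cs_df$pos, all_pos)]
  fp_ref <- substring(seqstr, fp_pos + 1L, fp_pos + 1L)
  others <- c(A = "C", C = "G", G = "T", T = "A")
  cs <- callset(
    c(cs_df$chrom, rep(name, length(fp_pos))),
    c(cs_df$pos, fp_pos),
    c(cs_df$ref, fp_ref),
    c(cs_df$alt, unname(others[fp_ref])),
    c(cs_df$genotype, rep("het", length(fp_pos))),
    c(cs_qual, rep(45, length(fp_pos))),
    platform_id = platform_name)

  labels <- data.frame(
    chrom = name,
    pos = c(truth_df$pos, fp_pos),
    label = c(ifelse(truth_df$pos %in% planned_misses$pos,
                     planned_misses$category[match(truth_df$pos,
                                                   planned_misses$pos)],
                     "called"),
              rep("false_positive", length(fp_pos))),
    stringsAsFactors = FALSE)
  labels <- labels[order(labels$pos), , drop = FALSE]
  rownames(labels) <- NULL

  # alignment coordinate table with PCR duplicates re-emitted
  read_len <- 100L
  n_reads <- max(1L, as.integer(round(n * model$mean_depth / read_len)))
  starts <- sample.int(max(1L, n - read_len), n_reads, replace = TRUE) - 1L
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  aln <- data.frame(chrom = name, start = starts, strand = strand,
                    stringsAsFactors = FALSE)
  n_dup <- as.integer(round(model$duplicate_fraction * n_reads))
  if (n_dup > 0L) {
    dup_rows <- aln[sample.int(n_reads, n_dup, replace = TRUE), , drop = FALSE]
    aln <- rbind(aln, dup_rows)
  }
  rownames(aln) <- NULL

  list(callset = cs, evidence = evidence, labels = labels, alignments = aln,
       platform = platform_name)
}

#' Simulate a coordinated multi-platform study
#'
#' Runs [simulate_platform()] for each model with coordinated planted
#' miss-causes: disjoint per-platform solo-miss sets (cycling the categories
#' applicable to each platform), plus for each platform a set of truth sites
#' missed by both other platforms for coverage reasons - those become
#' exclusive singleton calls that the false-positive estimator should excuse
#' as plausible true variants, while homopolymer false calls become putative
#' false positives. Every platform's evidence covers the union of candidate
#' sites so cross-platform classification and FP estimation are possible.
#'
#' @param truth a truth [callset()].
#' @param reference the `synthetic_reference`.
#' @param models named list of [platform_model()]s.
#' @param config an [analysis_config()] with a platform entry per model.
#' @param seed integer seed.
#' @param solo_miss_per_platform engineered solo misses per platform.
#' @param exclusive_per_platform engineered exclusive-singleton truths per
#'   platform.
#' @return named list of per-platform [simulate_platform()] results, plus
#'   attributes `planted` (the coordinated plan).
#' @export
simulate_study <- function(truth, reference, models, config, seed,
                           solo_miss_per_platform = 30L,
                           exclusive_per_platform = 9L) {
  platforms <- names(models)
  stopifnot(length(platforms) >= 2L, !is.null(platforms))
  name <- names(reference$sequence)[1L]
  truth_df <- as.data.frame(truth)
  snp_pos <- truth_df$pos[truth_df$kind == "substitution"]

  # fp sites per platform, mutually exclusive, reproducing the sub-seed
  # derivation used inside simulate_platform
  seeds <- stats::setNames(seed + 1000L * seq_along(platforms), platforms)
  fp_sites <- list(); used <- truth_df$pos
  for (p in platforms) {
    fp <- planted_fp_sites(reference, models[[p]], seeds[[p]] + 1L,
                           exclude = used)
    fp_sites[[p]] <- fp
    used <- c(used, fp)
  }

  # coordinated miss plan over disjoint chunks of truth SNP sites
  avail <- snp_pos
  take <- function(n) {
    got <- utils::head(avail, n)
    avail <<- avail[-seq_len(min(n, length(avail)))]
    got
  }
  plan <- stats::setNames(vector("list", length(platforms)), platforms)
  for (p in platforms) {
    cats <- applicable_categories(config$platforms[[p]])
    sites <- take(solo_miss_per_platform)
    plan[[p]] <- data.frame(pos = sites,
                            category = rep_len(cats, length(sites)),
                            stringsAsFactors = FALSE)
  }
  exclusive <- stats::setNames(vector("list", length(platforms)), platforms)
  cov_cats <- function(pcfg) c("NO_COVERAGE",
                               if (pcfg$min_depth >= 3L) "LOW_COVERAGE",
                               "EXCESS_COVERAGE")
  for (p in platforms) {
    sites <- take(exclusive_per_platform)
    exclusive[[p]] <- sites
    for (q in setdiff(platforms, p)) {
      cc <- cov_cats(config$platforms[[q]])
      plan[[q]] <- rbind(plan[[q]],
                         data.frame(pos = sites,
                                    category = rep_len(cc, length(sites)),
                                    stringsAsFactors = FALSE))
    }
  }

  out <- stats::setNames(vector("list", length(platforms)), platforms)
  for (p in platforms) {
    others <- unlist(fp_sites[setdiff(platforms, p)], use.names = FALSE)
    extra <- if (length(others))
      data.frame(chrom = name, pos = others, stringsAsFactors = FALSE)
      else NULL
    out[[p]] <- simulate_platform(truth, reference, models[[p]], config,
                                  seed = seeds[[p]], platform_name = p,
                                  extra_sites = extra,
                                  planned_misses = plan[[p]])
  }
  attr(out, "planted") <- list(misses = plan, exclusive = exclusive,
                               fp_sites = fp_sites)
  out
}

#' Simulate a per-base depth track
#'
#' Per-window Poisson depth at rate
#' `mean_depth * exp(gc_beta * (gc(w) - 0.5))`.
#'
#' @param reference a `synthetic_reference` (or named character vector).
#' @param model a [platform_model()].
#' @param window_bp window size for the GC-dependent rate.
#' @param seed integer seed.
#' @return integer vector of per-base depths.
#' @export
simulate_depth <- function(reference, model, window_bp, seed) {
  seqs <- if (inherits(reference, "synthetic_reference")) reference$sequence
          else reference
  set.seed(seed)
  n <- nchar(seqs[[1L]])
  win <- gc_coverage_windows(seqs, integer(n), window_bp)
  lambda <- model$mean_depth * exp(model$gc_beta * (win$gc_fraction - 0.5))
  unlist(lapply(seq_len(nrow(win)), function(i)
    stats::rpois(win$end[i] - win$start[i], lambda[i])), use.names = FALSE)
}
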