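# Independent brute-force oracles used to cross-check the implementation.

# All-placement mappability scan: for every fragment and both strands, count
# mismatches at every gapless offset with plain vector comparisons.
oracle_mappability_counts <- function(seqstr, frags, max_divergence) {
  n <- nchar(seqstr)
  L <- unique(frags$end - frags$start)
  stopifnot(length(L) == 1L)
  budget <- floor(max_divergence * L)
  ref <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  counts <- integer(n)
  offsets <- 0:(n - L)
  for (i in seq_len(nrow(frags))) {
    fwd <- strsplit(frags$sequence[i], "", fixed = TRUE)[[1]]
    rc <- rev(unname(comp[fwd]))
    for (pat in list(fwd, rc)) {
      mis <- integer(length(offsets))
      for (j in seq_len(L)) mis <- mis + (ref[offsets + j] != pat[j])
      for (o in offsets[mis <= budget])
        counts[(o + 1L):(o + L)] <- counts[(o + 1L):(o + L)] + 1L
    }
  }
  counts
}

oracle_unique_flags <- function(seqstr, fragment_length, max_divergence) {
  frags <- tile_reference(c(chr1 = seqstr), fragment_length)
  counts <- oracle_mappability_counts(seqstr, frags, max_divergence)
  mult <- integer(nchar(seqstr))
  for (i in seq_len(nrow(frags)))
    mult[(frags$start[i] + 1L):frags$end[i]] <-
      mult[(frags$start[i] + 1L):frags$end[i]] + 1L
  counts <= mult
}

unique_flags_from_intervals <- function(iv, n) {
  flags <- logical(n)
  for (i in seq_len(nrow(iv)))
    flags[(iv$start[i] + 1L):iv$end[i]] <- TRUE
  flags
}

# Poisson bounds by direct pmf summation
oracle_poisson_bounds <- function(lambda, alpha) {
  d <- 0L
  cdf <- exp(-lambda)   # P(X <= 0)
  term <- exp(-lambda)
  # max: smallest d with CDF(d) >= 1 - alpha
  while (cdf < 1 - alpha) {
    d <- d + 1L
    term <- term * lambda / d
    cdf <- cdf + term
  }
  max_d <- d
  # min: largest d with CDF(d - 1) <= alpha
  d <- 0L; cdf <- 0; term <- exp(-lambda); k <- 0L
  min_d <- 0L
  repeat {
    # cdf currently = P(X <= k - 1); candidate d = k qualifies if cdf <= alpha
    if (cdf <= alpha) min_d <- k else break
    cdf <- cdf + term
    k <- k + 1L
    term <- term * lambda / k
    if (k > lambda + 20 * sqrt(lambda) + 20) break
  }
  c(min_depth = min_d, max_depth = max_d)
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_intervals <- function(n, seed, chroms = c("chr1", "chr2"),
                             max_pos = 10000L) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(50L, n, replace = TRUE)
  intervals(sample(chroms, n, replace = TRUE), start, start + width)
}

demo_config_path <- function() {
  system.file("extdata", "demo_config.yaml", package = "concordkit")
}

small_config <- function(...) {
  over <- list(...)
  tmp <- tempfile(fileext = ".yaml")
  cfg <- utils::modifyList(list(
    random_seed = 7L, gc_window_bp = 1000L, indel_slop_bp = 10L,
    chrom_classes = list(chr1 = "autosome"),
    pipeline = list(genome_length = 60000L, gc_target = 0.45, gc_sd = 0.1,
                    snp_rate = 0.002, indel_rate = 5e-4,
                    fragment_length = 100L, uniqueome_divergence = 0,
                    solo_miss_per_platform = 12L,
                    exclusive_per_platform = 3L)), over)
  yaml::write_yaml(cfg, tmp)
  tmp
}
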