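#' Mean sequencing coverage
#'
#' Coverage is the number of distinct aligned bases divided by the number of
#' non-N bases in the reference. Reported to two decimals in summaries; this
#' function returns the exact quotient.
#'
#' @param aligned_bases total aligned (non-duplicate) base count.
#' @param genome_non_n_bases non-N reference length.
#' @return numeric coverage.
#' @export
compute_mean_coverage <- function(aligned_bases, genome_non_n_bases) {
  if (genome_non_n_bases <= 0) stop("genome_non_n_bases must be positive")
  if (aligned_bases < 0) stop("aligned_bases must be non-negative")
  aligned_bases / genome_non_n_bases
}

#' Depth-of-coverage histogram
#'
#' Fraction of reference bases at each observed depth. Depth-0 bases are
#' included in the denominator, so the fractions describe the whole
#' reference, not just the covered part.
#'
#' @param per_base_depths integer vector of per-base depths (>= 0).
#' @return list of class `depth_histogram` with `depth` (integer), `fraction`
#'   (numeric summing to 1) and `total_bases`.
#' @export
depth_histogram <- function(per_base_depths) {
  if (length(per_base_depths) == 0L) stop("empty depth vector")
  if (any(per_base_depths < 0L)) stop("negative depths")
  tab <- table(per_base_depths)
  out <- list(depth = as.integer(names(tab)),
              fraction = as.numeric(tab) / length(per_base_depths),
              total_bases = length(per_base_depths))
  class(out) <- "depth_histogram"
  out
}

#' Poisson depth model probabilities
#'
#' Probability mass e^(-lambda) lambda^d / d! for d = 0..max_depth, computed
#' in log space so large means stay numerically stable.
#'
#' @param lambda mean depth (> 0).
#' @param max_depth largest depth to tabulate.
#' @return named numeric vector, names "0".."max_depth".
#' @export
poisson_expected <- function(lambda, max_depth) {
  if (lambda <= 0) stop("lambda must be positive")
  d <- 0:max_depth
  p <- exp(stats::dpois(d, lambda, log = TRUE))
  names(p) <- d
  p
}

#' Poisson tail bounds for depth filtering
#'
#' Returns the depth interval implied by a Poisson coverage model:
#' `max_depth` is the smallest d with CDF(d) >= 1 - alpha, and `min_depth`
#' the largest d with CDF(d - 1) <= alpha (0 if no positive d qualifies).
#' These are the model-derived analogues of fixed depth cutoffs used when
#' filtering variant calls.
#'
#' @param lambda mean depth (> 0).
#' @param alpha tail probability in (0, 0.5).
#' @return named integer vector c(min_depth, max_depth).
#' @export
poisson_depth_bounds <- function(lambda, alpha) {
  if (lambda <= 0) stop("lambda must be positive")
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must be in (0, 0.5)")
  max_depth <- stats::qpois(1 - alpha, lambda)
  # largest d with P(X <= d - 1) <= alpha; qpois gives smallest q with
  # CDF(q) >= alpha, so scan down from there
  d <- stats::qpois(alpha, lambda)
  while (d > 0L && stats::ppois(d - 1L, lambda) > alpha) d <- d - 1L
  while (stats::ppois(d, lambda) <= alpha) d <- d + 1L
  c(min_depth = as.integer(d), max_depth = as.integer(max_depth))
}

#' GC content and mean coverage in non-overlapping windows
#'
#' Tiles each sequence left to right with fixed-size windows (the final
#' window may be shorter and is flagged `partial`). GC fraction is computed
#' over non-N bases only; windows consisting entirely of N are omitted.
#'
#' @param reference named character vector of sequences (a single unnamed
#'   sequence is accepted).
#' @param per_base_depths integer vector (single sequence) or named list of
#'   vectors matching `reference`.
#' @param window_bp window size in bp.
#' @return data frame with chrom, start, end, gc_fraction, mean_depth,
#'   partial.
#' @export
gc_coverage_windows <- function(reference, per_base_depths, window_bp) {
  stopifnot(window_bp > 0)
  if (is.character(reference) && is.null(names(reference)) &&
      length(reference) == 1L) names(reference) <- "chr1"
  if (!is.list(per_base_depths)) per_base_depths <-
      stats::setNames(list(per_base_depths), names(reference)[1L])
  out <- lapply(names(reference), function(nm) {
    seqstr <- reference[[nm]]
    depths <- per_base_depths[[nm]]
    n <- nchar(seqstr)
    if (length(depths) != n)
      stop("depth vector length (", length(depths),
           ") != sequence length (", n, ") for ", nm)
    starts <- seq(0L, n - 1L, by = window_bp)
    ends <- pmin(starts + window_bp, n)
    v <- Biostrings::Views(Biostrings::DNAString(seqstr), starts + 1L, ends)
    freq <- Biostrings::letterFrequency(v, letters = c("CG", "N"))
    len <- ends - starts
    non_n <- len - freq[, "N"]
    gc <- ifelse(non_n > 0, freq[, "C|G"] / non_n, NA_real_)
    md <- vapply(seq_along(starts), function(i)
      mean(depths[(starts[i] + 1L):ends[i]]), numeric(1))
    df <- data.frame(chrom = nm, start = starts, end = ends,
                     gc_fraction = gc, mean_depth = md,
                     partial = len < window_bp, stringsAsFactors = FALSE)
    df[non_n > 0L, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fit the log-linear GC-bias coefficient
#'
#' Regresses log mean window depth on centred GC fraction,
#' log E(depth) = log(mean) + beta (gc - 0.5), by least squares over windows
#' with positive depth. The slope estimates the GC-bias coefficient of the
#' coverage model.
#'
#' @param windows output of [gc_coverage_windows()].
#' @return list with `slope`, `se`, `intercept`, `n_windows`.
#' @export
fit_gc_bias <- function(windows) {
  w <- windows[!windows$partial & windows$mean_depth > 0, , drop = FALSE]
  if (nrow(w) < 3L) stop("need at least 3 complete windows with coverage")
  fit <- stats::lm(log(mean_depth) ~ I(gc_fraction - 0.5), data = w)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm[2L, 1L]), se = unname(sm[2L, 2L]),
       intercept = unname(sm[1L, 1L]), n_windows = nrow(w))
}

#' Mark PCR duplicates by identical alignment coordinates
#'
#' Within each group of records sharing (chrom, start, strand, mate_chrom,
#' mate_start), the first-seen record is retained and the remaining g - 1
#' are flagged duplicate. Single-end records (NA mate fields) group on the
#' first three fields.
#'
#' @param records data frame with columns chrom, start, strand and optionally
#'   mate_chrom, mate_start.
#' @return list with logical `is_duplicate` (input order) and
#'   `duplicate_count`.
#' @export
mark_duplicates <- function(records) {
  stopifnot(all(c("chrom", "start", "strand") %in% names(records)))
  mc <- if ("mate_chrom" %in% names(records)) records$mate_chrom else NA
  ms <- if ("mate_start" %in% names(records)) records$mate_start else NA
  key <- paste(records$chrom, records$start, records$strand, mc, ms,
               sep = "\r")
  dup <- duplicated(key)
  list(is_duplicate = dup, duplicate_count = sum(dup))
}
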