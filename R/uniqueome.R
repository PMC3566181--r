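#' Tile a reference into half-overlapping fragments
#'
#' Breaks each chromosome into fragments of the read length L, with adjacent
#' fragments overlapping by L/2: starts 0, L/2, L, ... If the final regular
#' start would overrun the chromosome, one extra fragment is anchored at
#' `chrom_length - L` so every base is covered. No duplicate fragments are
#' emitted.
#'
#' @param reference named character vector of sequences.
#' @param fragment_length L, even and >= 2.
#' @return data frame with chrom, start, end, sequence.
#' @export
tile_reference <- function(reference, fragment_length) {
  L <- as.integer(fragment_length)
  if (L < 2L || L %% 2L != 0L) stop("fragment_length must be even and >= 2")
  if (is.null(names(reference)) && length(reference) == 1L)
    names(reference) <- "chr1"
  out <- lapply(names(reference), function(nm) {
    n <- nchar(reference[[nm]])
    if (n < L)
      stop("chromosome ", nm, " (length ", n,
           ") is shorter than the fragment length ", L)
    starts <- seq(0L, n - L, by = L %/% 2L)
    if (starts[length(starts)] + L < n) starts <- c(starts, n - L)
    starts <- unique(starts)
    data.frame(chrom = nm, start = starts, end = starts + L,
               sequence = substring(reference[[nm]], starts + 1L, starts + L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Count fragment placements over the reference (self-masking scan)
#'
#' Every fragment is placed gaplessly at every offset, on both strands, of
#' every chromosome; a placement counts when it has at most
#' `floor(max_divergence * L)` mismatches. The counter of every reference
#' base under a counting placement is incremented. Each fragment's home
#' placement always counts (it has zero mismatches).
#'
#' @param reference named character vector of sequences.
#' @param fragments output of [tile_reference()].
#' @param max_divergence allowed mismatch fraction in [0, 1).
#' @return list of class `mappability_track`: `counts` and
#'   `tile_multiplicity` (named lists of per-base integer vectors),
#'   `fragment_length`, `max_divergence`.
#' @export
count_fragment_alignments <- function(reference, fragments, max_divergence = 0.05) {
  if (is.null(names(reference)) && length(reference) == 1L)
    names(reference) <- "chr1"
  L <- unique(fragments$end - fragments$start)
  stopifnot(length(L) == 1L)
  mm <- as.integer(floor(max_divergence * L))
  subjects <- lapply(reference, Biostrings::DNAString)
  counts <- lapply(reference, function(s) integer(nchar(s)))

  add_ranges <- function(counts_vec, starts, ends) {
    if (length(starts) == 0L) return(counts_vec)
    cov <- IRanges::coverage(IRanges::IRanges(start = starts, end = ends),
                             width = length(counts_vec))
    counts_vec + as.integer(cov)
  }

  if (mm == 0L) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(fragments$sequence))
    for (nm in names(subjects)) {
      hits <- Biostrings::matchPDict(pd, subjects[[nm]])
      r <- unlist(IRanges::IRangesList(hits))
      counts[[nm]] <- add_ranges(counts[[nm]], IRanges::start(r), IRanges::end(r))
      hits_rc <- Biostrings::matchPDict(
        pd, Biostrings::reverseComplement(subjects[[nm]]))
      r2 <- unlist(IRanges::IRangesList(hits_rc))
      n <- nchar(reference[[nm]])
      counts[[nm]] <- add_ranges(counts[[nm]],
                                 n - IRanges::end(r2) + 1L,
                                 n - IRanges::start(r2) + 1L)
    }
  } else {
    frag_seqs <- Biostrings::DNAStringSet(fragments$sequence)
    frag_rc <- Biostrings::reverseComplement(frag_seqs)
    for (i in seq_len(nrow(fragments))) {
      for (nm in names(subjects)) {
        m <- Biostrings::matchPattern(frag_seqs[[i]], subjects[[nm]],
                                      max.mismatch = mm, with.indels = FALSE)
        counts[[nm]] <- add_ranges(counts[[nm]], IRanges::start(m),
                                   IRanges::end(m))
        m2 <- Biostrings::matchPattern(frag_rc[[i]], subjects[[nm]],
                                       max.mismatch = mm, with.indels = FALSE)
        counts[[nm]] <- add_ranges(counts[[nm]], IRanges::start(m2),
                                   IRanges::end(m2))
      }
    }
  }

  mult <- lapply(names(reference), function(nm) {
    f <- fragments[fragments$chrom == nm, , drop = FALSE]
    v <- integer(nchar(reference[[nm]]))
    add_ranges(v, f$start + 1L, f$end)
  })
  names(mult) <- names(reference)

  out <- list(counts = counts, tile_multiplicity = mult,
              fragment_length = L, max_divergence = max_divergence)
  class(out) <- "mappability_track"
  out
}

#' Uniquely mappable intervals from a mappability track
#'
#' A base is uniquely mappable when its placement counter does not exceed its
#' tile multiplicity: interior bases lie in two tiles so they are expected in
#' exactly two self-alignments; bases near chromosome ends covered by a
#' single tile use threshold 1. Maximal runs of unique bases are emitted as
#' half-open intervals.
#'
#' @param track a `mappability_track` from [count_fragment_alignments()].
#' @return an [intervals()] data frame.
#' @export
unique_intervals <- function(track) {
  out <- lapply(names(track$counts), function(nm) {
    uniq <- track$counts[[nm]] <= track$tile_multiplicity[[nm]]
    r <- rle(uniq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (!any(keep)) return(intervals())
    intervals(nm, starts[keep], ends[keep])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Filter a callset to calls inside a set of regions
#'
#' @param x a [callset()].
#' @param regions an [intervals()] data frame (0-based half-open).
#' @return the retained [callset()].
#' @export
filter_by_regions <- function(x, regions) {
  if (nrow(x) == 0L || nrow(regions) == 0L)
    return(callset(platform_id = platform_id(x)))
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(start = regions$start + 1L,
                                                end = regions$end))
  sites <- GenomicRanges::GRanges(x$chrom,
                                  IRanges::IRanges(start = x$pos + 1L, width = 1L))
  keep <- GenomicRanges::countOverlaps(sites, gr) > 0L
  out <- as.data.frame(x)[keep, , drop = FALSE]
  callset(out$chrom, out$pos, out$ref, out$alt, out$genotype, out$qual,
          kind = out$kind, platform_id = platform_id(x))
}

#' Compute the uniqueome of a reference
#'
#' Convenience wrapper: tile, count placements, extract unique intervals.
#'
#' @param reference named character vector of sequences.
#' @param fragment_length read length L.
#' @param max_divergence allowed mismatch fraction.
#' @return an [intervals()] data frame of uniquely mappable regions.
#' @export
uniqueome <- function(reference, fragment_length, max_divergence = 0.05) {
  frags <- tile_reference(reference, fragment_length)
  track <- count_fragment_alignments(reference, frags, max_divergence)
  unique_intervals(track)
}
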