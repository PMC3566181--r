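#' Construct a callset
#'
#' A callset is a data frame of variant calls from one platform, one row per
#' call, kept sorted by (chrom, pos). Positions are 0-based internally; file
#' readers and writers convert to/from the 1-based VCF convention at the
#' boundary.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 0-based positions.
#' @param ref,alt reference and alternate alleles (VCF-style anchored strings
#'   for indels).
#' @param genotype `"hom"` or `"het"`.
#' @param qual non-negative call quality (Phred-scaled likelihood that the
#'   called genotype differs from the reference).
#' @param kind `"substitution"`, `"insertion"` or `"deletion"`; inferred from
#'   allele lengths when `NULL`.
#' @param platform_id platform label attached as an attribute.
#' @return A `callset` data frame with columns chrom, pos, ref, alt, kind,
#'   genotype, qual.
#' @export
callset <- function(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), genotype = character(),
                    qual = numeric(), kind = NULL, platform_id = "unknown") {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   genotype = as.character(genotype), qual = as.numeric(qual),
                   stringsAsFactors = FALSE)
  df$kind <- if (is.null(kind)) infer_kind(df$ref, df$alt) else as.character(kind)
  df <- df[, c("chrom", "pos", "ref", "alt", "kind", "genotype", "qual")]
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "platform_id") <- platform_id
  class(df) <- c("callset", "data.frame")
  validate_callset(df)
  df
}

infer_kind <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "substitution",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

#' Validate callset invariants
#'
#' Checks sortedness, coordinate validity, allele constraints for
#' substitutions, non-negative qualities and uniqueness of substitution sites.
#'
#' @param x a `callset`.
#' @return `x` invisibly; stops on violation.
#' @export
validate_callset <- function(x) {
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(x$pos < 0L)) stop("callset: negative positions")
  if (any(!nzchar(x$chrom))) stop("callset: empty chromosome names")
  o <- order(x$chrom, x$pos)
  if (!identical(o, seq_len(nrow(x)))) stop("callset: not sorted by (chrom, pos)")
  subs <- x$kind == "substitution"
  if (any(subs)) {
    if (any(nchar(x$ref[subs]) != 1L | nchar(x$alt[subs]) != 1L))
      stop("callset: substitution alleles must have length 1")
    if (any(x$ref[subs] == x$alt[subs]))
      stop("callset: substitution ref and alt alleles must differ")
    key <- paste(x$chrom[subs], x$pos[subs])
    if (anyDuplicated(key)) stop("callset: duplicated substitution site")
  }
  if (any(x$qual < 0, na.rm = TRUE)) stop("callset: negative quality")
  if (!all(x$genotype %in% c("hom", "het")))
    stop("callset: genotype must be 'hom' or 'het'")
  invisible(x)
}

#' Platform id of a callset
#' @param x a `callset`.
#' @return character scalar.
#' @export
platform_id <- function(x) attr(x, "platform_id") %||% "unknown"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an interval table
#'
#' Intervals use 0-based half-open coordinates, the BED convention.
#'
#' @param chrom character vector.
#' @param start 0-based inclusive starts.
#' @param end 0-based exclusive ends.
#' @return data frame with columns chrom, start, end.
#' @export
intervals <- function(chrom = character(), start = integer(), end = integer()) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  if (any(df$start < 0L)) stop("intervals: negative start coordinate")
  if (any(df$start >= df$end)) stop("intervals: require start < end")
  rownames(df) <- NULL
  df
}

#' Construct a per-site evidence table
#'
#' One row per (site, platform) pileup summary: post-deduplication depth,
#' alternate-allele observation count, RMS mapping quality (NA for aligners
#' without mapping qualities), SNP quality, number of other candidate SNPs in
#' the cluster window, distance to the nearest high-quality indel (NA if
#' none nearby) and whether the site lies in a uniquely mappable region.
#'
#' @param chrom,pos site coordinates (pos 0-based).
#' @param depth non-duplicate read depth.
#' @param alt_count reads showing the queried alternate allele.
#' @param rms_mapq root-mean-square mapping quality or NA.
#' @param snp_qual call quality or NA.
#' @param nearby_snp_count other candidate SNPs within the cluster window.
#' @param nearest_indel_distance bp to nearest high-quality indel, NA if none.
#' @param in_unique_region logical.
#' @return data frame of class `evidence`.
#' @export
evidence_table <- function(chrom = character(), pos = integer(),
                           depth = integer(), alt_count = integer(),
                           rms_mapq = NA_real_, snp_qual = NA_real_,
                           nearby_snp_count = 0L,
                           nearest_indel_distance = NA_integer_,
                           in_unique_region = TRUE) {
  n <- length(pos)
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   depth = as.integer(depth), alt_count = as.integer(alt_count),
                   rms_mapq = rep_len(as.numeric(rms_mapq), n),
                   snp_qual = rep_len(as.numeric(snp_qual), n),
                   nearby_snp_count = rep_len(as.integer(nearby_snp_count), n),
                   nearest_indel_distance = rep_len(as.integer(nearest_indel_distance), n),
                   in_unique_region = rep_len(as.logical(in_unique_region), n),
                   stringsAsFactors = FALSE)
  if (any(df$depth < 0L) || any(df$alt_count < 0L))
    stop("evidence: negative counts")
  if (any(df$alt_count > df$depth))
    stop("evidence: alt_count exceeds depth")
  rownames(df) <- NULL
  class(df) <- c("evidence", "data.frame")
  df
}

site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")
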