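#' Read a variant callset
#'
#' Supports a VCF 4.x subset (CHROM, POS, REF, ALT, QUAL plus the sample GT
#' field) and a tab-separated dialect with header
#' `chrom pos ref alt genotype qual` (pos 1-based in both dialects). Input
#' 1-based coordinates are converted to the internal 0-based convention.
#' Unsorted input is re-sorted with a notice.
#'
#' @param path input file.
#' @param dialect `"vcf"` or `"tsv"`.
#' @param platform_id label attached to the callset.
#' @return a [callset()].
#' @export
read_variant_calls <- function(path, dialect = c("vcf", "tsv"),
                               platform_id = "unknown") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF comes back bare
    if (is.null(fix) || nrow(fix) == 0L)
      return(callset(platform_id = platform_id))
    pos <- suppressWarnings(as.integer(fix[, "POS"]))
    if (anyNA(pos)) {
      bad <- which(is.na(pos))[1L]
      stop("malformed VCF record ", bad, ": non-numeric POS '",
           fix[bad, "POS"], "'")
    }
    gt <- tryCatch(vcfR::extract.gt(v, "GT")[, 1L],
                   error = function(e) rep(NA_character_, nrow(fix)))
    genotype <- ifelse(grepl("^1[/|]1", gt), "hom", "het")
    qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
    qual[is.na(qual)] <- 0
    df <- data.frame(chrom = fix[, "CHROM"], pos = pos - 1L,
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     genotype = genotype, qual = qual,
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "genotype", "qual")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("TSV callset missing column(s): ", paste(miss, collapse = ", "))
    pos <- suppressWarnings(as.integer(df$pos))
    if (anyNA(pos)) {
      bad <- which(is.na(pos))[1L]
      stop("malformed TSV record at line ", bad + 1L, ": non-numeric pos '",
           df$pos[bad], "'")
    }
    df$pos <- pos - 1L
  }
  o <- order(df$chrom, df$pos)
  if (!identical(o, seq_len(nrow(df)))) {
    message("input callset not sorted; re-sorting")
    df <- df[o, , drop = FALSE]
  }
  callset(df$chrom, df$pos, df$ref, df$alt, df$genotype, df$qual,
          platform_id = platform_id)
}

#' Write a callset
#'
#' The VCF dialect writes the documented subset (CHROM, POS, REF, ALT, QUAL,
#' FORMAT GT, one sample); internal 0-based positions are converted to VCF
#' 1-based. The TSV dialect writes the same columns as [read_variant_calls()]
#' expects.
#'
#' @param x a [callset()].
#' @param path output file.
#' @param dialect `"vcf"` or `"tsv"`.
#' @export
write_variant_calls <- function(x, path, dialect = c("vcf", "tsv")) {
  dialect <- match.arg(dialect)
  validate_callset(x)
  if (dialect == "vcf") {
    hdr <- c("##fileformat=VCFv4.2",
             paste0("##source=concordkit;platform=", platform_id(x)),
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", platform_id(x), sep = "\t"))
    gt <- ifelse(x$genotype == "hom", "1/1", "0/1")
    rec <- if (nrow(x)) paste(x$chrom, x$pos + 1L, ".", x$ref, x$alt,
                              format(x$qual, trim = TRUE, scientific = FALSE),
                              "PASS", ".", "GT", gt, sep = "\t")
           else character()
    writeLines(c(hdr, rec), path)
  } else {
    df <- as.data.frame(x)[, c("chrom", "pos", "ref", "alt", "genotype", "qual")]
    df$pos <- df$pos + 1L
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write BED3 interval tracks
#'
#' BED uses 0-based half-open coordinates, matching the internal convention.
#' Overlapping intervals are permitted.
#'
#' @param x interval data frame (chrom, start, end).
#' @param path file path.
#' @return `read_bed` returns an [intervals()] data frame.
#' @export
write_bed <- function(x, path) {
  if (nrow(x) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (any(x$start < 0L)) stop("negative coordinates are not valid BED")
  gr <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(start = x$start + 1L, end = x$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (length(readLines(path, n = 1L)) == 0L) return(intervals())
  gr <- rtracklayer::import(path, format = "BED")
  intervals(as.character(GenomicRanges::seqnames(gr)),
            GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
}

#' Read / write per-site evidence tables
#'
#' Tab-separated with header columns chrom, pos (1-based on disk), depth,
#' alt_count, rms_mapq, snp_qual, nearby_snp_count, nearest_indel_distance,
#' in_unique_region.
#'
#' @param x an [evidence_table()].
#' @param path file path.
#' @return `read_evidence` returns an [evidence_table()].
#' @export
write_evidence <- function(x, path) {
  df <- as.data.frame(x)
  df$pos <- df$pos + 1L
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_evidence
#' @export
read_evidence <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  evidence_table(df$chrom, df$pos - 1L, df$depth, df$alt_count, df$rms_mapq,
                 df$snp_qual, df$nearby_snp_count, df$nearest_indel_distance,
                 df$in_unique_region)
}

#' Read / write FASTA references
#'
#' @param x named character vector of sequences.
#' @param path file path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}
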