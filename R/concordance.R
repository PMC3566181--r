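#' Miss-category labels
#'
#' The nine reasons a platform can fail to call a site, in classification
#' precedence order, plus the explicit residual `UNEXPLAINED`. `NON_UNIQUE`
#' occupies the RMS-mapping-quality slot for platforms whose aligner reports
#' no mapping quality: for those, a site outside the uniquely mappable
#' region takes the place of the low-mapping-quality rule.
#'
#' @export
MISS_CATEGORIES <- c("NO_COVERAGE", "LOW_COVERAGE", "EXCESS_COVERAGE",
                     "ALT_NOT_SEEN", "ALT_SEEN_ONCE", "SNP_CLUSTER",
                     "NEAR_INDEL", "LOW_RMS_MAPQ", "NON_UNIQUE",
                     "LOW_SNP_QUAL", "UNEXPLAINED")

#' Venn partition of per-platform callsets
#'
#' Assigns every variant location (chrom, pos) to the cell of exactly the
#' platforms that called it. Site identity is by location only; a
#' mismatching alternate allele at a shared location is flagged but the
#' location still counts as concordant.
#'
#' @param callsets list of [callset()]s with distinct platform ids.
#' @return list of class `venn_partition`: `sites` (chrom, pos, cell,
#'   allele_mismatch), `platforms`.
#' @export
venn_partition <- function(callsets) {
  if (length(callsets) < 2L) stop("need at least 2 callsets")
  platforms <- unname(vapply(callsets, platform_id, character(1)))
  if (anyDuplicated(platforms))
    stop("duplicate platform id: ",
         platforms[duplicated(platforms)][1L])
  per <- lapply(seq_along(callsets), function(i) {
    cs <- callsets[[i]]
    data.frame(chrom = cs$chrom, pos = cs$pos, alt = cs$alt,
               platform = platforms[i], stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per)
  if (nrow(all) == 0L)
    return(structure(list(sites = data.frame(chrom = character(),
                                             pos = integer(),
                                             cell = character(),
                                             allele_mismatch = logical()),
                          platforms = platforms),
                     class = "venn_partition"))
  key <- site_key(all$chrom, all$pos)
  split_idx <- split(seq_len(nrow(all)), key)
  cell <- vapply(split_idx, function(ix)
    paste(platforms[platforms %in% all$platform[ix]], collapse = "+"),
    character(1))
  mism <- vapply(split_idx, function(ix)
    length(unique(all$alt[ix])) > 1L, logical(1))
  first <- vapply(split_idx, `[`, integer(1), 1L)
  sites <- data.frame(chrom = all$chrom[first], pos = all$pos[first],
                      cell = cell, allele_mismatch = mism,
                      stringsAsFactors = FALSE)
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sites = sites, platforms = platforms),
            class = "venn_partition")
}

#' Cell sizes of a Venn partition
#' @param partition a `venn_partition`.
#' @return named integer vector over all non-empty platform subsets.
#' @export
venn_cell_sizes <- function(partition) {
  p <- partition$platforms
  subsets <- unlist(lapply(seq_along(p), function(k)
    utils::combn(p, k, paste, collapse = "+", simplify = FALSE)),
    recursive = FALSE)
  out <- stats::setNames(integer(length(subsets)), unlist(subsets))
  tab <- table(partition$sites$cell)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Aggregate per-platform totals from Venn cell sizes
#'
#' Platform total = sum of cells containing that platform; union = sum of
#' all cells; discordant = union minus the all-platform cell.
#'
#' @param cell_sizes named numeric vector, names like `"A"`, `"A+B"`
#'   (platform ids joined by `+`), or a `venn_partition`.
#' @return list with `platform_totals` (named), `union`, `discordant`.
#' @export
aggregate_platform_totals <- function(cell_sizes) {
  if (inherits(cell_sizes, "venn_partition"))
    cell_sizes <- venn_cell_sizes(cell_sizes)
  members <- strsplit(names(cell_sizes), "+", fixed = TRUE)
  platforms <- unique(unlist(members))
  totals <- vapply(platforms, function(p)
    sum(cell_sizes[vapply(members, function(m) p %in% m, logical(1))]),
    numeric(1))
  full_cell <- vapply(members, length, integer(1)) == length(platforms)
  list(platform_totals = totals,
       union = sum(cell_sizes),
       discordant = sum(cell_sizes) - sum(cell_sizes[full_cell]))
}

#' Classify why a platform missed sites
#'
#' Applies the fixed-precedence rule list to each evidence record of a
#' platform that did not call the site; the first matching rule wins:
#' depth 0; depth below the minimum; depth above the class maximum;
#' alternate allele unseen; alternate allele seen exactly once; too many
#' candidate SNPs in the cluster window; proximity to a high-quality indel;
#' low RMS mapping quality (or, for platforms without mapping qualities, a
#' non-uniquely-mappable location); low SNP quality; else UNEXPLAINED.
#'
#' @param evidence an [evidence_table()] of missed sites for one platform.
#' @param pcfg the platform's [platform_config()].
#' @param chrom_class chromosome class per record (scalar or vector),
#'   selecting the maximum-depth bound.
#' @return character vector of [MISS_CATEGORIES] labels.
#' @export
classify_missed_sites <- function(evidence, pcfg, chrom_class = "autosome") {
  n <- nrow(evidence)
  if (n == 0L) return(character())
  max_depth <- max_depth_for_class(pcfg, rep_len(chrom_class, n))
  cat <- rep(NA_character_, n)
  set <- function(cond, label) {
    cond[is.na(cond)] <- FALSE
    ifelse(is.na(cat) & cond, label, cat)
  }
  cat <- set(evidence$depth == 0L, "NO_COVERAGE")
  cat <- set(evidence$depth < pcfg$min_depth, "LOW_COVERAGE")
  cat <- set(evidence$depth > max_depth, "EXCESS_COVERAGE")
  cat <- set(evidence$alt_count == 0L, "ALT_NOT_SEEN")
  cat <- set(evidence$alt_count == 1L, "ALT_SEEN_ONCE")
  cat <- set(evidence$nearby_snp_count > pcfg$cluster_max_snps, "SNP_CLUSTER")
  cat <- set(evidence$nearest_indel_distance <= pcfg$indel_distance_bp,
             "NEAR_INDEL")
  if (pcfg$has_mapq) {
    cat <- set(evidence$rms_mapq < pcfg$min_rms_mapq, "LOW_RMS_MAPQ")
  } else {
    cat <- set(!evidence$in_unique_region, "NON_UNIQUE")
  }
  if (!is.na(pcfg$min_qual))
    cat <- set(evidence$snp_qual < pcfg$min_qual, "LOW_SNP_QUAL")
  cat[is.na(cat)] <- "UNEXPLAINED"
  cat
}

#' Classify a single missed site
#' @param evidence_row one-row [evidence_table()].
#' @inheritParams classify_missed_sites
#' @return a single [MISS_CATEGORIES] label.
#' @export
classify_missed_site <- function(evidence_row, pcfg, chrom_class = "autosome") {
  classify_missed_sites(evidence_row, pcfg, chrom_class)[1L]
}

#' Summarize miss categories per comparison
#'
#' @param classified data frame with columns `comparison` (e.g. "454+illumina
#'   vs solid") and `category`.
#' @return data frame comparison, category, count, fraction; fractions sum
#'   to 1 within each comparison.
#' @export
summarize_categories <- function(classified) {
  if (nrow(classified) == 0L)
    return(data.frame(comparison = character(), category = character(),
                      count = integer(), fraction = numeric()))
  tab <- as.data.frame(table(comparison = classified$comparison,
                             category = classified$category),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "count"
  tab <- tab[tab$count > 0L, , drop = FALSE]
  tot <- tapply(tab$count, tab$comparison, sum)
  tab$fraction <- tab$count / as.numeric(tot[tab$comparison])
  tab <- tab[order(tab$comparison, match(tab$category, MISS_CATEGORIES)), ]
  rownames(tab) <- NULL
  tab
}

#' Estimate false positives among one platform's singleton calls
#'
#' A singleton (a location called by exactly one platform) is considered a
#' plausible true variant when, for each of the other platforms, either its
#' coverage at the location was compromised (zero, below the minimum, or
#' above the class maximum) or it observed the alternate allele at least
#' once. Singletons excused by neither condition on some other platform are
#' counted as putative false positives.
#'
#' @param singletons data frame (chrom, pos) of the platform's exclusive
#'   calls.
#' @param others_evidence named list of [evidence_table()]s, one per other
#'   platform, covering every singleton site.
#' @param others_configs named list of [platform_config()]s matching
#'   `others_evidence`.
#' @param config an [analysis_config()] supplying chromosome classes.
#' @return list with `plausible_true`, `putative_fp` and `per_site` (logical
#'   plausible flag per singleton).
#' @export
estimate_false_positives <- function(singletons, others_evidence,
                                     others_configs, config) {
  n <- nrow(singletons)
  if (n == 0L)
    return(list(plausible_true = 0L, putative_fp = 0L, per_site = logical()))
  cls <- chrom_class(singletons$chrom, config)
  ok <- rep(TRUE, n)
  for (nm in names(others_evidence)) {
    ev <- others_evidence[[nm]]
    pcfg <- others_configs[[nm]]
    idx <- match(site_key(singletons$chrom, singletons$pos),
                 site_key(ev$chrom, ev$pos))
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1L]
      stop("no ", nm, " evidence for singleton ", singletons$chrom[bad], ":",
           singletons$pos[bad] + 1L)
    }
    depth <- ev$depth[idx]
    alt <- ev$alt_count[idx]
    compromised <- depth == 0L | depth < pcfg$min_depth |
      depth > max_depth_for_class(pcfg, cls)
    ok <- ok & (compromised | alt >= 1L)
  }
  list(plausible_true = sum(ok), putative_fp = sum(!ok), per_site = ok)
}

#' Match two indel interval sets with slop tolerance
#'
#' Each interval of `a` is matched to at most one interval of `b`: the
#' nearest one (leftmost on ties). An exact match intersects at slop 0; a
#' slop-only match intersects only after symmetric expansion by `slop_bp`;
#' remaining intervals are unmatched. The three categories are disjoint.
#'
#' @param a,b [intervals()] data frames (0-based half-open).
#' @param slop_bp symmetric expansion in bp (>= 0).
#' @return list with counts `n_exact`, `n_slop_only`, `n_unmatched` and an
#'   assignment data frame `matches` (a_index, b_index, gap, type).
#' @export
indel_overlap <- function(a, b, slop_bp) {
  stopifnot(slop_bp >= 0)
  n <- nrow(a)
  type <- rep("unmatched", n)
  b_index <- rep(NA_integer_, n)
  gap_out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    cand <- which(b$chrom == a$chrom[i])
    if (!length(cand)) next
    gap <- pmax(b$start[cand] - a$end[i], a$start[i] - b$end[cand], 0L)
    j <- cand[order(gap, b$start[cand])][1L]
    g <- min(gap)
    overlap0 <- b$start[j] < a$end[i] && b$end[j] > a$start[i]
    overlap_slop <- b$start[j] < a$end[i] + slop_bp &&
      b$end[j] > a$start[i] - slop_bp
    if (overlap0) {
      type[i] <- "exact"; b_index[i] <- j; gap_out[i] <- 0L
    } else if (overlap_slop) {
      type[i] <- "slop_only"; b_index[i] <- j; gap_out[i] <- g
    }
  }
  matches <- data.frame(a_index = seq_len(n), b_index = b_index,
                        gap = gap_out, type = type, stringsAsFactors = FALSE)
  list(n_exact = sum(type == "exact"),
       n_slop_only = sum(type == "slop_only"),
       n_unmatched = sum(type == "unmatched"),
       matches = matches)
}
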