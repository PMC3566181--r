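#' Zygosity from the alternate-allele fraction
#'
#' A call is homozygous when the fraction of reads supporting the alternate
#' allele strictly exceeds the threshold (default 0.8), heterozygous
#' otherwise.
#'
#' @param alt_fraction numeric in [0, 1].
#' @param threshold homozygosity threshold in (0, 1).
#' @return `"hom"` or `"het"` (vectorized).
#' @export
zygosity_call <- function(alt_fraction, threshold = 0.8) {
  stopifnot(all(alt_fraction >= 0 & alt_fraction <= 1),
            threshold > 0, threshold < 1)
  ifelse(alt_fraction > threshold, "hom", "het")
}

#' Apply per-platform call-retention rules
#'
#' A call is retained iff its post-deduplication depth lies inside the
#' inclusive per-chromosome-class bounds, its quality reaches `min_qual`
#' (when the platform reports one), and, on sex and mitochondrial
#' chromosomes, the genotype is homozygous. Rules are evaluated in the fixed
#' order depth-low, depth-high, quality, zygosity-class; the rejection log
#' records the first failing rule per call.
#'
#' @param x a [callset()].
#' @param evidence an [evidence_table()] covering every call site.
#' @param pcfg a [platform_config()].
#' @param config an [analysis_config()] supplying chromosome classes.
#' @return list with `retained` (a [callset()]) and `rejections` (data frame
#'   chrom, pos, rule).
#' @export
apply_platform_filter <- function(x, evidence, pcfg, config) {
  if (nrow(x) == 0L)
    return(list(retained = x,
                rejections = data.frame(chrom = character(), pos = integer(),
                                        rule = character())))
  idx <- match(site_key(x$chrom, x$pos), site_key(evidence$chrom, evidence$pos))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop("no evidence record for site ", x$chrom[bad], ":", x$pos[bad] + 1L)
  }
  ev <- evidence[idx, , drop = FALSE]
  cls <- chrom_class(x$chrom, config)
  max_depth <- max_depth_for_class(pcfg, cls)

  rule <- rep(NA_character_, nrow(x))
  fail <- function(cond, name) ifelse(is.na(rule) & cond, name, rule)
  rule <- fail(ev$depth < pcfg$min_depth, "depth-low")
  rule <- fail(ev$depth > max_depth, "depth-high")
  if (!is.na(pcfg$min_qual)) rule <- fail(x$qual < pcfg$min_qual, "quality")
  rule <- fail(cls %in% c("sex", "mito") & x$genotype != "hom",
               "zygosity-class")

  keep <- is.na(rule)
  df <- as.data.frame(x)
  retained <- callset(df$chrom[keep], df$pos[keep], df$ref[keep],
                      df$alt[keep], df$genotype[keep], df$qual[keep],
                      kind = df$kind[keep], platform_id = platform_id(x))
  rejections <- data.frame(chrom = df$chrom[!keep], pos = df$pos[!keep],
                           rule = rule[!keep], stringsAsFactors = FALSE)
  list(retained = retained, rejections = rejections)
}

#' Derive per-class depth limits from a Poisson coverage model
#'
#' In fixed mode the configured limits are returned unchanged. In model mode
#' autosome limits come from [poisson_depth_bounds()] at the platform's mean
#' depth, sex-chromosome limits from the same bounds at half the mean depth
#' (haploid coverage), and the mitochondrial upper limit is left effectively
#' unbounded (10000).
#'
#' @param mean_depth platform mean autosomal depth.
#' @param alpha Poisson tail probability.
#' @param pcfg a [platform_config()] supplying the fixed limits.
#' @param mode `"fixed"` or `"model"`.
#' @return list with min_depth and per-class max depths.
#' @export
derive_depth_limits <- function(mean_depth, alpha, pcfg, mode = c("fixed", "model")) {
  mode <- match.arg(mode)
  if (mode == "fixed")
    return(list(min_depth = pcfg$min_depth,
                max_depth_autosome = pcfg$max_depth_autosome,
                max_depth_sex = pcfg$max_depth_sex,
                max_depth_mito = pcfg$max_depth_mito))
  stopifnot(mean_depth > 0)
  auto <- poisson_depth_bounds(mean_depth, alpha)
  sex <- poisson_depth_bounds(mean_depth / 2, alpha)
  list(min_depth = unname(auto["min_depth"]),
       max_depth_autosome = unname(auto["max_depth"]),
       max_depth_sex = unname(sex["max_depth"]),
       max_depth_mito = 10000L)
}
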