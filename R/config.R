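#' Per-platform filtering thresholds
#'
#' Thresholds used both to retain calls (`apply_platform_filter`) and to
#' classify why a platform missed a site (`classify_missed_sites`). Depth
#' bounds are inclusive on both ends. `min_qual = NA` disables the quality
#' rule (callers that report no comparable quality). `has_mapq = FALSE` marks
#' aligners without mapping qualities; such platforms use the uniqueness flag
#' in place of the RMS-mapping-quality rule.
#'
#' @param min_depth,max_depth_autosome,max_depth_sex,max_depth_mito inclusive
#'   depth bounds per chromosome class.
#' @param min_qual minimum call quality, or NA to disable.
#' @param hom_fraction_threshold a call is homozygous when the alternate
#'   fraction strictly exceeds this value.
#' @param has_mapq does the aligner report mapping qualities?
#' @param cluster_window_bp,cluster_max_snps SNP-cluster rule: more than
#'   `cluster_max_snps` other candidates within `cluster_window_bp`.
#' @param indel_distance_bp miss-classification rule: within this distance of
#'   a high-quality indel.
#' @param min_rms_mapq miss-classification rule: RMS mapping quality below
#'   this value.
#' @return list of class `platform_config`.
#' @export
platform_config <- function(min_depth = 4L, max_depth_autosome = 60L,
                            max_depth_sex = 45L, max_depth_mito = 10000L,
                            min_qual = 20, hom_fraction_threshold = 0.8,
                            has_mapq = TRUE, cluster_window_bp = 10L,
                            cluster_max_snps = 2L, indel_distance_bp = 3L,
                            min_rms_mapq = 25) {
  cfg <- list(min_depth = as.integer(min_depth),
              max_depth_autosome = as.integer(max_depth_autosome),
              max_depth_sex = as.integer(max_depth_sex),
              max_depth_mito = as.integer(max_depth_mito),
              min_qual = as.numeric(min_qual),
              hom_fraction_threshold = as.numeric(hom_fraction_threshold),
              has_mapq = isTRUE(has_mapq),
              cluster_window_bp = as.integer(cluster_window_bp),
              cluster_max_snps = as.integer(cluster_max_snps),
              indel_distance_bp = as.integer(indel_distance_bp),
              min_rms_mapq = as.numeric(min_rms_mapq))
  with(cfg, {
    stopifnot(min_depth <= max_depth_autosome, min_depth <= max_depth_sex,
              min_depth <= max_depth_mito,
              hom_fraction_threshold > 0, hom_fraction_threshold < 1)
  })
  class(cfg) <- "platform_config"
  cfg
}

#' Default per-platform configurations
#'
#' Three platform archetypes with the thresholds used in the original
#' three-platform study: a pyrosequencing-like caller (depth between 2 and 30
#' on every chromosome class, no comparable call quality, no mapping
#' quality), a short-read caller with depth 4-60 (45 on sex chromosomes,
#' 10000 on the mitochondrion) and minimum quality 20, and a second
#' short-read caller with depth 4-100 (60 on sex chromosomes).
#'
#' @return named list of `platform_config`: `"454"`, `"illumina"`, `"solid"`.
#' @export
default_platform_configs <- function() {
  list(
    `454` = platform_config(min_depth = 2L, max_depth_autosome = 30L,
                            max_depth_sex = 30L, max_depth_mito = 30L,
                            min_qual = NA, has_mapq = FALSE),
    illumina = platform_config(min_depth = 4L, max_depth_autosome = 60L,
                               max_depth_sex = 45L, max_depth_mito = 10000L,
                               min_qual = 20),
    solid = platform_config(min_depth = 4L, max_depth_autosome = 100L,
                            max_depth_sex = 60L, max_depth_mito = 10000L,
                            min_qual = 20)
  )
}

#' Analysis-wide configuration
#'
#' @param platforms named list of [platform_config()] objects. Defaults are
#'   filled in from [default_platform_configs()] for the three archetype
#'   names; unnamed platforms must be given explicitly.
#' @param chrom_classes named character vector mapping every chromosome name
#'   to one of `"autosome"`, `"sex"`, `"mito"`.
#' @param gc_window_bp non-overlapping window size for GC/coverage profiling.
#' @param indel_slop_bp symmetric tolerance for indel interval matching.
#' @param random_seed integer seed recorded with each run.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(platforms = default_platform_configs(),
                            chrom_classes = c(chr1 = "autosome"),
                            gc_window_bp = 50000L, indel_slop_bp = 10L,
                            random_seed = 1L) {
  stopifnot(gc_window_bp > 0, indel_slop_bp >= 0)
  if (!all(chrom_classes %in% c("autosome", "sex", "mito")))
    stop("chrom_classes values must be 'autosome', 'sex' or 'mito'")
  cfg <- list(platforms = platforms,
              chrom_classes = chrom_classes,
              gc_window_bp = as.integer(gc_window_bp),
              indel_slop_bp = as.integer(indel_slop_bp),
              random_seed = as.integer(random_seed))
  class(cfg) <- "analysis_config"
  cfg
}

config_keys <- c("platforms", "chrom_classes", "gc_window_bp",
                 "indel_slop_bp", "random_seed")
platform_keys <- names(formals(platform_config))

#' Load an analysis configuration from a YAML file
#'
#' Unspecified fields are filled with the package defaults: the three
#' archetype platform configurations, a 50-kbp GC window and 10-bp indel
#' slop. Platform entries override the archetype of the same name field by
#' field; new platform names start from the generic short-read defaults.
#'
#' @param path YAML file.
#' @return an [analysis_config()].
#' @export
load_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c(config_keys, "pipeline"))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; valid keys: ", paste(c(config_keys, "pipeline"), collapse = ", "))
  platforms <- default_platform_configs()
  for (nm in names(raw$platforms)) {
    over <- raw$platforms[[nm]]
    bad <- setdiff(names(over), platform_keys)
    if (length(bad))
      stop("unknown platform key(s) for '", nm, "': ",
           paste(bad, collapse = ", "),
           "; valid keys: ", paste(platform_keys, collapse = ", "))
    base <- if (nm %in% names(platforms)) unclass(platforms[[nm]])
            else unclass(platform_config())
    base[names(over)] <- over
    platforms[[nm]] <- do.call(platform_config, base)
  }
  chrom_classes <- if (!is.null(raw$chrom_classes))
    unlist(raw$chrom_classes) else c(chr1 = "autosome")
  cfg <- analysis_config(
    platforms = platforms,
    chrom_classes = chrom_classes,
    gc_window_bp = raw$gc_window_bp %||% 50000L,
    indel_slop_bp = raw$indel_slop_bp %||% 10L,
    random_seed = raw$random_seed %||% 1L)
  cfg$pipeline <- raw$pipeline
  cfg
}

#' Chromosome class lookup
#' @param chrom chromosome names.
#' @param config an [analysis_config()].
#' @return character vector of classes; errors on unmapped chromosomes.
#' @export
chrom_class <- function(chrom, config) {
  cls <- config$chrom_classes[chrom]
  if (anyNA(cls))
    stop("no chromosome class configured for: ",
         paste(unique(chrom[is.na(cls)]), collapse = ", "))
  unname(cls)
}

max_depth_for_class <- function(pcfg, class) {
  unname(c(autosome = pcfg$max_depth_autosome, sex = pcfg$max_depth_sex,
           mito = pcfg$max_depth_mito)[class])
}
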