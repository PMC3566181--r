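pipeline_defaults <- function() {
  list(platforms = c("454", "illumina", "solid"),
       genome_length = 200000L, gc_target = 0.45, gc_sd = 0.1,
       repeat_spec = list(c(2000L, 2L)), snp_rate = 1e-3, indel_rate = 2e-4,
       fragment_length = 100L, uniqueome_divergence = 0,
       solo_miss_per_platform = 30L, exclusive_per_platform = 9L)
}

#' Indel intervals of a callset
#'
#' Converts VCF-anchored indel calls to half-open intervals: a deletion of k
#' bases anchored at pos spans `[pos + 1, pos + 1 + k)`; an insertion is
#' assigned the unit interval after its anchor base.
#'
#' @param x a [callset()].
#' @return an [intervals()] data frame.
#' @export
indel_intervals <- function(x) {
  ind <- as.data.frame(x)[x$kind != "substitution", , drop = FALSE]
  if (nrow(ind) == 0L) return(intervals())
  del <- ind$kind == "deletion"
  end <- ifelse(del, ind$pos + nchar(ind$ref), ind$pos + 2L)
  intervals(ind$chrom, ind$pos + 1L, end)
}

#' Run the full concordance analysis end to end
#'
#' simulate -> filter -> uniqueome -> venn -> classify -> estimate false
#' positives -> report, as one reproducible run. Deterministic given the
#' configuration and seed; every stage's outputs are written to the run
#' directory and a machine-readable JSON report is produced. Stage timings
#' and record counts go to stderr and `run.log` only, so reports from
#' identical runs are byte-identical.
#'
#' @param config_path YAML configuration file (see [load_config()]); the
#'   optional `pipeline` section controls the synthetic study (genome length,
#'   GC target, variant rates, fragment length).
#' @param out_dir run directory; defaults to `runs/<config md5>-seed<seed>`
#'   under the current directory.
#' @param seed overrides the configured random seed when non-NULL.
#' @return the run report (list), invisibly also written to
#'   `report.json`.
#' @export
run_full_analysis <- function(config_path, out_dir = NULL, seed = NULL) {
  cfg <- load_config(config_path)
  if (!is.null(seed)) cfg$random_seed <- as.integer(seed)
  pl <- utils::modifyList(pipeline_defaults(), cfg$pipeline %||% list())
  if (is.null(out_dir)) {
    hash <- substr(unname(tools::md5sum(config_path)), 1L, 8L)
    out_dir <- file.path("runs", paste0(hash, "-seed", cfg$random_seed))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "run.log")
  cat("", file = logfile)
  log_stage <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%OS2"), " ", ...)
    message(msg)
    cat(msg, "\n", file = logfile, append = TRUE)
  }
  stop_stage <- function(stage, e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)

  seed0 <- cfg$random_seed
  wanted <- unlist(pl$platforms)
  models <- default_platform_models()[wanted]
  if (anyNA(names(models)))
    stop("pipeline platforms must be among: ",
         paste(names(default_platform_models()), collapse = ", "))
  missing_cfg <- setdiff(wanted, names(cfg$platforms))
  if (length(missing_cfg))
    stop("no platform config for: ", paste(missing_cfg, collapse = ", "))

  # --- simulate ---------------------------------------------------------
  t0 <- Sys.time()
  sim <- tryCatch({
    ref <- generate_reference(pl$genome_length, pl$gc_target,
                              repeat_spec = pl$repeat_spec, seed = seed0,
                              gc_sd = pl$gc_sd)
    truth <- plant_truth_variants(ref, pl$snp_rate, pl$indel_rate,
                                  seed = seed0 + 1L)
    study <- simulate_study(truth, ref, models, cfg, seed = seed0 + 2L,
                            solo_miss_per_platform = pl$solo_miss_per_platform,
                            exclusive_per_platform = pl$exclusive_per_platform)
    list(ref = ref, truth = truth, study = study)
  }, error = function(e) stop_stage("simulate", e))
  write_fasta(sim$ref$sequence, file.path(out_dir, "reference.fa"))
  write_variant_calls(sim$truth, file.path(out_dir, "truth.vcf"))
  for (p in names(sim$study)) {
    write_variant_calls(sim$study[[p]]$callset,
                        file.path(out_dir, paste0(p, ".calls.vcf")))
    write_evidence(sim$study[[p]]$evidence,
                   file.path(out_dir, paste0(p, ".evidence.tsv")))
    utils::write.table(sim$study[[p]]$labels,
                       file.path(out_dir, paste0(p, ".labels.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  log_stage("simulate: ", nrow(sim$truth), " truth variants, ",
            length(sim$study), " platforms (",
            round(as.numeric(Sys.time() - t0, units = "secs"), 1), "s)")

  # --- coverage summaries ----------------------------------------------
  t0 <- Sys.time()
  coverage <- tryCatch(lapply(names(models), function(p) {
    depths <- simulate_depth(sim$ref, models[[p]], cfg$gc_window_bp,
                             seed = seed0 + 10L + match(p, names(models)))
    dup <- mark_duplicates(sim$study[[p]]$alignments)
    win <- gc_coverage_windows(sim$ref$sequence, depths, cfg$gc_window_bp)
    utils::write.table(win, file.path(out_dir, paste0(p, ".gc_windows.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    hist <- depth_histogram(depths)
    utils::write.table(data.frame(depth = hist$depth, fraction = hist$fraction),
                       file.path(out_dir, paste0(p, ".depth_hist.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(platform = p,
         mean_coverage = round(compute_mean_coverage(sum(depths),
                                                     nchar(sim$ref$sequence[[1L]])), 2),
         duplicate_reads = dup$duplicate_count,
         gc_bias_slope = round(fit_gc_bias(win)$slope, 3))
  }), error = function(e) stop_stage("coverage", e))
  names(coverage) <- names(models)
  log_stage("coverage: profiled ", length(coverage), " platforms (",
            round(as.numeric(Sys.time() - t0, units = "secs"), 1), "s)")

  # --- filter -----------------------------------------------------------
  filtered <- tryCatch(lapply(names(models), function(p) {
    res <- apply_platform_filter(sim$study[[p]]$callset,
                                 sim$study[[p]]$evidence,
                                 cfg$platforms[[p]], cfg)
    utils::write.table(res$rejections,
                       file.path(out_dir, paste0(p, ".rejections.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res
  }), error = function(e) stop_stage("filter", e))
  names(filtered) <- names(models)
  log_stage("filter: retained ",
            paste(vapply(filtered, function(f) nrow(f$retained), integer(1)),
                  collapse = "/"), " calls")

  # --- uniqueome --------------------------------------------------------
  t0 <- Sys.time()
  uniq <- tryCatch(
    uniqueome(sim$ref$sequence, pl$fragment_length, pl$uniqueome_divergence),
    error = function(e) stop_stage("uniqueome", e))
  write_bed(uniq, file.path(out_dir, "uniqueome.bed"))
  log_stage("uniqueome: ", nrow(uniq), " intervals (",
            round(as.numeric(Sys.time() - t0, units = "secs"), 1), "s)")

  # --- venn -------------------------------------------------------------
  subs_only <- function(cs) {
    df <- as.data.frame(cs)[cs$kind == "substitution", , drop = FALSE]
    callset(df$chrom, df$pos, df$ref, df$alt, df$genotype, df$qual,
            kind = df$kind, platform_id = platform_id(cs))
  }
  sub_sets <- lapply(filtered, function(f) subs_only(f$retained))
  part <- tryCatch(venn_partition(sub_sets),
                   error = function(e) stop_stage("venn", e))
  cells <- venn_cell_sizes(part)
  totals <- aggregate_platform_totals(cells)
  part_filtered <- venn_partition(lapply(sub_sets, filter_by_regions, uniq))
  cells_filtered <- venn_cell_sizes(part_filtered)
  log_stage("venn: union ", totals$union, ", discordant ", totals$discordant)

  # --- classify ---------------------------------------------------------
  classified <- tryCatch({
    out <- lapply(names(models), function(p) {
      miss <- part$sites[!grepl(paste0("(^|\\+)", p, "($|\\+)"),
                                part$sites$cell), , drop = FALSE]
      if (nrow(miss) == 0L) return(NULL)
      ev <- sim$study[[p]]$evidence
      idx <- match(site_key(miss$chrom, miss$pos), site_key(ev$chrom, ev$pos))
      if (anyNA(idx))
        stop("missing evidence for ", sum(is.na(idx)), " sites on ", p)
      cat_ <- classify_missed_sites(ev[idx, , drop = FALSE], cfg$platforms[[p]],
                                    chrom_class(miss$chrom, cfg))
      data.frame(chrom = miss$chrom, pos = miss$pos,
                 comparison = paste(miss$cell, "vs", p),
                 platform = p, category = cat_, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }, error = function(e) stop_stage("classify", e))
  if (is.null(classified))
    classified <- data.frame(chrom = character(), pos = integer(),
                             comparison = character(), platform = character(),
                             category = character())
  utils::write.table(classified, file.path(out_dir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  category_summary <- summarize_categories(classified)
  log_stage("classify: ", nrow(classified), " missed (site, platform) pairs")

  # --- false positives --------------------------------------------------
  fp <- tryCatch(lapply(names(models), function(p) {
    single <- part$sites[part$sites$cell == p, , drop = FALSE]
    others <- setdiff(names(models), p)
    est <- estimate_false_positives(
      single[, c("chrom", "pos")],
      lapply(stats::setNames(others, others),
             function(q) sim$study[[q]]$evidence),
      cfg$platforms[others], cfg)
    list(platform = p, singletons = nrow(single),
         plausible_true = est$plausible_true, putative_fp = est$putative_fp)
  }), error = function(e) stop_stage("false_positives", e))
  names(fp) <- names(models)

  # --- indels -----------------------------------------------------------
  indels <- tryCatch({
    prs <- utils::combn(names(models), 2L, simplify = FALSE)
    out <- lapply(prs, function(pq) {
      ov <- indel_overlap(indel_intervals(filtered[[pq[1]]]$retained),
                          indel_intervals(filtered[[pq[2]]]$retained),
                          cfg$indel_slop_bp)
      list(pair = paste(pq, collapse = " vs "), n_exact = ov$n_exact,
           n_slop_only = ov$n_slop_only, n_unmatched = ov$n_unmatched)
    })
    stats::setNames(out, vapply(out, `[[`, character(1), "pair"))
  }, error = function(e) stop_stage("indels", e))

  report <- list(
    tool = "concordkit",
    version = as.character(utils::packageVersion("concordkit")),
    seed = seed0,
    config = yaml::read_yaml(config_path),
    coverage = coverage,
    venn_cells = as.list(cells),
    platform_totals = as.list(totals$platform_totals),
    union_size = totals$union,
    discordant = totals$discordant,
    venn_cells_uniqueome_filtered = as.list(cells_filtered),
    category_summary = category_summary,
    false_positive_estimates = fp,
    indel_overlap = indels)

  # internal consistency: cell sums reproduce per-platform callset sizes
  for (p in names(models)) {
    stopifnot(totals$platform_totals[[p]] == nrow(sub_sets[[p]]))
  }
  if (nrow(category_summary)) {
    fr <- tapply(category_summary$fraction, category_summary$comparison, sum)
    stopifnot(all(abs(fr - 1) < 1e-9))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  log_stage("report written to ", file.path(out_dir, "report.json"))
  invisible(report)
}
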