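# End-to-end pipeline and configuration. A single config (YAML or JSON)
# drives simulate -> classify -> annotate -> delcand -> popwindows ->
# flag-denovo and a summary report with conservation checks.

#' Pipeline configuration
#'
#' @param sim named list of [sim_config()] overrides (the `seed` below is
#'   injected automatically).
#' @param filters named list of [filter_config()] overrides.
#' @param delcand named list: `category`, `repeat_class`, `min_alignability`,
#'   `ratio_bound`, `max_gap`, `min_cluster_size`.
#' @param window_size genomic window size in bp for the PCA (default 1e6).
#' @param recurrence_min de novo flagging recurrence threshold (default 2).
#' @param seed single master seed; every stage seed derives from it.
#' @return object of class `triomic_pipeline_config` (a validated list that
#'   round-trips through YAML/JSON serialization unchanged).
#' @export
pipeline_config <- function(sim = list(), filters = list(), delcand = list(),
                            window_size = 1e6, recurrence_min = 2, seed = 1L) {
  cfg <- list(sim = sim, filters = filters, delcand = delcand,
              window_size = window_size, recurrence_min = recurrence_min,
              seed = as.integer(seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "triomic_pipeline_config")
}

#' Validate a pipeline configuration before any stage runs
#' @param cfg configuration list.
#' @return the config, invisibly; stops with a descriptive error otherwise.
#' @export
validate_pipeline_config <- function(cfg) {
  fl <- utils::modifyList(list(dp_fraction = 0.25, gq_min = 30, ab_min = 0.25),
                          cfg$filters %||% list())
  if (fl$ab_min < 0 || fl$ab_min > 1) stop("invalid filters: ab_min must be in [0, 1]")
  if (fl$dp_fraction < 0 || fl$dp_fraction > 1) {
    stop("invalid filters: dp_fraction must be in [0, 1]")
  }
  if (!is.null(cfg$window_size) && cfg$window_size <= 0) {
    stop("window_size must be positive")
  }
  if (!is.null(cfg$recurrence_min) && cfg$recurrence_min < 1) {
    stop("recurrence_min must be >= 1")
  }
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration from YAML or JSON
#' @param path `.yaml`/`.yml` or `.json` file with the [pipeline_config()]
#'   fields.
#' @return a `triomic_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, raw[intersect(names(raw),
                                         names(formals(pipeline_config)))])
}

#' Run the full pipeline on a simulated cohort
#'
#' Executes simulate, classify, annotate, delcand, popwindows and flag-denovo
#' in order, writing per-stage outputs under `out_dir`, and returns a report
#' with cohort totals and internal conservation checks.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param use_files when `TRUE` (default) the simulated cohort is written to
#'   and re-read from VCF/PED/track files, exercising the file interfaces;
#'   `FALSE` keeps the cohort in memory (faster for large simulations).
#' @return report list (also written as `report.json`): stage record counts,
#'   cohort summary totals, and logical conservation checks.
#' @export
run_all <- function(config = pipeline_config(seed = 1L), out_dir = tempfile("triomic_run_"),
                    use_files = TRUE) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_args <- utils::modifyList(config$sim %||% list(), list(seed = config$seed))
  scfg <- do.call(sim_config, sim_args)
  fcfg <- do.call(filter_config, config$filters %||% list())

  message("stage simulate: generating cohort")
  cohort <- simulate_trios(scfg)
  trios <- cohort$trios
  if (use_files) {
    paths <- write_cohort(cohort, file.path(out_dir, "sim"))
    message("stage classify: detecting MIC from ", paths$vcf)
    records <- detect_mic(paths$vcf, paths$ped, cfg = fcfg)
    repeats <- read_repeat_track(paths$repeats)
    align <- read_alignability_track(paths$alignability)
  } else {
    message("stage classify: detecting MIC in memory")
    records <- detect_mic_cohort(cohort, trios, cfg = fcfg)
    rp <- cohort$tracks$repeats
    repeats <- GenomicRanges::GRanges(rp$chrom, IRanges::IRanges(rp$start + 1L, rp$end),
                                      repeat_class = rp$repeat_class, name = rp$name)
    al <- cohort$tracks$alignability
    align <- GenomicRanges::GRanges(al$chrom, IRanges::IRanges(al$start + 1L, al$end),
                                    score = al$score)
  }
  log <- attr(records, "log")
  message("stage classify: ", nrow(records), " MIC records (",
          sum(records$pass), " pass filters)")

  coverage <- sample_mean_coverage(cohort)
  message("stage annotate")
  records <- annotate_mic(records, repeats = repeats, alignability = align,
                          coverage = coverage, trios = trios)
  write_mic(records, file.path(out_dir, "mic.annot.tsv"))
  summaries <- summarize_by_signature(records)

  message("stage delcand")
  dc_args <- config$delcand %||% list()
  crit <- deletion_criteria(
    category = dc_args$category %||% "MATERNAL_DEL",
    repeat_class = dc_args$repeat_class %||% NULL,
    min_alignability = dc_args$min_alignability %||% 1.0,
    ratio_bound = dc_args$ratio_bound %||% NULL)
  cands <- select_candidates(records, crit)
  regions <- cluster_candidates(cands, max_gap = dc_args$max_gap %||% 10000,
                                min_cluster_size = dc_args$min_cluster_size %||% 2)
  write_regions_bed(regions, file.path(out_dir, "regions.bed"))

  message("stage popwindows")
  parents <- unique(c(trios$mother, trios$father))
  ref_labels <- stats::setNames(cohort$ancestry_pcs$population,
                                cohort$ancestry_pcs$sample)
  assignments <- assign_ancestry(
    as.data.frame(cohort$ancestry_pcs[cohort$ancestry_pcs$sample %in% parents,
                                      c("sample", "PC1", "PC2", "PC3")]),
    reference = ref_labels, k = nrow(scfg$populations), seed = config$seed)
  groups <- group_trios(trios, assignments)
  windows <- make_windows(scfg$genome, window_size = config$window_size %||% 1e6)
  mat_del <- aggregate_counts(records, windows, "deletion", trio_ids = trios$trio_id)
  mat_non <- aggregate_counts(records, windows, "nondeletion", trio_ids = trios$trio_id)
  pca <- tryCatch(run_mic_pca(mat_del), error = function(e) NULL)
  top <- if (!is.null(pca) && ncol(pca$loadings) >= 2) {
    top_windows(pca, windows, component = 2, k = 10)
  } else NULL
  tracks <- write_population_tracks(records, groups,
                                    out_prefix = file.path(out_dir, "pop"))

  message("stage flag-denovo")
  cand_dn <- records[signature == "1,0,0" & pass == TRUE,
                     .(chrom, pos, ref, alt, sample = trio_id)]
  flagged <- if (nrow(cand_dn) > 0) {
    flag_denovo(intersect_candidates(cand_dn, tracks), regions = regions,
                recurrence_min = config$recurrence_min %||% 2)
  } else NULL
  if (!is.null(flagged)) {
    data.table::fwrite(flagged, file.path(out_dir, "denovo_flags.tsv"), sep = "\t")
  }

  # conservation checks
  pass_snv <- records[pass == TRUE & var_class == "SNV"]
  checks <- list(
    window_matrix_totals = sum(mat_del) == nrow(pass_snv[deletion_category != "NONE"]) &&
      sum(mat_non) == nrow(pass_snv[deletion_category == "NONE"]),
    track_counts_bounded = all(vapply(names(tracks), function(p) {
      n_pop <- sum(groups$population == p, na.rm = TRUE)
      nrow(tracks[[p]]) == 0 || max(tracks[[p]]$value) <= n_pop
    }, logical(1))),
    all_mic_attributed = all(attribute_mic(records, cohort$truth) != "unexplained"))

  report <- list(
    seed = config$seed,
    n_trios = nrow(trios),
    stage_counts = list(
      sites_simulated = nrow(cohort$sites),
      mic_raw = nrow(records), mic_pass = sum(records$pass),
      skipped = log,
      delcand_candidates = nrow(cands), delcand_regions = nrow(regions),
      populations = as.list(table(groups$population)),
      denovo_candidates = if (is.null(flagged)) 0L else nrow(flagged),
      denovo_flagged_error = if (is.null(flagged)) 0L else
        sum(flagged$verdict == "LIKELY_ERROR")),
    totals = summaries$totals,
    pca = if (is.null(pca)) NULL else list(
      explained = pca$explained[seq_len(min(3, length(pca$explained)))],
      top_pc2_windows = if (is.null(top)) NULL else top$window_id),
    checks = checks)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE)
  if (!all(unlist(checks))) {
    warning("one or more conservation checks failed; see report.json")
  }
  invisible(report)
}
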