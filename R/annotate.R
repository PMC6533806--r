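# Genomic-context and trio-level annotations for MIC records: repeat class,
# offset within SINEs, alignability, normalized parental depth ratio,
# single-bp indel flag, and per-signature summaries.

.records_gr <- function(records) {
  # MIC are treated as point loci anchored at POS (1-based), including indels
  GenomicRanges::GRanges(records$chrom, IRanges::IRanges(records$pos, records$pos))
}

#' Annotate MIC records with the overlapping repeat class
#'
#' When several repeat intervals overlap a position, the shortest one wins
#' (most specific, mirroring nested RepeatMasker elements); ties break to the
#' leftmost start. Positions outside any repeat get class `"NONE"`.
#'
#' @param records MIC record table.
#' @param repeats `GRanges` from [read_repeat_track()] (or equivalent, with a
#'   `repeat_class` metadata column).
#' @return the records with columns `repeat_class`, and `sine_offset` (0-based
#'   nt offset from the repeat start, SINE overlaps only, `NA` otherwise).
#' @export
overlap_repeats <- function(records, repeats) {
  records <- data.table::as.data.table(records)
  if (BiocGenerics::is.unsorted(repeats, ignore.strand = TRUE)) {
    warning("repeat track not sorted; sorting internally")
    repeats <- GenomicRanges::sort(repeats, ignore.strand = TRUE)
  }
  hits <- GenomicRanges::findOverlaps(.records_gr(records), repeats,
                                      ignore.strand = TRUE)
  ht <- data.table::data.table(
    q = S4Vectors::queryHits(hits),
    width = BiocGenerics::width(repeats)[S4Vectors::subjectHits(hits)],
    start0 = BiocGenerics::start(repeats)[S4Vectors::subjectHits(hits)] - 1L,
    class = repeats$repeat_class[S4Vectors::subjectHits(hits)])
  data.table::setorder(ht, q, width, start0)
  best <- ht[!duplicated(q)]
  records[, repeat_class := "NONE"]
  records[, sine_offset := NA_integer_]
  records[best$q, repeat_class := best$class]
  sine <- best[class == "SINE"]
  records[sine$q, sine_offset := pos1_to_0(pos) - sine$start0]
  records[]
}

#' Offset of an MIC within a SINE element
#'
#' @param pos 1-based MIC position(s).
#' @param sine_start 0-based start(s) of the overlapping SINE interval.
#' @param sine_end exclusive end(s); used only to validate containment.
#' @return integer offset(s) from the repeat start, in [0, length - 1].
#' @export
#' @examples
#' sine_offset(1001, 1000, 1300)  # 0: first base of the element
sine_offset <- function(pos, sine_start, sine_end) {
  p0 <- pos1_to_0(pos)
  if (any(p0 < sine_start | p0 >= sine_end)) {
    stop("position outside the SINE interval")
  }
  as.integer(p0 - sine_start)
}

#' Alignability score at MIC positions
#'
#' @param records MIC record table.
#' @param track `GRanges` from [read_alignability_track()] (sorted,
#'   non-overlapping, numeric `score`).
#' @return the records with an `alignability` column; `NA` where the position
#'   is not covered by the track (excluded from summaries, never imputed).
#' @export
alignability_at <- function(records, track) {
  records <- data.table::as.data.table(records)
  hits <- GenomicRanges::findOverlaps(.records_gr(records), track,
                                      ignore.strand = TRUE, select = "first")
  records[, alignability := ifelse(is.na(hits), NA_real_, track$score[hits])]
  records[]
}

#' Normalized maternal-to-paternal read-depth ratio
#'
#' `(mother_dp / maternal mean coverage) / (father_dp / paternal mean
#' coverage)`. Within a hemizygous deletion inherited from the mother the
#' ratio is expected near 0.5; near 2 for a paternal deletion; near 1 when
#' both or neither parent carries a deletion.
#'
#' @param mother_dp,father_dp read depths at the site.
#' @param maternal_mean_cov,paternal_mean_cov per-sample mean coverages (> 0).
#' @return numeric ratio; `NA` where `father_dp` is 0 (flagged, excluded from
#'   medians downstream).
#' @export
#' @examples
#' depth_ratio(20, 40, 40, 40)  # 0.5
depth_ratio <- function(mother_dp, father_dp, maternal_mean_cov, paternal_mean_cov) {
  if (any(maternal_mean_cov <= 0, na.rm = TRUE) ||
      any(paternal_mean_cov <= 0, na.rm = TRUE)) {
    stop("mean coverages must be > 0")
  }
  num <- mother_dp / maternal_mean_cov
  den <- father_dp / paternal_mean_cov
  ifelse(!is.na(den) & den > 0, num / den, NA_real_)
}

#' Attach all annotations to MIC records
#'
#' Driver combining [overlap_repeats()], [alignability_at()], [depth_ratio()]
#' and the single-bp indel flag.
#'
#' @param records MIC record table from [detect_mic()].
#' @param repeats repeat `GRanges` (or `NULL` to skip).
#' @param alignability alignability `GRanges` (or `NULL` to skip).
#' @param coverage named per-sample mean coverage vector; required for depth
#'   ratios.
#' @param trios trio table (`trio_id`, `child`, `mother`, `father`) used to
#'   map records to parental samples for the depth ratio.
#' @return annotated records (`repeat_class`, `sine_offset`, `alignability`,
#'   `depth_ratio`, `is_single_bp_indel`).
#' @export
annotate_mic <- function(records, repeats = NULL, alignability = NULL,
                         coverage = NULL, trios = NULL) {
  records <- data.table::as.data.table(records)
  if (!is.null(repeats)) records <- overlap_repeats(records, repeats)
  if (!is.null(alignability)) records <- alignability_at(records, alignability)
  if (!is.null(coverage) && !is.null(trios)) {
    trios <- data.table::as.data.table(trios)
    mi <- match(records$trio_id, trios$trio_id)
    mat_cov <- coverage[trios$mother[mi]]
    pat_cov <- coverage[trios$father[mi]]
    records[, depth_ratio := depth_ratio(mother_dp, father_dp, mat_cov, pat_cov)]
  }
  records[, is_single_bp_indel := !is.na(indel_len) & indel_len == 1L]
  records[]
}

#' Per-signature summary tables of annotated MIC
#'
#' @param records annotated MIC record table.
#' @param pass_only summarize filtered-pass records only (default `FALSE`).
#' @return list with:
#'   \describe{
#'     \item{summary}{per (signature, var_class): count, median/mean
#'       alignability, median depth ratio, median child AB over heterozygous
#'       child calls, proportion of single-bp indels.}
#'     \item{repeat_props}{per (signature, var_class, repeat_class) proportion
#'       of records (including `NONE`), summing to 1 within each group.}
#'     \item{totals}{cohort totals: MIC count, distinct sites, sites with
#'       exactly one inconsistent trio, mean inconsistent trios per site.}
#'   }
#' @export
summarize_by_signature <- function(records, pass_only = FALSE) {
  records <- data.table::as.data.table(records)
  if (pass_only) records <- records[pass == TRUE]
  if (nrow(records) == 0) {
    return(list(summary = data.table::data.table(),
                repeat_props = data.table::data.table(),
                totals = list(n_mic = 0L, n_sites = 0L,
                              n_singleton_sites = 0L, mean_trios_per_site = NA_real_)))
  }
  has <- function(col) col %in% names(records)
  summary <- records[, {
    list(count = .N,
         median_alignability = if (has("alignability")) stats::median(alignability, na.rm = TRUE) else NA_real_,
         mean_alignability = if (has("alignability")) mean(alignability, na.rm = TRUE) else NA_real_,
         median_depth_ratio = if (has("depth_ratio")) stats::median(depth_ratio, na.rm = TRUE) else NA_real_,
         median_child_ab = stats::median(child_ab[child_gt == 1L], na.rm = TRUE),
         prop_single_bp_indel = if (has("is_single_bp_indel")) mean(is_single_bp_indel) else NA_real_)
  }, by = .(signature_ordinal, signature, deletion_category, var_class)]
  data.table::setorder(summary, signature_ordinal, var_class)

  repeat_props <- if (has("repeat_class")) {
    rp <- records[, .(n = .N), by = .(signature_ordinal, var_class, repeat_class)]
    rp[, prop := n / sum(n), by = .(signature_ordinal, var_class)]
    data.table::setorder(rp, signature_ordinal, var_class, repeat_class)[]
  } else data.table::data.table()

  per_site <- records[, .(n_trios = data.table::uniqueN(trio_id)), by = .(chrom, pos, ref, alt)]
  totals <- list(n_mic = nrow(records),
                 n_sites = nrow(per_site),
                 n_singleton_sites = sum(per_site$n_trios == 1L),
                 mean_trios_per_site = mean(per_site$n_trios))
  list(summary = summary, repeat_props = repeat_props, totals = totals)
}
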