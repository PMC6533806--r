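# Selection of high-confidence inherited-deletion candidate MIC and their
# clustering into per-trio candidate deletion regions.

#' Deletion-candidate selection criteria
#'
#' Mirrors the selection used for maternally inherited deletion candidates in
#' LINEs: deletion-compatible signature, high alignability, and a normalized
#' maternal/paternal depth ratio strictly below 0.5 (maternal) or strictly
#' above 2 (paternal).
#'
#' @param category `"MATERNAL_DEL"` or `"PATERNAL_DEL"`.
#' @param repeat_class optional repeat class restriction (e.g. `"LINE"`), or
#'   `NULL` for no restriction.
#' @param min_alignability minimum alignability score, inclusive (default 1.0;
#'   unique regions score exactly 1).
#' @param ratio_bound depth-ratio bound: upper (strict `<`) for maternal,
#'   lower (strict `>`) for paternal. Default 0.5 for maternal, 2 for
#'   paternal.
#' @param var_class variant class restriction (default `"SNV"`).
#' @return object of class `triomic_delcand_criteria`.
#' @export
deletion_criteria <- function(category = c("MATERNAL_DEL", "PATERNAL_DEL"),
                              repeat_class = NULL, min_alignability = 1.0,
                              ratio_bound = NULL, var_class = "SNV") {
  category <- match.arg(category)
  if (is.null(ratio_bound)) {
    ratio_bound <- if (category == "MATERNAL_DEL") 0.5 else 2.0
  }
  structure(list(category = category, repeat_class = repeat_class,
                 min_alignability = min_alignability, ratio_bound = ratio_bound,
                 var_class = var_class),
            class = "triomic_delcand_criteria")
}

#' Select deletion-candidate MIC records
#'
#' @param records annotated MIC records (need `deletion_category`,
#'   `alignability`, `depth_ratio`, and `repeat_class` if a class filter is
#'   set).
#' @param criteria a [deletion_criteria()].
#' @return the matching subset of `records`.
#' @export
select_candidates <- function(records, criteria = deletion_criteria()) {
  records <- data.table::as.data.table(records)
  keep <- records$deletion_category == criteria$category
  if (!is.null(criteria$var_class)) {
    keep <- keep & records$var_class == criteria$var_class
  }
  if (!is.null(criteria$repeat_class)) {
    keep <- keep & records$repeat_class == criteria$repeat_class
  }
  keep <- keep & !is.na(records$alignability) &
    records$alignability >= criteria$min_alignability
  r <- records$depth_ratio
  keep <- keep & !is.na(r) &
    if (criteria$category == "MATERNAL_DEL") r < criteria$ratio_bound else r > criteria$ratio_bound
  records[which(keep)]
}

#' Cluster candidate MIC into candidate deletion regions
#'
#' Per trio and chromosome, maximal runs of candidates whose consecutive
#' positions are at most `max_gap` apart, with at least `min_cluster_size`
#' members, become regions spanning the member MIC.
#'
#' @param records candidate records from [select_candidates()].
#' @param max_gap maximum inter-MIC gap in bp (default 10000).
#' @param min_cluster_size minimum number of member MIC (default 2; 1 admits
#'   isolated candidates).
#' @return `data.table` of regions: `chrom`, `start`/`end` (0-based
#'   half-open, spanning member positions), `trio_id`, `parent_of_origin`
#'   (`"maternal"`/`"paternal"`), `n_mic`, `positions` (comma-joined 1-based
#'   member positions).
#' @export
cluster_candidates <- function(records, max_gap = 10000, min_cluster_size = 2) {
  records <- data.table::as.data.table(records)
  if (nrow(records) == 0) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), trio_id = character(),
                                  parent_of_origin = character(), n_mic = integer(),
                                  positions = character()))
  }
  stopifnot(length(unique(records$deletion_category)) <= 1L)
  data.table::setorder(records, trio_id, chrom, pos)
  records[, gap := c(Inf, diff(pos)), by = .(trio_id, chrom)]
  records[, cluster := cumsum(gap > max_gap), by = .(trio_id, chrom)]
  regions <- records[, .(
    start = pos1_to_0(min(pos)), end = max(pos),
    parent_of_origin = ifelse(deletion_category[1L] == "MATERNAL_DEL",
                              "maternal", "paternal"),
    n_mic = .N,
    positions = paste(pos, collapse = ",")
  ), by = .(trio_id, chrom, cluster)]
  regions <- regions[n_mic >= min_cluster_size]
  regions[, cluster := NULL]
  data.table::setcolorder(regions, c("chrom", "start", "end", "trio_id",
                                     "parent_of_origin", "n_mic", "positions"))
  data.table::setorder(regions, chrom, start, trio_id)
  regions[]
}

#' Write candidate deletion regions as BED6
#'
#' name = `trio_id:parent`, score = number of member MIC.
#'
#' @param regions regions from [cluster_candidates()].
#' @param path output BED path.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.table::as.data.table(regions)[, .(
    chrom, start, end,
    name = paste(trio_id, parent_of_origin, sep = ":"),
    score = n_mic, strand = ".")]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a candidate deletion regions BED6 written by [write_regions_bed()]
#' @param path BED path.
#' @return `data.table` with `chrom`, `start`, `end`, `trio_id`,
#'   `parent_of_origin`, `n_mic`.
#' @export
read_regions_bed <- function(path) {
  bed <- data.table::fread(path, header = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  bed[, c("trio_id", "parent_of_origin") := data.table::tstrsplit(name, ":", fixed = TRUE)]
  bed[, .(chrom, start, end, trio_id, parent_of_origin, n_mic = score)]
}
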