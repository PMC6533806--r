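# Annotation of candidate de novo mutations with population MIC recurrence
# and deterministic flagging of likely false positives.

#' Read a candidate de novo mutation table
#'
#' @param path TSV with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `sample` (header optional, this column order assumed without one), or a
#'   VCF whose records each carry a single candidate (sample taken from the
#'   only genotyped sample with an alternate allele).
#' @return `data.table` with `chrom`, `pos`, `ref`, `alt`, `sample`.
#' @export
read_denovo_candidates <- function(path) {
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path)) {
    vcf <- VariantAnnotation::readVcf(path)
    gt <- VariantAnnotation::geno(vcf)$GT
    carrier <- apply(gt, 1L, function(r) {
      hit <- which(grepl("1", r, fixed = TRUE))
      if (length(hit) >= 1L) colnames(gt)[hit[1L]] else NA_character_
    })
    rr <- SummarizedExperiment::rowRanges(vcf)
    return(data.table::data.table(
      chrom = as.character(GenomeInfoDb::seqnames(rr)),
      pos = BiocGenerics::start(rr),
      ref = as.character(VariantAnnotation::ref(vcf)),
      alt = vapply(VariantAnnotation::alt(vcf), function(a) as.character(a)[1L], character(1)),
      sample = carrier))
  }
  tab <- data.table::fread(path, header = "auto")
  data.table::setnames(tab, 1:5, c("chrom", "pos", "ref", "alt", "sample"))
  tab[, .(chrom = as.character(chrom), pos = as.integer(pos),
          ref = as.character(ref), alt = as.character(alt),
          sample = as.character(sample))]
}

#' Intersect candidates with population MIC tracks
#'
#' Exact-position (chrom + pos) match of each candidate against each
#' population bedGraph; a track interval of width one covering `pos - 1`
#' matches.
#'
#' @param candidates candidate table ([read_denovo_candidates()]).
#' @param tracks named list of population track tables (`chrom`, `start`,
#'   `end`, `value`) as from [write_population_tracks()] or
#'   [read_bedgraph()].
#' @return candidates with one `mic_<population>` count column per track and
#'   `mic_total` (their sum).
#' @export
intersect_candidates <- function(candidates, tracks) {
  out <- data.table::as.data.table(candidates)
  total <- rep(0, nrow(out))
  for (p in names(tracks)) {
    tr <- data.table::as.data.table(tracks[[p]])
    key <- paste(tr$chrom, tr$end)  # end == 1-based position for point rows
    cnt <- tr$value[match(paste(out$chrom, out$pos), key)]
    cnt[is.na(cnt)] <- 0
    out[, (paste0("mic_", p)) := cnt]
    total <- total + cnt
  }
  out[, mic_total := total]
  out[]
}

#' Flag candidate de novo mutations
#'
#' Flags:
#' \describe{
#'   \item{RECURRENT_MIC}{the position is Mendelian-inconsistent in at least
#'     `recurrence_min` trios across the population tracks (systematic-error
#'     behaviour: true de novo mutations are expected to be rare and
#'     non-recurrent).}
#'   \item{DELETION_SIGNATURE_REGION}{the position falls inside a candidate
#'     deletion region, or the candidate's own trio genotype triple is
#'     deletion-compatible (an inherited deletion must be ruled out).}
#'   \item{REPEAT_OVERLAP}{the candidate has a repeat-class annotation other
#'     than `"NONE"` (only assessed when `repeat_class` is supplied).}
#' }
#' Verdict: `LIKELY_ERROR` if RECURRENT_MIC; otherwise `REVIEW` if any other
#' flag; otherwise `KEEP`. The verdict is a deterministic function of the
#' flags and is monotone in the MIC count.
#'
#' @param candidates candidates with `mic_total` from
#'   [intersect_candidates()].
#' @param regions optional deletion-region table ([cluster_candidates()] or
#'   [read_regions_bed()]).
#' @param trio_genotypes optional per-candidate trio genotype codes: columns
#'   `child_gt`, `mother_gt`, `father_gt` aligned with `candidates`.
#' @param repeat_class optional per-candidate repeat class vector (from
#'   [overlap_repeats()]).
#' @param recurrence_min MIC-trio count at which a candidate is considered
#'   recurrent (default 2).
#' @return candidates with `flags` (comma-joined) and `verdict`.
#' @export
flag_denovo <- function(candidates, regions = NULL, trio_genotypes = NULL,
                        repeat_class = NULL, recurrence_min = 2) {
  out <- data.table::as.data.table(candidates)
  if (!"mic_total" %in% names(out)) {
    stop("candidates lack mic_total; run intersect_candidates() first")
  }
  recurrent <- out$mic_total >= recurrence_min
  in_region <- rep(FALSE, nrow(out))
  if (!is.null(regions) && nrow(regions) > 0) {
    rg <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1L, regions$end))
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$pos, out$pos)),
      rg, select = "first")
    in_region <- !is.na(hits)
  }
  del_triple <- rep(FALSE, nrow(out))
  if (!is.null(trio_genotypes)) {
    tg <- data.table::as.data.table(trio_genotypes)
    ok <- stats::complete.cases(tg[, .(child_gt, mother_gt, father_gt)])
    if (any(ok)) {
      sig <- classify_signature(tg$child_gt[ok], tg$mother_gt[ok], tg$father_gt[ok])
      del_triple[ok] <- !is.na(sig$deletion_category) & sig$deletion_category != "NONE"
    }
  }
  in_repeat <- if (!is.null(repeat_class)) {
    !is.na(repeat_class) & repeat_class != "NONE"
  } else rep(FALSE, nrow(out))

  flags <- mapply(function(r, d, rp) {
    f <- c(if (r) "RECURRENT_MIC",
           if (d) "DELETION_SIGNATURE_REGION",
           if (rp) "REPEAT_OVERLAP")
    paste(f, collapse = ",")
  }, recurrent, in_region | del_triple, in_repeat)
  out[, flags := flags]
  out[, verdict := ifelse(recurrent, "LIKELY_ERROR",
                          ifelse(nzchar(flags), "REVIEW", "KEEP"))]
  out[]
}
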