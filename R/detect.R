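# Mendelian-inconsistency detection: shared matrix core used both by the VCF
# file route and by in-memory simulated cohorts.

.mic_columns <- function() {
  c("trio_id", "chrom", "pos", "ref", "alt", "var_class", "indel_len",
    "signature_ordinal", "signature", "deletion_category",
    "child_gt", "mother_gt", "father_gt",
    "child_dp", "child_gq", "child_ab",
    "mother_dp", "mother_gq", "mother_ab",
    "father_dp", "father_gq", "father_ab",
    "pass", "fail_reasons")
}

.empty_mic <- function() {
  out <- data.table::data.table(
    trio_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), var_class = character(),
    indel_len = integer(), signature_ordinal = integer(),
    signature = character(), deletion_category = character(),
    child_gt = integer(), mother_gt = integer(), father_gt = integer(),
    child_dp = numeric(), child_gq = numeric(), child_ab = numeric(),
    mother_dp = numeric(), mother_gq = numeric(), mother_ab = numeric(),
    father_dp = numeric(), father_gq = numeric(), father_ab = numeric(),
    pass = logical(), fail_reasons = character())
  out
}

#' Detect Mendelian-inconsistent calls in an in-memory cohort
#'
#' One record is emitted per (trio, biallelic autosomal site) whose
#' (child, mother, father) genotype triple violates Mendelian transmission.
#' Sites where any member's genotype is missing are skipped for that trio.
#' Records failing quality filters are kept with `pass = FALSE`, so raw and
#' filtered counts are both derivable. Filters are applied to all three
#' members; one failing member fails the record.
#'
#' @param cohort a `triomic_cohort` (from [read_trio_vcf()] or
#'   [simulate_trios()]).
#' @param trios trio table as from [read_ped()] (`trio_id`, `child`,
#'   `mother`, `father`).
#' @param cfg a [filter_config()].
#' @param coverage optional named vector of per-sample mean coverage;
#'   computed with [sample_mean_coverage()] when `NULL`.
#' @return `data.table` of MIC records (one row per violation), with the skip
#'   counters of the cohort plus `n_missing_skipped` attached as attribute
#'   `"log"`.
#' @export
detect_mic_cohort <- function(cohort, trios, cfg = filter_config(), coverage = NULL) {
  trios <- data.table::as.data.table(trios)
  missing_samples <- setdiff(unique(c(trios$child, trios$mother, trios$father)),
                             cohort$samples)
  if (length(missing_samples) > 0) {
    stop("pedigree samples absent from VCF/cohort: ",
         paste(missing_samples, collapse = ", "))
  }
  if (is.null(coverage)) coverage <- sample_mean_coverage(cohort)
  sites <- cohort$sites
  n_missing <- 0L
  out <- vector("list", nrow(trios))
  for (i in seq_len(nrow(trios))) {
    ch <- trios$child[i]; mo <- trios$mother[i]; fa <- trios$father[i]
    gc <- cohort$geno[, ch]; gm <- cohort$geno[, mo]; gf <- cohort$geno[, fa]
    called <- !is.na(gc) & !is.na(gm) & !is.na(gf)
    n_missing <- n_missing + sum(!called)
    # inconsistency test on called triples (vectorized dose bounds)
    min_dose <- (gm == 2L) + (gf == 2L)
    max_dose <- (gm >= 1L) + (gf >= 1L)
    mic <- called & (gc < min_dose | gc > max_dose)
    if (!any(mic)) next
    idx <- which(mic)
    sig <- classify_signature(gc[idx], gm[idx], gf[idx])
    rec <- data.table::data.table(
      trio_id = trios$trio_id[i],
      sites[idx, .(chrom, pos, ref, alt, var_class, indel_len)],
      signature_ordinal = sig$ordinal,
      signature = sig$signature,
      deletion_category = sig$deletion_category,
      child_gt = gc[idx], mother_gt = gm[idx], father_gt = gf[idx],
      child_dp = cohort$dp[idx, ch], child_gq = cohort$gq[idx, ch],
      child_ab = allele_balance(cohort$ad_ref[idx, ch], cohort$ad_alt[idx, ch]),
      mother_dp = cohort$dp[idx, mo], mother_gq = cohort$gq[idx, mo],
      mother_ab = allele_balance(cohort$ad_ref[idx, mo], cohort$ad_alt[idx, mo]),
      father_dp = cohort$dp[idx, fa], father_gq = cohort$gq[idx, fa],
      father_ab = allele_balance(cohort$ad_ref[idx, fa], cohort$ad_alt[idx, fa]))
    fc <- apply_quality_filters(rec$child_dp, rec$child_gq, rec$child_ab,
                                rec$child_gt, coverage[[ch]], cfg)
    fm <- apply_quality_filters(rec$mother_dp, rec$mother_gq, rec$mother_ab,
                                rec$mother_gt, coverage[[mo]], cfg)
    ff <- apply_quality_filters(rec$father_dp, rec$father_gq, rec$father_ab,
                                rec$father_gt, coverage[[fa]], cfg)
    rec[, pass := fc$pass & fm$pass & ff$pass]
    tag <- function(x, who) ifelse(nzchar(x), paste0(who, ":", x), "")
    reasons <- apply(cbind(tag(fc$reasons, "child"), tag(fm$reasons, "mother"),
                           tag(ff$reasons, "father")), 1L,
                     function(r) paste(r[nzchar(r)], collapse = ";"))
    rec[, fail_reasons := reasons]
    out[[i]] <- rec
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out) == 0) .empty_mic() else data.table::rbindlist(out)
  data.table::setattr(res, "log",
                      c(cohort$log, list(n_missing_skipped = n_missing)))
  res[]
}

#' Detect Mendelian-inconsistent calls from VCF and PED files
#'
#' File-based front end of [detect_mic_cohort()].
#'
#' @param vcf path to a multi-sample VCF (v4.2, FORMAT GT/DP/GQ/AD).
#' @param ped path to a 6-column PED file (or a pedigree data.frame).
#' @param cfg a [filter_config()].
#' @param coverage optional named per-sample mean coverage vector or the path
#'   to a two-column coverage TSV; computed from the VCF when `NULL`.
#' @return `data.table` of MIC records; see [detect_mic_cohort()].
#' @export
detect_mic <- function(vcf, ped, cfg = filter_config(), coverage = NULL) {
  cohort <- read_trio_vcf(vcf)
  trios <- read_ped(ped)
  if (is.character(coverage) && length(coverage) == 1L && file.exists(coverage)) {
    coverage <- read_coverage_table(coverage)
  }
  detect_mic_cohort(cohort, trios, cfg = cfg, coverage = coverage)
}

#' Write MIC records to a TSV file
#' @param records MIC record table.
#' @param path output path.
#' @export
write_mic <- function(records, path) {
  data.table::fwrite(records, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read MIC records from a TSV written by [write_mic()]
#' @param path input path.
#' @return `data.table` of MIC records.
#' @export
read_mic <- function(path) {
  data.table::fread(path, sep = "\t", na.strings = "NA")
}
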