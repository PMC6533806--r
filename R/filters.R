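#' Genotype-call quality filter configuration
#'
#' Thresholds applied to individual genotype calls before an MIC is counted as
#' filtered-pass: read depth at least `dp_fraction` of the sample's mean
#' coverage, genotype quality at least `gq_min`, and (for heterozygous calls
#' only, when `apply_ab_to_het_only`) allele balance at least `ab_min`. All
#' comparisons are inclusive (`>=`).
#'
#' @param dp_fraction fraction of the sample mean coverage required as minimum
#'   depth (default 0.25).
#' @param gq_min minimum genotype quality (default 30).
#' @param ab_min minimum allele balance, alt reads / (ref + alt reads)
#'   (default 0.25).
#' @param apply_ab_to_het_only logical; restrict the AB filter to heterozygous
#'   calls (default `TRUE`).
#' @return An object of class `triomic_filter_config`.
#' @export
filter_config <- function(dp_fraction = 0.25, gq_min = 30, ab_min = 0.25,
                          apply_ab_to_het_only = TRUE) {
  stopifnot(dp_fraction >= 0, dp_fraction <= 1, gq_min >= 0,
            ab_min >= 0, ab_min <= 1, is.logical(apply_ab_to_het_only))
  structure(list(dp_fraction = dp_fraction, gq_min = gq_min, ab_min = ab_min,
                 apply_ab_to_het_only = apply_ab_to_het_only),
            class = "triomic_filter_config")
}

#' Apply quality filters to genotype calls
#'
#' @param dp,gq numeric vectors of read depth and genotype quality.
#' @param ab numeric vector of allele balance; `NA` where undefined
#'   (no informative reads).
#' @param genotype integer genotype codes 0/1/2.
#' @param sample_mean_coverage positive mean coverage of the sample the calls
#'   belong to (scalar or vector).
#' @param cfg a [filter_config()].
#' @return `data.table` with logical `pass` and character `reasons`
#'   (semicolon-joined subset of `"DP"`, `"GQ"`, `"AB"`, `"AB undefined"`;
#'   empty string when passing).
#' @export
#' @examples
#' apply_quality_filters(dp = 10, gq = 30, ab = NA, genotype = 0,
#'                       sample_mean_coverage = 40, cfg = filter_config())
apply_quality_filters <- function(dp, gq, ab, genotype, sample_mean_coverage,
                                  cfg = filter_config()) {
  if (any(sample_mean_coverage <= 0)) stop("sample_mean_coverage must be > 0")
  n <- max(length(dp), length(gq), length(ab), length(genotype))
  dp <- rep_len(dp, n); gq <- rep_len(gq, n); ab <- rep_len(ab, n)
  genotype <- rep_len(as.integer(genotype), n)
  mc <- rep_len(sample_mean_coverage, n)
  ok_dp <- !is.na(dp) & dp >= cfg$dp_fraction * mc
  ok_gq <- !is.na(gq) & gq >= cfg$gq_min
  need_ab <- if (cfg$apply_ab_to_het_only) genotype == 1L else rep(TRUE, n)
  ab_undef <- need_ab & is.na(ab)
  ok_ab <- !need_ab | (!is.na(ab) & ab >= cfg$ab_min)
  pass <- ok_dp & ok_gq & ok_ab
  reasons <- character(n)
  add <- function(reasons, bad, tag) {
    reasons[bad] <- ifelse(nzchar(reasons[bad]), paste(reasons[bad], tag, sep = ";"), tag)
    reasons
  }
  reasons <- add(reasons, !ok_dp, "DP")
  reasons <- add(reasons, !ok_gq, "GQ")
  reasons <- add(reasons, !ok_ab & !ab_undef, "AB")
  reasons <- add(reasons, ab_undef, "AB undefined")
  data.table::data.table(pass = pass, reasons = reasons)
}

#' Allele balance from allelic depths
#'
#' @param ad_ref,ad_alt reference- and alternate-supporting read counts.
#' @return `ad_alt / (ad_ref + ad_alt)`; `NA` where the denominator is 0 or
#'   either count is missing.
#' @export
allele_balance <- function(ad_ref, ad_alt) {
  tot <- ad_ref + ad_alt
  ifelse(!is.na(tot) & tot > 0, ad_alt / tot, NA_real_)
}
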