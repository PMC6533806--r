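# File input/output: PED pedigrees, multi-sample VCF (via VariantAnnotation),
# repeat BED, alignability bedGraph/wig (via rtracklayer), coverage tables.

# Coordinate convention: VCF positions are 1-based; BED/bedGraph intervals are
# 0-based half-open. All conversions go through these two helpers.
pos1_to_0 <- function(pos) as.integer(pos) - 1L
pos0_to_1 <- function(start0) as.integer(start0) + 1L

.is_autosome <- function(chrom) {
  !grepl("^(chr)?(x|y|m|mt|w|z)$", tolower(chrom))
}

#' Read a 6-column PED pedigree and extract trios
#'
#' PED columns are family, individual, father, mother, sex, phenotype ("0"
#' denotes a missing parent). A trio is any individual with both parents
#' present. Note PED lists father before mother, while signature triples are
#' ordered (child, mother, father).
#'
#' @param path path to a whitespace-delimited PED file, or a data.frame with
#'   the six PED columns.
#' @return `data.table` with columns `trio_id`, `child`, `mother`, `father`.
#' @export
read_ped <- function(path) {
  ped <- if (is.data.frame(path)) {
    data.table::as.data.table(path)
  } else {
    data.table::fread(path, header = FALSE, colClasses = "character")
  }
  if (ncol(ped) < 6) stop("PED file must have 6 columns")
  data.table::setnames(ped, 1:6,
                       c("family", "individual", "father", "mother", "sex", "phenotype"))
  trios <- ped[father != "0" & mother != "0",
               .(trio_id = family, child = individual, mother = mother, father = father)]
  if (nrow(trios) == 0) stop("no complete trios in pedigree")
  bad <- trios[child == mother | child == father | mother == father]
  if (nrow(bad) > 0) stop("pedigree has trios with non-distinct members: ",
                          paste(bad$trio_id, collapse = ", "))
  if (anyDuplicated(trios$trio_id)) {
    trios[, trio_id := ifelse(duplicated(trio_id) | duplicated(trio_id, fromLast = TRUE),
                              paste(trio_id, child, sep = "."), trio_id)]
  }
  trios[]
}

.gt_to_code <- function(gt) {
  # unphase, then code by alt-allele dose; anything with missing or >1 alt
  # allele index is NA (half-calls count as missing)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- rep(NA_integer_, length(gt))
  code[gt %in% c("0/0")] <- 0L
  code[gt %in% c("0/1", "1/0")] <- 1L
  code[gt %in% c("1/1")] <- 2L
  code
}

.ad_split <- function(ad, nsite, nsample) {
  # AD comes back from readVcf either as a 3-d array (uniform Number=R) or a
  # matrix of integer lists; normalize to ref/alt matrices
  if (is.array(ad) && length(dim(ad)) == 3L) {
    return(list(ref = ad[, , 1L, drop = TRUE], alt = ad[, , 2L, drop = TRUE]))
  }
  refm <- matrix(NA_integer_, nsite, nsample)
  altm <- matrix(NA_integer_, nsite, nsample)
  vals <- as.list(ad)
  len <- lengths(vals)
  first <- vapply(vals, function(v) if (length(v) >= 1L) v[[1L]] else NA_integer_, integer(1))
  second <- vapply(vals, function(v) if (length(v) >= 2L) v[[2L]] else NA_integer_, integer(1))
  refm[] <- ifelse(len >= 2L, first, NA_integer_)
  altm[] <- ifelse(len >= 2L, second, NA_integer_)
  list(ref = refm, alt = altm)
}

#' Read a multi-sample trio VCF into the internal cohort representation
#'
#' Uses `VariantAnnotation::readVcf()`. Keeps biallelic, non-symbolic,
#' autosomal records; multiallelic, symbolic and non-autosomal records are
#' skipped with logged counts.
#'
#' @param path VCF file (plain or bgzipped), FORMAT fields GT, DP, GQ, AD.
#' @return A `triomic_cohort` list: `sites` (data.table chrom/pos/ref/alt/
#'   var_class/indel_len), matrices `geno`, `dp`, `gq`, `ad_ref`, `ad_alt`
#'   (sites x samples), `samples`, and a `log` of skip counts.
#' @export
read_trio_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  nalt <- S4Vectors::elementNROWS(VariantAnnotation::fixed(vcf)$ALT)
  keep_bi <- nalt == 1L
  n_multi <- sum(!keep_bi)
  vcf <- vcf[keep_bi]
  chrom <- chrom[keep_bi]

  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  vc <- classify_variant(ref, alt)
  keep_sym <- !is.na(vc$var_class)
  n_symbolic <- sum(!keep_sym)
  keep_auto <- .is_autosome(chrom)
  n_nonauto <- sum(!keep_auto & keep_sym)
  keep <- keep_sym & keep_auto
  vcf <- vcf[keep]
  sites <- data.table::data.table(
    chrom = chrom[keep],
    pos = BiocGenerics::start(SummarizedExperiment::rowRanges(vcf)),
    ref = ref[keep], alt = alt[keep],
    var_class = vc$var_class[keep], indel_len = vc$indel_len[keep]
  )

  g <- VariantAnnotation::geno(vcf)
  if (!all(c("GT", "DP", "GQ", "AD") %in% names(g))) {
    stop("VCF must provide FORMAT fields GT, DP, GQ and AD")
  }
  gt <- g$GT
  geno <- matrix(.gt_to_code(gt), nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  dp <- matrix(as.numeric(g$DP), nrow(gt), ncol(gt), dimnames = dimnames(gt))
  gq <- matrix(as.numeric(g$GQ), nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ad <- .ad_split(g$AD, nrow(gt), ncol(gt))
  ad_ref <- matrix(as.numeric(ad$ref), nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ad_alt <- matrix(as.numeric(ad$alt), nrow(gt), ncol(gt), dimnames = dimnames(gt))

  structure(list(sites = sites, geno = geno, dp = dp, gq = gq,
                 ad_ref = ad_ref, ad_alt = ad_alt,
                 samples = colnames(gt),
                 log = list(skipped_multiallelic = n_multi,
                            skipped_symbolic = n_symbolic,
                            skipped_non_autosomal = n_nonauto)),
            class = "triomic_cohort")
}

#' Per-sample mean coverage from a cohort
#'
#' Mean of FORMAT/DP over all retained autosomal sites with a called genotype,
#' the default stand-in for "average coverage" in the depth filter and in
#' normalized parental depth ratios.
#'
#' @param cohort a `triomic_cohort`.
#' @return named numeric vector, one mean per sample.
#' @export
sample_mean_coverage <- function(cohort) {
  dp <- cohort$dp
  dp[is.na(cohort$geno)] <- NA_real_
  colMeans(dp, na.rm = TRUE)
}

#' Read a per-sample coverage table
#'
#' @param path two-column TSV `sample`, `mean_coverage` (header optional).
#' @return named numeric vector.
#' @export
read_coverage_table <- function(path) {
  tab <- data.table::fread(path, header = "auto")
  data.table::setnames(tab, 1:2, c("sample", "mean_coverage"))
  stats::setNames(as.numeric(tab$mean_coverage), tab$sample)
}

#' Read a repeat annotation track
#'
#' Accepts BED6+ with the repeat class in column 7, or a RepeatMasker-style
#' TSV containing `genoName`/`genoStart`/`genoEnd`/`repClass` (UCSC rmsk
#' dialect). Classes outside the fixed vocabulary map to `"Other"`.
#'
#' @param path file path.
#' @return `GRanges` with metadata columns `repeat_class`, `name`.
#' @export
read_repeat_track <- function(path) {
  vocab <- c("SINE", "LINE", "LTR", "Simple_repeat", "Satellite",
             "Low_complexity", "DNA", "Other")
  header_line <- readLines(path, n = 1L)
  if (grepl("genoName", header_line)) {
    tab <- data.table::fread(path)
    gr <- GenomicRanges::GRanges(tab$genoName,
                                 IRanges::IRanges(tab$genoStart + 1L, tab$genoEnd),
                                 repeat_class = tab$repClass,
                                 name = if ("repName" %in% names(tab)) tab$repName else NA_character_)
  } else {
    tab <- data.table::fread(path, header = FALSE)
    if (ncol(tab) < 7) stop("repeat BED must have >= 7 columns (class in column 7)")
    data.table::setnames(tab, 1:7, c("chrom", "start", "end", "name", "score",
                                     "strand", "repeat_class"))
    gr <- GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$start + 1L, tab$end),
                                 strand = ifelse(tab$strand %in% c("+", "-"), tab$strand, "*"),
                                 repeat_class = tab$repeat_class, name = tab$name)
  }
  cls <- as.character(gr$repeat_class)
  cls[!cls %in% vocab] <- "Other"
  gr$repeat_class <- cls
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  gr
}

#' Read an alignability track (bedGraph or fixed-step wig)
#'
#' Scores are clipped to [0, 1]. Overlapping input intervals are not allowed.
#'
#' @param path bedGraph (4 columns) or wig file.
#' @return `GRanges` with a numeric `score` column, sorted, non-overlapping.
#' @export
read_alignability_track <- function(path) {
  gr <- rtracklayer::import(path)
  if (is.null(gr$score)) stop("alignability track has no score column")
  gr$score <- pmin(pmax(as.numeric(gr$score), 0), 1)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (!IRanges::isDisjoint(gr)) stop("alignability track intervals overlap")
  gr
}

#' Write a bedGraph track
#'
#' @param tab data.frame/data.table with columns `chrom`, `start` (0-based),
#'   `end` (exclusive), `value`.
#' @param path output path.
#' @param track_line optional UCSC `track` header line (`NULL` to omit).
#' @export
write_bedgraph <- function(tab, path, track_line = NULL) {
  tab <- data.table::as.data.table(tab)[, .(chrom, start, end, value)]
  data.table::setorder(tab, chrom, start)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(track_line)) writeLines(track_line, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph track written by [write_bedgraph()] or UCSC tools
#'
#' @param path bedGraph path (a leading `track` line is tolerated).
#' @return `data.table` with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (grepl("^track", first)) 1L else 0L
  tab <- data.table::fread(path, header = FALSE, skip = skip)
  data.table::setnames(tab, 1:4, c("chrom", "start", "end", "value"))
  tab[]
}
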