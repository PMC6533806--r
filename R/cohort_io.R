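# Serialization of a simulated cohort to standard file formats: VCF v4.2,
# PED, coverage table, ancestry PCs, repeat BED, alignability bedGraph and a
# ground-truth JSON. Output is byte-deterministic for a fixed cohort.

.format_vcf_entries <- function(cohort) {
  gt_codes <- c("0/0", "0/1", "1/1")
  g <- cohort$geno
  ent <- paste0(gt_codes[g + 1L], ":",
                formatC(cohort$dp, format = "d"), ":",
                formatC(cohort$gq, format = "d"), ":",
                formatC(cohort$ad_ref, format = "d"), ",",
                formatC(cohort$ad_alt, format = "d"))
  ent[is.na(g)] <- "./.:.:.:.,."
  matrix(ent, nrow(g), ncol(g), dimnames = dimnames(g))
}

#' Write a simulated cohort as a multi-sample VCF v4.2
#'
#' FORMAT fields GT, DP, GQ, AD; missing genotypes written as `./.`.
#'
#' @param cohort a `triomic_cohort` from [simulate_trios()].
#' @param path output path (plain text).
#' @export
write_cohort_vcf <- function(cohort, path) {
  genome <- if (!is.null(cohort$tracks)) cohort$tracks$genome else NULL
  contigs <- if (!is.null(genome)) {
    sprintf("##contig=<ID=%s,length=%d>", genome$chrom, as.integer(genome$length))
  } else {
    sprintf("##contig=<ID=%s>", unique(cohort$sites$chrom))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=triomic-simulator",
    contigs,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t"))
  ent <- .format_vcf_entries(cohort)
  fixed <- paste(cohort$sites$chrom, cohort$sites$pos, ".", cohort$sites$ref,
                 cohort$sites$alt, ".", "PASS", ".", "GT:DP:GQ:AD", sep = "\t")
  body <- do.call(paste, c(list(fixed), as.data.frame(ent), list(sep = "\t")))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a cohort pedigree as a 6-column PED file
#' @param cohort a `triomic_cohort` with a `trios` table.
#' @param path output path.
#' @export
write_cohort_ped <- function(cohort, path) {
  tr <- cohort$trios
  ped <- data.table::rbindlist(list(
    data.table::data.table(family = tr$trio_id, individual = tr$child,
                           father = tr$father, mother = tr$mother,
                           sex = 0L, phenotype = 0L),
    data.table::data.table(family = tr$trio_id, individual = tr$mother,
                           father = "0", mother = "0", sex = 2L, phenotype = 0L),
    data.table::data.table(family = tr$trio_id, individual = tr$father,
                           father = "0", mother = "0", sex = 1L, phenotype = 0L)))
  utils::write.table(ped, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write all outputs of a simulated cohort to a directory
#'
#' Writes `cohort.vcf`, `trios.ped`, `coverage.tsv` (per-sample mean DP
#' observed over called sites), `ancestry_pcs.tsv`, `repeats.bed` (BED6 +
#' repeat class in column 7), `alignability.bedGraph` and `truth.json`.
#'
#' @param cohort a `triomic_cohort` from [simulate_trios()].
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    ped = file.path(dir, "trios.ped"),
    coverage = file.path(dir, "coverage.tsv"),
    pcs = file.path(dir, "ancestry_pcs.tsv"),
    repeats = file.path(dir, "repeats.bed"),
    alignability = file.path(dir, "alignability.bedGraph"),
    truth = file.path(dir, "truth.json"))
  write_cohort_vcf(cohort, paths$vcf)
  write_cohort_ped(cohort, paths$ped)
  cov <- sample_mean_coverage(cohort)
  utils::write.table(
    data.frame(sample = names(cov), mean_coverage = sprintf("%.4f", cov)),
    paths$coverage, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$ancestry_pcs, paths$pcs, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rp <- cohort$tracks$repeats
  utils::write.table(
    data.frame(chrom = rp$chrom, start = rp$start, end = rp$end,
               name = rp$name, score = 0L, strand = rp$strand,
               class = rp$repeat_class),
    paths$repeats, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  al <- cohort$tracks$alignability
  write_bedgraph(data.table::data.table(chrom = al$chrom, start = al$start,
                                        end = al$end, value = al$score),
                 paths$alignability)
  truth <- cohort$truth
  jsonlite::write_json(
    list(deletions = truth$deletions, errors = truth$errors,
         de_novos = truth$de_novos,
         callability = list(sample = names(truth$callability),
                            value = unname(truth$callability))),
    paths$truth, dataframe = "columns", digits = NA)
  paths
}
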