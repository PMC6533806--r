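# Hand-built small fixtures, independent of the simulator.

# entries: list of character vectors (one per site), each of length
# length(samples), formatted "GT:DP:GQ:AD"
write_test_vcf <- function(path, samples, sites, entries,
                           contigs = c(chr1 = 1000000L)) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(sites)), function(i) {
    paste(c(sites$chrom[i], sites$pos[i], ".", sites$ref[i], sites$alt[i],
            ".", "PASS", ".", "GT:DP:GQ:AD", entries[[i]]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# a clean call string for a genotype code at depth dp
call_str <- function(code, dp = 40, gq = 99) {
  switch(code + 1L,
         sprintf("0/0:%d:%d:%d,0", dp, gq, dp),
         sprintf("0/1:%d:%d:%d,%d", dp, gq, dp - dp %/% 2L, dp %/% 2L),
         sprintf("1/1:%d:%d:0,%d", dp, gq, dp))
}

write_test_ped <- function(path, trios) {
  lines <- unlist(lapply(seq_len(nrow(trios)), function(i) {
    with(trios[i, ], c(
      paste(trio_id, child, father, mother, 0, 0, sep = "\t"),
      paste(trio_id, mother, 0, 0, 2, 0, sep = "\t"),
      paste(trio_id, father, 0, 0, 1, 0, sep = "\t")))
  }))
  writeLines(lines, path)
  path
}

# small deterministic simulated cohort shared across tests (cached)
.test_env <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.test_env$small)) {
    cfg <- sim_config(
      populations = data.frame(label = c("EUR", "AMR"), n_trios = c(12L, 12L)),
      genome = data.frame(chrom = c("chr1", "chr2"), length = c(4e5, 4e5)),
      deletion_regions = data.frame(chrom = "chr1", start = 1e5, end = 1.6e5,
                                    freq = 0.5),
      seed = 20240601L)
    .test_env$small <- simulate_trios(cfg)
  }
  .test_env$small
}
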