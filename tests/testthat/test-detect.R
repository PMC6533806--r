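# VCF/PED ingestion and MIC detection on hand-built fixtures.

make_toy <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  samples <- c("C1", "M1", "F1", "C2", "M2", "F2", "C3", "M3", "F3")
  sites <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chrX", "chr1"),
    pos = c(100L, 200L, 300L, 400L, 500L),
    ref = c("A", "C", "G", "T", "A"),
    alt = c("G", "T", "A", "C", "G,T"))
  entries <- list(
    # trio1 MIC (1,0,0); trio2/3 consistent
    c(call_str(1), call_str(0), call_str(0),
      call_str(0), call_str(0), call_str(0),
      call_str(1), call_str(1), call_str(0)),
    # trio2 MIC (0,2,0) all clean
    c(call_str(0), call_str(0), call_str(0),
      call_str(0), call_str(2), call_str(0),
      call_str(0), call_str(0), call_str(0)),
    # trio3 missing child genotype -> skipped for trio3
    c(call_str(0), call_str(0), call_str(0),
      call_str(0), call_str(0), call_str(0),
      "./.:.:.:.,.", call_str(2), call_str(2)),
    # chrX site with an apparent violation: must be skipped (non-autosome)
    c(call_str(1), call_str(0), call_str(0),
      call_str(0), call_str(0), call_str(0),
      call_str(0), call_str(0), call_str(0)),
    # multiallelic: skipped
    c(call_str(1), call_str(0), call_str(0),
      call_str(0), call_str(0), call_str(0),
      call_str(0), call_str(0), call_str(0)))
  vcf <- write_test_vcf(file.path(dir, "toy.vcf"), samples, sites, entries,
                        contigs = c(chr1 = 1000L, chrX = 1000L))
  ped <- write_test_ped(file.path(dir, "toy.ped"),
                        data.frame(trio_id = c("T1", "T2", "T3"),
                                   child = c("C1", "C2", "C3"),
                                   mother = c("M1", "M2", "M3"),
                                   father = c("F1", "F2", "F3")))
  list(vcf = vcf, ped = ped)
}

test_that("detect_mic finds exactly the inconsistent trios and skips the rest", {
  toy <- make_toy()
  rec <- detect_mic(toy$vcf, toy$ped, coverage = setNames(rep(40, 9),
                                                          c("C1", "M1", "F1", "C2", "M2", "F2", "C3", "M3", "F3")))
  expect_equal(nrow(rec), 2L)
  r1 <- rec[rec$trio_id == "T1", ]
  expect_equal(r1$signature, "1,0,0")
  expect_equal(r1$signature_ordinal, 6L)
  expect_equal(r1$deletion_category, "NONE")
  r2 <- rec[rec$trio_id == "T2", ]
  expect_equal(r2$signature_ordinal, 1L)
  expect_equal(r2$deletion_category, "MATERNAL_DEL")
  expect_true(all(rec$pass))
  log <- attr(rec, "log")
  expect_equal(log$skipped_multiallelic, 1L)
  expect_equal(log$skipped_non_autosomal, 1L)
  expect_gte(log$n_missing_skipped, 1L)
})

test_that("records failing filters are kept with pass = FALSE and reasons", {
  dir <- withr::local_tempdir()
  samples <- c("C1", "M1", "F1")
  sites <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "G")
  # (1,0,0) violation; mother low GQ, child het with skewed AB below 0.25
  entries <- list(c("0/1:40:99:35,5", "0/0:40:12:40,0", call_str(0)))
  vcf <- write_test_vcf(file.path(dir, "f.vcf"), samples, sites, entries)
  ped <- write_test_ped(file.path(dir, "f.ped"),
                        data.frame(trio_id = "T1", child = "C1",
                                   mother = "M1", father = "F1"))
  rec <- detect_mic(vcf, ped, coverage = setNames(rep(40, 3), samples))
  expect_equal(nrow(rec), 1L)
  expect_false(rec$pass)
  expect_match(rec$fail_reasons, "mother:GQ")
  expect_match(rec$fail_reasons, "child:AB")
  expect_equal(rec$child_ab, 5 / 40)
})

test_that("pedigree samples absent from the VCF are a hard error", {
  toy <- make_toy()
  ped2 <- withr::local_tempfile(fileext = ".ped")
  write_test_ped(ped2, data.frame(trio_id = "TX", child = "C1",
                                  mother = "M1", father = "NOT_THERE"))
  expect_error(detect_mic(toy$vcf, ped2), "NOT_THERE")
})

test_that("read_ped validates structure and extracts trios", {
  ped <- read_ped(data.frame(fam = "T1", id = "C1", fa = "F1", mo = "M1",
                             sex = 0, ph = 0))
  expect_equal(ped$child, "C1")
  expect_equal(ped$mother, "M1")   # PED order is father-then-mother
  expect_equal(ped$father, "F1")
  expect_error(read_ped(data.frame(f = "T1", i = "C1", fa = "C1", mo = "M1",
                                   s = 0, p = 0)), "non-distinct")
  expect_error(read_ped(data.frame(f = "T1", i = "C1", fa = "0", mo = "0",
                                   s = 0, p = 0)), "no complete trios")
})

test_that("phased and half-called genotypes are normalized", {
  dir <- withr::local_tempdir()
  samples <- c("C1", "M1", "F1")
  sites <- data.frame(chrom = "chr1", pos = c(100L, 200L), ref = "A", alt = "G")
  entries <- list(
    c("1|1:40:99:0,40", "0|1:40:99:20,20", "0|0:40:99:40,0"),  # (2,1,0) MIC
    c("./1:40:99:20,20", call_str(0), call_str(0)))            # half-call: missing
  vcf <- write_test_vcf(file.path(dir, "p.vcf"), samples, sites, entries)
  ped <- write_test_ped(file.path(dir, "p.ped"),
                        data.frame(trio_id = "T1", child = "C1",
                                   mother = "M1", father = "F1"))
  rec <- detect_mic(vcf, ped, coverage = setNames(rep(40, 3), samples))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$signature, "2,1,0")
  expect_equal(rec$signature_ordinal, 11L)
})

test_that("sample mean coverage is the mean DP over called sites", {
  co <- small_cohort()
  cov <- sample_mean_coverage(co)
  expect_equal(names(cov), co$samples)
  # nominal coverage 40, deletions only shave a little off
  expect_true(all(cov > 30 & cov < 50))
  s <- co$samples[1]
  expect_equal(unname(cov[s]),
               mean(co$dp[!is.na(co$geno[, s]), s], na.rm = TRUE))
})

test_that("MIC TSV round-trips through write_mic/read_mic", {
  co <- small_cohort()
  rec <- detect_mic_cohort(co, co$trios)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mic(rec, path)
  back <- read_mic(path)
  expect_equal(nrow(back), nrow(rec))
  expect_equal(back$signature, rec$signature)
  expect_equal(back$pass, rec$pass)
})
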