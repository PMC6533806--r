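# Simulator properties: Mendelian consistency by construction, depth
# conservation in hemizygous regions, error placement, determinism.

test_that("error-free, deletion-free, de-novo-free cohorts have zero MIC", {
  em <- default_error_model()
  em$base_rate <- 0; em$slippage_rate <- 0
  cfg <- sim_config(populations = data.frame(label = "EUR", n_trios = 10L),
                    genome = data.frame(chrom = "chr1", length = 3e5),
                    deletion_regions = data.frame(chrom = "chr1", start = 0L,
                                                  end = 1000L, freq = 0),
                    error_model = em, de_novo_rate = 0, seed = 5L)
  co <- simulate_trios(cfg)
  rec <- detect_mic_cohort(co, co$trios)
  expect_equal(nrow(rec), 0L)
})

test_that("simulated tracks tile the genome and respect element lengths", {
  cfg <- sim_config(populations = data.frame(label = "EUR", n_trios = 2L),
                    genome = data.frame(chrom = "chr1", length = 5e5),
                    deletion_regions = data.frame(chrom = "chr1", start = 0L,
                                                  end = 1000L, freq = 0),
                    seed = 17L)
  tr <- simulate_genome_tracks(cfg)
  sine <- tr$repeats[tr$repeats$repeat_class == "SINE", ]
  expect_gt(nrow(sine), 0)
  expect_true(all(sine$end - sine$start >= 250 & sine$end - sine$start <= 350))
  line <- tr$repeats[tr$repeats$repeat_class == "LINE", ]
  expect_true(all(line$end - line$start >= 500 & line$end - line$start <= 8000))
  # repeats do not overlap; alignability tiles [0, L) exactly once
  expect_true(all(diff(as.matrix(tr$repeats[order(start), .(start, end)]))[, 1] >= 0))
  al <- tr$alignability[order(start)]
  expect_equal(al$start[1], 0L)
  expect_equal(al$end[nrow(al)], 500000L)
  expect_true(all(al$start[-1] == al$end[-nrow(al)]))
  expect_true(all(al$score >= 0 & al$score <= 1))
  # a repeat-free config gives an empty BED and alignability 1 everywhere
  cfg0 <- sim_config(populations = data.frame(label = "EUR", n_trios = 2L),
                     genome = data.frame(chrom = "chr1", length = 1e5),
                     deletion_regions = data.frame(chrom = "chr1", start = 0L,
                                                   end = 100L, freq = 0),
                     repeat_model = NULL, seed = 3L)
  tr0 <- simulate_genome_tracks(cfg0)
  expect_equal(nrow(tr0$repeats), 0L)
  expect_true(all(tr0$alignability$score == 1))
  expect_true(all(tr0$sites$error_rate ==
                    default_error_model()$base_rate * 1))
})

test_that("read depth halves inside hemizygous deletions", {
  em <- default_error_model(); em$base_rate <- 0; em$slippage_rate <- 0
  cfg <- sim_config(populations = data.frame(label = "EUR", n_trios = 60L),
                    genome = data.frame(chrom = "chr1", length = 4e5),
                    deletion_regions = data.frame(chrom = "chr1", start = 1e5,
                                                  end = 2e5, freq = 1,
                                                  carrier_parent = "mother"),
                    error_model = em, de_novo_rate = 0, transmission_prob = 1,
                    callability_range = c(1, 1), seed = 77L)
  co <- simulate_trios(cfg)
  inside <- co$sites$pos > 1e5 & co$sites$pos <= 2e5
  mothers <- co$trios$mother
  dp_in <- mean(co$dp[inside, mothers])
  dp_out <- mean(co$dp[!inside, mothers])
  expect_gt(sum(inside) * length(mothers), 1000)
  expect_equal(dp_in / dp_out, 0.5, tolerance = 0.05 / 0.5)
  # fathers unaffected
  expect_equal(mean(co$dp[inside, co$trios$father]) /
                 mean(co$dp[!inside, co$trios$father]), 1, tolerance = 0.05)
})

test_that("maternal-deletion MIC carry only maternal-deletion signatures", {
  em <- default_error_model(); em$base_rate <- 0; em$slippage_rate <- 0
  cfg <- sim_config(populations = data.frame(label = "EUR", n_trios = 40L),
                    genome = data.frame(chrom = "chr1", length = 3e5),
                    deletion_regions = data.frame(chrom = "chr1", start = 1e5,
                                                  end = 1.8e5, freq = 1,
                                                  carrier_parent = "mother"),
                    error_model = em, de_novo_rate = 0, transmission_prob = 1,
                    seed = 31L)
  co <- simulate_trios(cfg)
  rec <- detect_mic_cohort(co, co$trios)
  expect_gt(nrow(rec), 0)
  expect_true(all(rec$deletion_category == "MATERNAL_DEL"))
  expect_true(all(rec$pos > 1e5 & rec$pos <= 1.8e5))
})

test_that("every detected MIC maps to a truth-set cause", {
  co <- small_cohort()
  rec <- detect_mic_cohort(co, co$trios)
  cause <- attribute_mic(rec, co$truth)
  expect_equal(sum(cause == "unexplained"), 0L)
  expect_true(all(cause %in% c("deletion", "error", "de_novo")))
})

test_that("de novo counts follow the configured binomial rate", {
  n_trios <- 40L
  rate <- 2e-6   # inflated so the expectation is testable at desk scale
  L <- 4e5
  cfg <- sim_config(populations = data.frame(label = "EUR", n_trios = n_trios),
                    genome = data.frame(chrom = "chr1", length = L),
                    deletion_regions = data.frame(chrom = "chr1", start = 0L,
                                                  end = 100L, freq = 0),
                    de_novo_rate = rate, seed = 13L)
  co <- simulate_trios(cfg)
  expected <- rate * L * n_trios
  sd3 <- 3 * sqrt(expected)
  expect_gt(nrow(co$truth$de_novos), expected - sd3)
  expect_lt(nrow(co$truth$de_novos), expected + sd3)
  # de novos are clean child-only hets: all yield (1,0,0) MIC
  rec <- detect_mic_cohort(co, co$trios)
  dn_key <- paste(co$truth$de_novos$trio_id, co$truth$de_novos$pos)
  got <- rec[paste(rec$trio_id, rec$pos) %in% dn_key, ]
  expect_equal(nrow(got), nrow(co$truth$de_novos))
  expect_true(all(got$signature == "1,0,0"))
})

test_that("injected error MIC are enriched in repeats", {
  co <- small_cohort()
  rec <- detect_mic_cohort(co, co$trios)
  cause <- attribute_mic(rec, co$truth)
  err <- rec[cause == "error", ]
  rp <- co$tracks$repeats
  repeats <- GenomicRanges::GRanges(rp$chrom, IRanges::IRanges(rp$start + 1, rp$end),
                                    repeat_class = rp$repeat_class, name = rp$name)
  err <- overlap_repeats(err, repeats)
  repeat_fraction <- sum(rp$end - rp$start) / 8e5
  expect_gt(mean(err$repeat_class != "NONE"), repeat_fraction)
  # non-deletion MIC sit at lower alignability than deletion MIC
  al <- co$tracks$alignability
  track <- GenomicRanges::GRanges(al$chrom, IRanges::IRanges(al$start + 1, al$end),
                                  score = al$score)
  ann <- alignability_at(rec, track)
  m_del <- mean(ann$alignability[ann$deletion_category != "NONE" &
                                   cause == "deletion"], na.rm = TRUE)
  m_err <- mean(ann$alignability[cause == "error"], na.rm = TRUE)
  expect_gt(m_del, m_err)
})

test_that("identical seeds give byte-identical outputs, different seeds differ", {
  cfg <- function(s) sim_config(
    populations = data.frame(label = "EUR", n_trios = 4L),
    genome = data.frame(chrom = "chr1", length = 1e5),
    deletion_regions = data.frame(chrom = "chr1", start = 2e4, end = 4e4,
                                  freq = 0.5),
    seed = s)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  write_cohort(simulate_trios(cfg(123L)), d1)
  write_cohort(simulate_trios(cfg(123L)), d2)
  write_cohort(simulate_trios(cfg(124L)), d3)
  for (f in c("cohort.vcf", "trios.ped", "coverage.tsv", "truth.json",
              "repeats.bed", "alignability.bedGraph", "ancestry_pcs.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_false(identical(readLines(file.path(d1, "cohort.vcf")),
                         readLines(file.path(d3, "cohort.vcf"))))
})

test_that("slippage-driven indel MIC are single-bp by construction", {
  co <- small_cohort()
  rec <- detect_mic_cohort(co, co$trios)
  cause <- attribute_mic(rec, co$truth)
  slip_key <- paste(co$truth$errors[co$truth$errors$type == "slippage", ]$chrom,
                    co$truth$errors[co$truth$errors$type == "slippage", ]$pos)
  slip <- rec[paste(rec$chrom, rec$pos) %in% slip_key, ]
  if (nrow(slip) > 0) {
    expect_true(all(slip$indel_len == 1L))
    expect_true(all(slip$var_class %in% c("INSERTION", "DELETION")))
  }
})
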