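# Ancestry assignment, trio grouping, window tiling, count aggregation, PCA
# and population tracks.

test_that("window tiling is exact with a truncated final window", {
  w <- make_windows(data.frame(chrom = c("chrA", "chrB"),
                               length = c(2500000, 1000000)))
  expect_equal(nrow(w), 4L)
  expect_equal(w[w$chrom == "chrA", ]$start, c(0L, 1000000L, 2000000L))
  expect_equal(w[w$chrom == "chrA", ]$end, c(1000000L, 2000000L, 2500000L))
  expect_equal(w[w$chrom == "chrB", ]$end, 1000000L)
  # every position belongs to exactly one window
  expect_equal(sum(w$end - w$start), 3500000)
  expect_error(make_windows(data.frame(chrom = "c", length = -1)), "positive")
})

test_that("silhouette-gated ancestry assignment recovers separable blobs", {
  set.seed(42)
  pcs <- rbind(matrix(rnorm(60, 0, 0.2), ncol = 3),
               matrix(rnorm(60, 5, 0.2), ncol = 3))
  rownames(pcs) <- paste0("S", 1:40)
  colnames(pcs) <- paste0("PC", 1:3)
  ref <- setNames(rep(c("EUR", "EAS"), each = 20), rownames(pcs))
  asg <- assign_ancestry(pcs, reference = ref, k = 2, seed = 9)
  expect_true(all(asg$silhouette > 0.6))
  expect_equal(asg$ancestry, unname(ref[asg$sample_id]))
  # the silhouette rule is strict: at or below 0.6 means OTHERS
  asg2 <- data.table::copy(asg)
  asg2$silhouette <- c(0.61, 0.60, rep(0.9, 38))
  asg2$ancestry <- ifelse(asg2$silhouette > 0.6, asg2$cluster_label, "OTHERS")
  expect_equal(asg2$ancestry[1], asg2$cluster_label[1])
  expect_equal(asg2$ancestry[2], "OTHERS")
  expect_error(assign_ancestry(pcs[1:3, ], ref, k = 5), "exceeds")
})

test_that("trios group only when both parents share an ancestry label", {
  trios <- data.frame(trio_id = c("T1", "T2", "T3", "T4"),
                      child = paste0("C", 1:4),
                      mother = paste0("M", 1:4), father = paste0("F", 1:4))
  anc <- c(M1 = "EUR", F1 = "EUR", M2 = "EUR", F2 = "AMR",
           M3 = "EUR", F3 = "OTHERS", M4 = "OTHERS", F4 = "OTHERS")
  g <- suppressMessages(group_trios(trios, anc))
  expect_equal(g$population, c("EUR", NA, NA, "OTHERS"))
  expect_equal(attr(g, "n_excluded"), 2L)
  expect_error(group_trios(trios, anc[-1]), "no ancestry")
})

test_that("aggregation conserves counts and matches per-trio totals", {
  co <- small_cohort()
  rec <- detect_mic_cohort(co, co$trios)
  win <- make_windows(data.frame(chrom = c("chr1", "chr2"), length = c(4e5, 4e5)),
                      window_size = 1e5)
  md <- aggregate_counts(rec, win, "deletion", trio_ids = co$trios$trio_id)
  mn <- aggregate_counts(rec, win, "nondeletion", trio_ids = co$trios$trio_id)
  ps <- rec[rec$pass & rec$var_class == "SNV", ]
  expect_equal(sum(md), nrow(ps[ps$deletion_category != "NONE", ]))
  expect_equal(sum(mn), nrow(ps[ps$deletion_category == "NONE", ]))
  # row sums equal per-trio category counts from the classifier
  per_trio <- table(factor(ps[ps$deletion_category != "NONE", ]$trio_id,
                           levels = co$trios$trio_id))
  expect_equal(unname(rowSums(md)), as.vector(per_trio))
  # a record at pos 1,500,00x lands in the second 1e5 window of its chrom
  one <- rec[1, ]
  one$pos <- 150000L; one$chrom <- "chr1"; one$pass <- TRUE; one$var_class <- "SNV"
  m1 <- aggregate_counts(one, win, if (one$deletion_category == "NONE")
    "nondeletion" else "deletion")
  expect_equal(unname(m1[1, win[win$chrom == "chr1" & win$start == 100000, ]$index]), 1L)
  expect_error(aggregate_counts(transform(one, chrom = "chrZZ"), win, "deletion"),
               "absent")
})

test_that("PCA centers, keeps unit-norm loadings and reconstructs the matrix", {
  set.seed(8)
  mat <- matrix(rpois(300, 5), nrow = 30)
  colnames(mat) <- paste0("w", 1:10); rownames(mat) <- paste0("t", 1:30)
  p <- run_mic_pca(mat)
  expect_equal(unname(colSums(p$loadings^2)), rep(1, ncol(p$loadings)))
  # full reconstruction of the centered matrix
  centered <- scale(mat, center = TRUE, scale = FALSE)
  expect_equal(p$scores %*% t(p$loadings), centered,
               tolerance = 1e-8, ignore_attr = TRUE)
  # PC1 sign fixed to correlate positively with row totals
  expect_gte(cor(p$scores[, 1], rowSums(mat)), 0)
  expect_error(run_mic_pca(matrix(3, 4, 4)), "variance")
  # a single varying window concentrates PC1 loading mass on it
  m2 <- matrix(2, 20, 5); m2[, 3] <- rpois(20, 50)
  colnames(m2) <- paste0("w", 1:5)
  p2 <- run_mic_pca(m2)
  expect_equal(unname(which.max(abs(p2$loadings[, 1]))), 3L)
})

test_that("top_windows ranks by absolute loading with genomic tie-break", {
  win <- make_windows(data.frame(chrom = "chr1", length = 3e6))
  mat <- matrix(rpois(60, 5), nrow = 20)
  colnames(mat) <- win$window_id
  p <- run_mic_pca(mat)
  p$loadings[, 2] <- c(0.9, -0.95, 0.1)
  tw <- top_windows(p, win, component = 2, k = 2)
  expect_equal(tw$index, c(2L, 1L))
  expect_equal(nrow(top_windows(p, win, component = 2, k = 0)), 0L)
  expect_equal(nrow(top_windows(p, win, component = 2, k = 99)), 3L)
  expect_error(top_windows(p, win, component = 9), "not computed")
})

test_that("population tracks conserve counts and respect group sizes", {
  co <- small_cohort()
  rec <- detect_mic_cohort(co, co$trios)
  groups <- co$populations
  dir <- withr::local_tempdir()
  tracks <- write_population_tracks(rec, groups,
                                    out_prefix = file.path(dir, "pop"))
  expect_setequal(names(tracks), unique(groups$population))
  pooled <- data.table::as.data.table(rec)[pass == TRUE][
    , .(n = data.table::uniqueN(trio_id)), by = .(chrom, pos)]
  combined <- data.table::rbindlist(tracks)[, .(n = sum(value)), by = .(chrom, end)]
  merged <- merge(pooled, combined, by.x = c("chrom", "pos"),
                  by.y = c("chrom", "end"))
  expect_equal(nrow(merged), nrow(pooled))
  expect_equal(merged$n.x, merged$n.y)
  for (p in names(tracks)) {
    expect_lte(max(tracks[[p]]$value), sum(groups$population == p))
    expect_true(all(diff(order(tracks[[p]]$chrom, tracks[[p]]$start)) == 1))
  }
  # written files parse back identically
  back <- read_bedgraph(file.path(dir, "pop_EUR.bedGraph"))
  expect_equal(back$value, tracks$EUR$value)
})
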