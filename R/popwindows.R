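# Population-level analysis: ancestry assignment by clustering with a
# silhouette acceptance rule, trio grouping, 1 Mb window aggregation of MIC
# counts, PCA to find population-stratifying deletion regions, and
# population-specific bedGraph MIC tracks.

.POPULATIONS <- c("AFR", "AMR", "EAS", "EUR", "SAS", "OTHERS")

#' Assign ancestry from principal-component coordinates
#'
#' Samples are clustered on PCs 1-3 with k-means into `k` clusters. Each
#' cluster is labelled by the majority population among the reference-labelled
#' samples it contains. A sample receives the cluster's population iff its
#' silhouette score exceeds 0.6 (strict), otherwise `"OTHERS"`.
#'
#' @param pcs numeric matrix/data.frame of per-sample PCs (columns PC1..PC3 at
#'   least), rownames = sample ids (or a `sample` column).
#' @param reference named character vector mapping sample ids to known
#'   population labels, used to name clusters; must cover at least one sample
#'   per cluster.
#' @param k number of clusters (default 5, the super-population count).
#' @param silhouette_min silhouette acceptance threshold (default 0.6,
#'   strict `>`).
#' @param seed RNG seed for k-means initialization.
#' @return `data.table` with `sample_id`, `cluster_label`, `silhouette`,
#'   `ancestry`.
#' @export
assign_ancestry <- function(pcs, reference, k = 5, silhouette_min = 0.6,
                            seed = 1L) {
  pcs <- as.data.frame(pcs)
  if ("sample" %in% names(pcs)) {
    rownames(pcs) <- pcs$sample
    pcs$sample <- NULL
  }
  x <- as.matrix(pcs[, seq_len(min(3L, ncol(pcs))), drop = FALSE])
  if (k > nrow(x)) stop("k exceeds the number of samples")
  withr_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  km <- withr_seed(seed, stats::kmeans(x, centers = k, nstart = 25, iter.max = 100))
  sil <- if (k > 1L) {
    cluster::silhouette(km$cluster, stats::dist(x))[, "sil_width"]
  } else rep(1, nrow(x))
  labels <- vapply(seq_len(k), function(cl) {
    ids <- rownames(x)[km$cluster == cl]
    ref <- reference[intersect(ids, names(reference))]
    if (length(ref) == 0) return(NA_character_)
    names(sort(table(ref), decreasing = TRUE))[1L]
  }, character(1))
  if (anyNA(labels)) stop("some clusters contain no reference-labelled sample")
  out <- data.table::data.table(
    sample_id = rownames(x),
    cluster_label = labels[km$cluster],
    silhouette = as.numeric(sil))
  out[, ancestry := ifelse(silhouette > silhouette_min, cluster_label, "OTHERS")]
  out[]
}

#' Group trios by parental ancestry
#'
#' A trio belongs to population P iff both parents are assigned P (including
#' the OTHERS label); trios with discordant parents are excluded and logged.
#'
#' @param trios trio table (`trio_id`, `child`, `mother`, `father`).
#' @param assignments output of [assign_ancestry()] covering all parents, or
#'   a named sample -> ancestry vector.
#' @return `data.table` with `trio_id`, `population`; excluded trios carry
#'   `NA` population. The number excluded is attached as attribute
#'   `"n_excluded"`.
#' @export
group_trios <- function(trios, assignments) {
  trios <- data.table::as.data.table(trios)
  anc <- if (is.data.frame(assignments)) {
    stats::setNames(assignments$ancestry, assignments$sample_id)
  } else assignments
  missing <- setdiff(unique(c(trios$mother, trios$father)), names(anc))
  if (length(missing) > 0) {
    stop("no ancestry assignment for parents: ", paste(missing, collapse = ", "))
  }
  out <- trios[, .(trio_id,
                   population = ifelse(anc[mother] == anc[father],
                                       anc[mother], NA_character_))]
  n_excl <- sum(is.na(out$population))
  if (n_excl > 0) {
    message(n_excl, " trio(s) excluded from population groups (discordant parental ancestry)")
  }
  data.table::setattr(out, "n_excluded", n_excl)
  out[]
}

#' Tile chromosomes into fixed-size genomic windows
#'
#' @param chrom_sizes two-column data.frame/data.table (`chrom`, `length`) or
#'   a named vector of chromosome lengths.
#' @param window_size window width in bp (default 1e6); the last window of
#'   each chromosome is truncated at the chromosome end.
#' @return `data.table` with `chrom`, `start` (0-based), `end` (exclusive),
#'   `index` (1-based over the whole tiling) and `window_id`
#'   ("chrom:start-end").
#' @export
make_windows <- function(chrom_sizes, window_size = 1e6) {
  if (is.data.frame(chrom_sizes)) {
    sl <- stats::setNames(as.numeric(chrom_sizes[[2L]]), as.character(chrom_sizes[[1L]]))
  } else {
    sl <- chrom_sizes
  }
  if (any(sl <= 0)) stop("chromosome lengths must be positive")
  tiles <- GenomicRanges::tileGenome(sl, tilewidth = window_size,
                                     cut.last.tile.in.chrom = TRUE)
  out <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(tiles)),
    start = BiocGenerics::start(tiles) - 1L,
    end = BiocGenerics::end(tiles))
  out[, index := .I]
  out[, window_id := paste0(chrom, ":", start, "-", end)]
  out[]
}

#' Aggregate MIC counts per trio in genomic windows
#'
#' Restricted to filtered-pass SNV records, split by deletion category:
#' `"deletion"` counts records with a deletion-compatible signature,
#' `"nondeletion"` the remaining ones.
#'
#' @param records MIC record table.
#' @param windows window table from [make_windows()].
#' @param category `"deletion"` or `"nondeletion"`.
#' @param trio_ids optional character vector fixing the row set/order (trios
#'   with zero counts included); defaults to trios present in `records`.
#' @return integer matrix trios x windows (dimnames trio ids / window ids).
#' @export
aggregate_counts <- function(records, windows, category = c("deletion", "nondeletion"),
                             trio_ids = NULL) {
  category <- match.arg(category)
  records <- data.table::as.data.table(records)
  records <- records[pass == TRUE & var_class == "SNV"]
  records <- if (category == "deletion") {
    records[deletion_category != "NONE"]
  } else {
    records[deletion_category == "NONE"]
  }
  if (is.null(trio_ids)) trio_ids <- sort(unique(records$trio_id))
  bad_chrom <- setdiff(unique(records$chrom), unique(windows$chrom))
  if (length(bad_chrom) > 0) {
    stop("records on chromosomes absent from the window tiling: ",
         paste(bad_chrom, collapse = ", "))
  }
  # windows tile each chromosome without gaps, so a findInterval on the sorted
  # window starts locates the containing window
  wi <- integer(nrow(records))
  for (ch in unique(records$chrom)) {
    rows <- which(records$chrom == ch)
    w <- windows[chrom == ch][order(start)]
    wi[rows] <- w$index[findInterval(records$pos[rows] - 1L, w$start)]
  }
  mat <- matrix(0L, nrow = length(trio_ids), ncol = nrow(windows),
                dimnames = list(trio_ids, windows$window_id))
  if (nrow(records) > 0) {
    tab <- data.table::data.table(trio = records$trio_id, win = wi)[
      , .(n = .N), by = .(trio, win)]
    tab <- tab[trio %in% trio_ids]
    mat[cbind(match(tab$trio, trio_ids), tab$win)] <- tab$n
  }
  mat
}

#' PCA on a trio-by-window MIC count matrix
#'
#' Column-mean-centered, unscaled PCA. The sign of PC1 is fixed so that PC1
#' scores correlate positively with per-trio total counts (PC1 tracks overall
#' MIC load).
#'
#' @param mat trios x windows count matrix.
#' @param k number of components to retain (default all).
#' @return list with `scores` (trios x k), `loadings` (windows x k, unit
#'   norm), `explained` (variance fractions).
#' @export
run_mic_pca <- function(mat, k = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2) stop("need at least 2 trios and 2 windows")
  if (all(apply(mat, 2L, function(x) stats::var(x) == 0))) {
    stop("no variance in the count matrix")
  }
  p <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  if (is.null(k)) k <- ncol(p$rotation)
  k <- min(k, ncol(p$rotation))
  scores <- p$x[, seq_len(k), drop = FALSE]
  loadings <- p$rotation[, seq_len(k), drop = FALSE]
  tot <- rowSums(mat)
  if (stats::var(tot) > 0 && stats::cor(scores[, 1L], tot) < 0) {
    scores[, 1L] <- -scores[, 1L]
    loadings[, 1L] <- -loadings[, 1L]
  }
  explained <- p$sdev^2 / sum(p$sdev^2)
  list(scores = scores, loadings = loadings, explained = explained[seq_len(k)])
}

#' Top windows by absolute component loading
#'
#' @param pca result of [run_mic_pca()].
#' @param windows window table used to build the matrix.
#' @param component component number (default 2, the population-stratifying
#'   axis).
#' @param k number of windows to return (default 10; all if `k` exceeds the
#'   window count).
#' @return `data.table` of windows ranked by `abs(loading)` descending, ties
#'   broken by genomic order.
#' @export
top_windows <- function(pca, windows, component = 2, k = 10) {
  if (component > ncol(pca$loadings)) stop("component not computed")
  ld <- pca$loadings[, component]
  out <- data.table::as.data.table(windows)[window_id %in% names(ld)]
  out[, loading := ld[window_id]]
  out[, abs_loading := abs(loading)]
  data.table::setorder(out, -abs_loading, index)
  utils::head(out, min(k, nrow(out)))
}

#' Write population-specific MIC bedGraph tracks
#'
#' One bedGraph per population listing every position with a filtered-pass
#' MIC in at least one grouped trio of that population, valued by the number
#' of distinct trios with an MIC there.
#'
#' @param records MIC record table (filtered to `pass == TRUE` internally).
#' @param groups trio -> population table from [group_trios()].
#' @param out_prefix path prefix; files are written as
#'   `<prefix>_<population>.bedGraph`. Use `NULL` to skip writing.
#' @param track_line logical; prepend a UCSC track header line.
#' @return named list (by population) of `data.table`s with `chrom`, `start`,
#'   `end`, `value`, invisibly carrying written paths in attribute `"paths"`.
#' @export
write_population_tracks <- function(records, groups, out_prefix = NULL,
                                    track_line = FALSE) {
  records <- data.table::as.data.table(records)[pass == TRUE]
  groups <- data.table::as.data.table(groups)[!is.na(population)]
  recs <- merge(records, groups, by = "trio_id")
  pops <- sort(unique(groups$population))
  out <- list()
  paths <- character()
  for (p in pops) {
    tab <- recs[population == p,
                .(value = data.table::uniqueN(trio_id)), by = .(chrom, pos)]
    tab <- tab[, .(chrom, start = pos - 1L, end = pos, value)]
    data.table::setorder(tab, chrom, start)
    out[[p]] <- tab
    if (!is.null(out_prefix)) {
      path <- paste0(out_prefix, "_", p, ".bedGraph")
      tl <- if (track_line) {
        sprintf("track type=bedGraph name=\"MIC_%s\" description=\"MIC trio counts (%s)\"", p, p)
      } else NULL
      write_bedgraph(tab, path, track_line = tl)
      paths <- c(paths, path)
    }
  }
  data.table::setattr(out, "paths", paths)
  out
}
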