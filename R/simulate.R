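# Synthetic trio-cohort simulator. Generates a small pseudo-genome with
# repeat and alignability tracks, then trio genotype calls with the
# statistical structure the MIC analysis assumes: inherited hemizygous
# deletions at population-specific frequencies (hemizygous samples called
# homozygous for their remaining allele, depth proportional to copy number),
# genotype-caller errors concentrated in low-alignability repeats, 1-bp indel
# slippage at poly-A/T homopolymer runs, and true de novo SNVs.

#' Simulation configuration
#'
#' Defaults encode the cohort the analysis is designed around, scaled to a
#' desk-size pseudo-genome: two ancestral populations of 300 trios, 40x mean
#' coverage, one heterozygous-site catalog per ~1 kb, shared hemizygous
#' deletion regions plus one population-specific region at 40% parental
#' carrier frequency, error rates sharply elevated in repeats and
#' low-alignability sequence, homopolymer slippage in SINE poly-A/T runs, and
#' a de novo SNV rate of 1.2e-8 per bp per generation.
#'
#' @param populations data.frame with columns `label`, `n_trios`.
#' @param genome data.frame with columns `chrom`, `length` (bp).
#' @param deletion_regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), `carrier_parent` (`"both"`, `"mother"` or `"father"`), and
#'   either a single `freq` column or one `freq_<label>` column per
#'   population (per-parent carrier probability).
#' @param mean_coverage diploid mean read depth per sample (default 40).
#' @param site_density heterozygous SNV catalog density per bp (default
#'   1e-3).
#' @param indel_density polymorphic small-indel density per bp (default
#'   5e-5).
#' @param repeat_model list of per-class genome fractions, length ranges and
#'   alignability score models; see the package vignette. `NULL` fractions
#'   give a repeat-free genome.
#' @param error_model list: `base_rate` (per-genotype error probability in
#'   unique sequence), `class_mult` (named multipliers per repeat class),
#'   `align_weight` (scaling of the (1 - alignability) term), `cap` (upper
#'   bound on any per-site error rate), `slippage_rate` (per-genotype 1-bp
#'   indel miscall rate at homopolymer sites), `het_error_ab` (binomial alt
#'   fraction for erroneous het calls), `gq_range` (degraded GQ bounds),
#'   `trio_batch_sdlog` (lognormal sd of a per-family error-rate multiplier
#'   emulating sequencing-batch effects; with `callability_range`, the source
#'   of per-trio MIC load heterogeneity).
#' @param de_novo_rate true de novo SNV rate per bp per generation (default
#'   1.2e-8).
#' @param transmission_prob probability a carrier parent transmits the
#'   deleted haplotype (default 0.5).
#' @param callability_range per-sample probability range that a clean call is
#'   emitted at full confidence (GQ 99) rather than degraded GQ; drawn
#'   uniformly per sample. Source of realistic per-trio load heterogeneity.
#' @param seed mandatory integer seed; same seed, same cohort, byte-identical
#'   outputs.
#' @return object of class `triomic_sim_config`.
#' @export
sim_config <- function(populations = data.frame(label = c("EUR", "AMR"),
                                                n_trios = c(300L, 300L)),
                       genome = data.frame(chrom = c("chr1", "chr2"),
                                           length = c(3e6, 3e6)),
                       deletion_regions = NULL,
                       mean_coverage = 40,
                       site_density = 1e-3,
                       indel_density = 5e-5,
                       repeat_model = default_repeat_model(),
                       error_model = default_error_model(),
                       de_novo_rate = 1.2e-8,
                       transmission_prob = 0.5,
                       callability_range = c(0.35, 0.95),
                       seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  populations <- as.data.frame(populations)
  genome <- as.data.frame(genome)
  if (is.null(deletion_regions)) {
    deletion_regions <- default_deletion_regions(populations$label)
  }
  deletion_regions <- as.data.frame(deletion_regions)
  if (!"carrier_parent" %in% names(deletion_regions)) {
    deletion_regions$carrier_parent <- "both"
  }
  fcols <- paste0("freq_", populations$label)
  if ("freq" %in% names(deletion_regions)) {
    for (fc in fcols) deletion_regions[[fc]] <- deletion_regions$freq
  }
  if (!all(fcols %in% names(deletion_regions))) {
    stop("deletion_regions needs freq or freq_<label> columns for every population")
  }
  rates <- c(unlist(deletion_regions[fcols]), de_novo_rate, transmission_prob,
             error_model$base_rate, error_model$slippage_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  gl <- stats::setNames(genome$length, genome$chrom)
  for (i in seq_len(nrow(deletion_regions))) {
    ch <- deletion_regions$chrom[i]
    if (!ch %in% names(gl) || deletion_regions$end[i] > gl[[ch]] ||
        deletion_regions$start[i] < 0) {
      stop("deletion region ", i, " lies outside the genome")
    }
  }
  structure(list(populations = populations, genome = genome,
                 deletion_regions = deletion_regions,
                 mean_coverage = mean_coverage, site_density = site_density,
                 indel_density = indel_density, repeat_model = repeat_model,
                 error_model = error_model, de_novo_rate = de_novo_rate,
                 transmission_prob = transmission_prob,
                 callability_range = callability_range,
                 seed = as.integer(seed)),
            class = "triomic_sim_config")
}

#' Default repeat model for the simulated pseudo-genome
#'
#' Genome fractions approximate the human repeat landscape; SINEs are
#' Alu-like (~300 nt, poly-T head / poly-A tail of 20 nt), LINEs 500-8000 nt.
#' Alignability is 1 in unique sequence, near 1 in LINEs (60% of LINEs score
#' exactly 1), and low in SINEs/simple repeats.
#'
#' @return list consumed by [simulate_genome_tracks()].
#' @export
default_repeat_model <- function() {
  list(
    fractions = c(SINE = 0.12, LINE = 0.18, LTR = 0.06, Simple_repeat = 0.03,
                  Low_complexity = 0.01, Satellite = 0.01, DNA = 0.02),
    length_range = list(SINE = c(250, 350), LINE = c(500, 8000),
                        LTR = c(200, 1000), Simple_repeat = c(30, 200),
                        Low_complexity = c(30, 150), Satellite = c(500, 3000),
                        DNA = c(100, 1000)),
    align_range = list(SINE = c(0.1, 0.6), LINE = c(0.7, 1),
                       LTR = c(0.4, 0.9), Simple_repeat = c(0.05, 0.5),
                       Low_complexity = c(0.1, 0.5), Satellite = c(0.05, 0.4),
                       DNA = c(0.5, 1)),
    line_unique_prob = 0.6,   # fraction of LINEs with alignability exactly 1
    polyat_len = 20L,         # SINE poly-T head / poly-A tail length
    simple_homopolymer_prob = 0.5
  )
}

#' Default genotype-error model
#' @return list consumed by [simulate_trios()].
#' @export
default_error_model <- function() {
  list(base_rate = 1e-3,
       class_mult = c(SINE = 25, LINE = 4, LTR = 10, Simple_repeat = 40,
                      Low_complexity = 30, Satellite = 20, DNA = 5,
                      Other = 2, NONE = 1),
       align_weight = 4,
       cap = 0.3,
       trio_batch_sdlog = 0.6,   # lognormal sd of the per-family error multiplier
       slippage_rate = 0.02,
       het_error_ab = 0.3,
       gq_range = c(10L, 50L))
}

#' Default deletion regions for a two-chromosome 6 Mb pseudo-genome
#'
#' Five shared 60 kb regions (6% per-parent carrier frequency in every
#' population) spread over distinct 1 Mb windows, plus one region specific to
#' the second population (40% vs 0%), emulating a population-specific
#' hemizygous deletion.
#'
#' @param labels population labels (>= 1); the last label owns the specific
#'   region.
#' @return deletion-region data.frame for [sim_config()].
#' @export
default_deletion_regions <- function(labels = c("EUR", "AMR")) {
  reg <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
    start = c(200000L, 1200000L, 2200000L, 300000L, 1400000L, 2400000L),
    end   = c(260000L, 1260000L, 2260000L, 360000L, 1460000L, 2460000L),
    carrier_parent = "both")
  for (lb in labels) reg[[paste0("freq_", lb)]] <- 0.06
  # region 4 (chr2 first window) is specific to the last population
  for (lb in labels) reg[4L, paste0("freq_", lb)] <- 0
  reg[4L, paste0("freq_", labels[length(labels)])] <- 0.4
  reg
}

.runif_int <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))

.place_repeats <- function(chrom, L, model) {
  if (is.null(model) || is.null(model$fractions) || length(model$fractions) == 0) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), repeat_class = character(),
                                  name = character(), strand = character(),
                                  alignability = numeric()))
  }
  cand <- list()
  for (cls in names(model$fractions)) {
    lr <- model$length_range[[cls]]
    n <- max(0L, round(model$fractions[[cls]] * L / mean(lr)))
    if (n == 0L) next
    len <- .runif_int(n, lr[1L], lr[2L])
    start <- .runif_int(n, 0L, pmax(0L, L - len))
    ar <- model$align_range[[cls]]
    score <- stats::runif(n, ar[1L], ar[2L])
    if (cls == "LINE") {
      score[stats::runif(n) < model$line_unique_prob] <- 1
    }
    cand[[cls]] <- data.table::data.table(
      chrom = chrom, start = as.integer(start),
      end = as.integer(start + len), repeat_class = cls,
      name = paste0(cls, "_", chrom, "_", seq_len(n)),
      strand = ifelse(stats::runif(n) < 0.5, "+", "-"),
      alignability = round(score, 3))
  }
  cand <- data.table::rbindlist(cand)
  data.table::setorder(cand, start, end)
  # greedy non-overlap resolution (rejection of later-starting conflicts)
  keep <- logical(nrow(cand))
  prev_end <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] > prev_end) {
      keep[i] <- TRUE
      prev_end <- cand$end[i]
    }
  }
  cand[keep]
}

#' Simulate the pseudo-genome context tracks and polymorphic-site catalog
#'
#' @param config a [sim_config()].
#' @return list of class `triomic_sim_tracks`: `repeats` (data.table, BED-like
#'   0-based with `repeat_class` and per-element `alignability`),
#'   `homopolymers` (poly-A/T subintervals), `alignability` (disjoint scored
#'   intervals tiling the genome), and `sites` (catalog with `chrom`, `pos`
#'   1-based, `ref`, `alt`, `af`, `site_type` of `"snv"`, `"indel_poly"` or
#'   `"indel_slip"`, `repeat_class`, `alignability`, `in_polyat`,
#'   `error_rate`).
#' @export
simulate_genome_tracks <- function(config) {
  stopifnot(inherits(config, "triomic_sim_config"))
  set.seed(config$seed)
  model <- config$repeat_model
  em <- config$error_model
  bases <- c("A", "C", "G", "T")

  reps <- list(); homs <- list(); aligns <- list(); sites <- list()
  for (ci in seq_len(nrow(config$genome))) {
    chrom <- config$genome$chrom[ci]
    L <- as.integer(config$genome$length[ci])
    rp <- .place_repeats(chrom, L, model)
    reps[[chrom]] <- rp

    # poly-T head / poly-A tail in SINEs; homopolymer cores in simple repeats
    hm <- list()
    sine <- rp[repeat_class == "SINE"]
    if (nrow(sine) > 0) {
      pl <- model$polyat_len
      hm$head <- data.table::data.table(chrom = chrom, start = sine$start,
                                        end = sine$start + pl, kind = "polyT_head")
      hm$tail <- data.table::data.table(chrom = chrom, start = sine$end - pl,
                                        end = sine$end, kind = "polyA_tail")
    }
    simple <- rp[repeat_class == "Simple_repeat"]
    if (nrow(simple) > 0) {
      pick <- stats::runif(nrow(simple)) < model$simple_homopolymer_prob
      if (any(pick)) {
        hm$simple <- data.table::data.table(chrom = chrom,
                                            start = simple$start[pick],
                                            end = simple$end[pick],
                                            kind = "homopolymer")
      }
    }
    hm <- data.table::rbindlist(hm)
    homs[[chrom]] <- hm

    # disjoint alignability intervals: repeats carry their score, gaps are 1.0
    if (nrow(rp) > 0) {
      gaps_start <- c(0L, rp$end)
      gaps_end <- c(rp$start, L)
      al <- data.table::rbindlist(list(
        data.table::data.table(chrom = chrom, start = rp$start, end = rp$end,
                               score = rp$alignability),
        data.table::data.table(chrom = chrom, start = gaps_start,
                               end = gaps_end, score = 1)[start < end]))
    } else {
      al <- data.table::data.table(chrom = chrom, start = 0L, end = L, score = 1)
    }
    data.table::setorder(al, start)
    aligns[[chrom]] <- al

    # SNV catalog
    n_snv <- round(L * config$site_density)
    pos_snv <- sort(sample.int(L, n_snv))  # 1-based
    # polymorphic small indels
    n_ind <- round(L * config$indel_density)
    pos_ind <- sort(sample.int(L, n_ind))
    # slippage indel sites inside homopolymer runs (monomorphic, error-driven)
    pos_slip <- integer(0)
    if (nrow(hm) > 0) {
      pick <- stats::runif(nrow(hm)) < 0.8
      h <- hm[pick]
      if (nrow(h) > 0) {
        pos_slip <- h$start + .runif_int(nrow(h), 1L, pmax(1L, h$end - h$start))
        pos_slip <- sort(unique(pos_slip))
      }
    }
    pos_ind <- setdiff(pos_ind, c(pos_snv, pos_slip))
    pos_slip <- setdiff(pos_slip, pos_snv)

    ref_snv <- sample(bases, length(pos_snv), replace = TRUE)
    alt_snv <- vapply(ref_snv, function(b) sample(setdiff(bases, b), 1L), character(1))
    mk_indel <- function(n) {
      if (n == 0L) return(list(ref = character(), alt = character()))
      base <- sample(bases, n, replace = TRUE)
      extra <- sample(bases, n, replace = TRUE)
      is_ins <- stats::runif(n) < 0.5
      list(ref = ifelse(is_ins, base, paste0(base, extra)),
           alt = ifelse(is_ins, paste0(base, extra), base))
    }
    ip <- mk_indel(length(pos_ind))
    is2 <- mk_indel(length(pos_slip))
    st <- data.table::rbindlist(list(
      data.table::data.table(chrom = chrom, pos = pos_snv, ref = ref_snv,
                             alt = alt_snv, af = stats::runif(length(pos_snv), 0.05, 0.95),
                             site_type = "snv"),
      data.table::data.table(chrom = chrom, pos = pos_ind, ref = ip$ref,
                             alt = ip$alt, af = stats::runif(length(pos_ind), 0.05, 0.5),
                             site_type = "indel_poly"),
      data.table::data.table(chrom = chrom, pos = pos_slip, ref = is2$ref,
                             alt = is2$alt, af = 0, site_type = "indel_slip")))
    data.table::setorder(st, pos)
    sites[[chrom]] <- st
  }
  repeats <- data.table::rbindlist(reps)
  homopolymers <- data.table::rbindlist(homs)
  alignability <- data.table::rbindlist(aligns)
  sites <- data.table::rbindlist(sites)

  # annotate catalog with context and per-genotype error rates
  ann <- function(pos0, chrom, tab, val, default) {
    out <- rep(default, length(pos0))
    for (ch in unique(chrom)) {
      rows <- which(chrom == ch)
      t2 <- tab[tab$chrom == ch, ]
      if (nrow(t2) == 0) next
      idx <- findInterval(pos0[rows], t2$start)
      hit <- idx >= 1L & pos0[rows] < ifelse(idx >= 1L, t2$end[pmax(idx, 1L)], 0L)
      out[rows[hit]] <- val(t2)[idx[hit]]
    }
    out
  }
  p0 <- sites$pos - 1L
  sites[, repeat_class := ann(p0, chrom, repeats, function(t) t$repeat_class, "NONE")]
  sites[, alignability := ann(p0, chrom, alignability, function(t) t$score, 1)]
  if (nrow(homopolymers) > 0) {
    hp <- homopolymers[order(chrom, start)]
    sites[, in_polyat := ann(p0, chrom, hp, function(t) rep(TRUE, nrow(t)), FALSE)]
  } else {
    sites[, in_polyat := FALSE]
  }
  mult <- em$class_mult[sites$repeat_class]
  mult[is.na(mult)] <- 1
  err <- em$base_rate * mult * (1 + em$align_weight * (1 - sites$alignability))
  err[sites$site_type == "indel_slip"] <- em$slippage_rate
  sites[, error_rate := pmin(err, em$cap)]

  structure(list(repeats = repeats, homopolymers = homopolymers,
                 alignability = alignability, sites = sites,
                 genome = data.table::as.data.table(config$genome)),
            class = "triomic_sim_tracks")
}

#' Simulate a trio cohort over generated genome tracks
#'
#' Parents are drawn from shared population allele frequencies; hemizygous
#' deletion carriers are called homozygous for the remaining allele with
#' depth ~ Poisson(mean coverage x copies / 2); heterozygous alt read counts
#' are Binomial(DP, 1/2); clean calls have GQ 99 subject to per-sample
#' callability, injected errors carry degraded GQ; de novo SNVs appear as
#' child-only heterozygous calls.
#'
#' @param config a [sim_config()].
#' @param tracks result of [simulate_genome_tracks()] (regenerated from
#'   `config` when `NULL`).
#' @return a `triomic_cohort` (see [read_trio_vcf()]) with extra elements:
#'   `trios` (pedigree table), `populations` (trio -> population),
#'   `ancestry_pcs` (per-sample PC coordinates), `coverage` (nominal mean
#'   coverage per sample) and `truth` (deletions, errors, de novos,
#'   callability).
#' @export
simulate_trios <- function(config, tracks = NULL) {
  stopifnot(inherits(config, "triomic_sim_config"))
  if (is.null(tracks)) tracks <- simulate_genome_tracks(config)
  set.seed((config$seed + 1000003L) %% .Machine$integer.max)
  sites <- data.table::copy(tracks$sites)
  data.table::setorder(sites, chrom, pos)
  ns <- nrow(sites)
  pops <- config$populations
  n_trio <- sum(pops$n_trios)
  trio_pop <- rep(pops$label, pops$n_trios)
  trio_id <- sprintf("%s_T%04d", trio_pop, unlist(lapply(pops$n_trios, seq_len)))
  child <- paste0(trio_id, "_C"); mother <- paste0(trio_id, "_M")
  father <- paste0(trio_id, "_F")
  samples <- as.vector(rbind(child, mother, father))
  nsamp <- length(samples)

  geno <- matrix(NA_integer_, ns, nsamp, dimnames = list(NULL, samples))
  dp <- matrix(NA_real_, ns, nsamp, dimnames = list(NULL, samples))
  gq <- matrix(NA_real_, ns, nsamp, dimnames = list(NULL, samples))
  ad_ref <- matrix(NA_real_, ns, nsamp, dimnames = list(NULL, samples))
  ad_alt <- matrix(NA_real_, ns, nsamp, dimnames = list(NULL, samples))

  callability <- stats::runif(nsamp, config$callability_range[1L],
                              config$callability_range[2L])
  names(callability) <- samples

  regions <- data.table::as.data.table(config$deletion_regions)
  # site index ranges per deletion region
  region_sites <- lapply(seq_len(nrow(regions)), function(i) {
    which(sites$chrom == regions$chrom[i] &
            sites$pos > regions$start[i] & sites$pos <= regions$end[i])
  })
  em <- config$error_model
  cov <- config$mean_coverage
  af <- sites$af
  genome_len <- sum(config$genome$length)

  truth_del <- list(); truth_err <- list(); truth_dn <- list()

  fill_calls <- function(g, copies, q) {
    # returns list(dp, gq, ad_ref, ad_alt, geno) for one sample's calls
    d <- stats::rpois(ns, cov * copies / 2)
    g[d == 0] <- NA_integer_
    alt <- numeric(ns)
    het <- !is.na(g) & g == 1L
    alt[het] <- stats::rbinom(sum(het), d[het], 0.5)
    alt[!is.na(g) & g == 2L] <- d[!is.na(g) & g == 2L]
    q_clean <- ifelse(stats::runif(ns) < q, 99,
                      .runif_int(ns, em$gq_range[1L], em$gq_range[2L]))
    list(geno = g, dp = d, gq = q_clean, ad_ref = d - alt, ad_alt = alt)
  }

  sdl <- em$trio_batch_sdlog %||% 0
  batch_mult <- stats::setNames(exp(stats::rnorm(n_trio, -sdl^2 / 2, sdl)), trio_id)

  for (t in seq_len(n_trio)) {
    pop <- trio_pop[t]
    fcol <- paste0("freq_", pop)
    p_err_t <- pmin(sites$error_rate * batch_mult[[t]], em$cap)
    # parental haplotypes (alt-allele indicators per site)
    hm1 <- stats::rbinom(ns, 1L, af); hm2 <- stats::rbinom(ns, 1L, af)
    hf1 <- stats::rbinom(ns, 1L, af); hf2 <- stats::rbinom(ns, 1L, af)
    # per-site transmitted haplotype selectors (no linkage needed)
    sm <- stats::runif(ns) < 0.5
    sf <- stats::runif(ns) < 0.5
    tm <- ifelse(sm, hm1, hm2)
    tf <- ifelse(sf, hf1, hf2)

    g_mo <- hm1 + hm2; g_fa <- hf1 + hf2; g_ch <- tm + tf
    copies_mo <- rep(2, ns); copies_fa <- rep(2, ns); copies_ch <- rep(2, ns)
    mat_del <- rep(FALSE, ns); pat_del <- rep(FALSE, ns)

    for (ri in seq_len(nrow(regions))) {
      freq <- regions[[fcol]][ri]
      rs <- region_sites[[ri]]
      cp <- regions$carrier_parent[ri]
      for (par in c("mother", "father")) {
        if (!(cp == "both" || cp == par)) next
        if (stats::runif(1) >= freq) next
        # carrier: one haplotype deleted; called hom for the remaining allele
        del_h1 <- stats::runif(1) < 0.5
        transmitted <- stats::runif(1) < config$transmission_prob
        # a non-transmitting carrier passes its remaining (non-deleted)
        # haplotype to the child at every region site
        if (par == "mother") {
          remaining <- if (del_h1) hm2[rs] else hm1[rs]
          g_mo[rs] <- 2L * remaining
          copies_mo[rs] <- 1
          if (transmitted) mat_del[rs] <- TRUE else tm[rs] <- remaining
        } else {
          remaining <- if (del_h1) hf2[rs] else hf1[rs]
          g_fa[rs] <- 2L * remaining
          copies_fa[rs] <- 1
          if (transmitted) pat_del[rs] <- TRUE else tf[rs] <- remaining
        }
        truth_del[[length(truth_del) + 1L]] <- data.table::data.table(
          trio_id = trio_id[t], parent = par, chrom = regions$chrom[ri],
          start = regions$start[ri], end = regions$end[ri],
          transmitted = transmitted)
      }
    }
    both_del <- mat_del & pat_del
    copies_ch <- 2 - mat_del - pat_del
    g_ch <- tm + tf                 # recompute: selectors fixed inside regions
    g_ch[both_del] <- NA_integer_   # zero copies: no call
    # child hemizygous for a single inherited allele where one side is deleted
    g_ch[mat_del & !pat_del] <- 2L * tf[mat_del & !pat_del]
    g_ch[pat_del & !mat_del] <- 2L * tm[pat_del & !mat_del]

    cols <- c(child[t], mother[t], father[t])
    gl <- list(g_ch, g_mo, g_fa)
    cpl <- list(copies_ch, copies_mo, copies_fa)
    for (m in 1:3) {
      cc <- fill_calls(as.integer(gl[[m]]), cpl[[m]], callability[cols[m]])
      # genotype errors: flip to a uniformly chosen different code
      err <- stats::runif(ns) < p_err_t & !is.na(cc$geno)
      if (any(err)) {
        ei <- which(err)
        shift <- .runif_int(length(ei), 1L, 2L)
        newg <- (cc$geno[ei] + shift) %% 3L
        cc$geno[ei] <- newg
        cc$gq[ei] <- .runif_int(length(ei), em$gq_range[1L], em$gq_range[2L])
        alt <- numeric(length(ei))
        het <- newg == 1L
        alt[het] <- stats::rbinom(sum(het), cc$dp[ei][het], em$het_error_ab)
        alt[newg == 2L] <- cc$dp[ei][newg == 2L]
        cc$ad_alt[ei] <- alt
        cc$ad_ref[ei] <- cc$dp[ei] - alt
        truth_err[[length(truth_err) + 1L]] <- data.table::data.table(
          trio_id = trio_id[t], sample = cols[m],
          member = c("child", "mother", "father")[m],
          chrom = sites$chrom[ei], pos = sites$pos[ei],
          type = ifelse(sites$site_type[ei] == "indel_slip", "slippage", "flip"))
      }
      geno[, cols[m]] <- cc$geno
      dp[, cols[m]] <- cc$dp
      gq[, cols[m]] <- cc$gq
      ad_ref[, cols[m]] <- cc$ad_ref
      ad_alt[, cols[m]] <- cc$ad_alt
    }
    # true de novo SNVs: child-only hets at fresh positions
    ndn <- stats::rbinom(1L, genome_len, config$de_novo_rate)
    if (ndn > 0) {
      chs <- sample(config$genome$chrom, ndn, replace = TRUE,
                    prob = config$genome$length)
      posd <- .runif_int(ndn, 1L, config$genome$length[match(chs, config$genome$chrom)])
      refd <- sample(c("A", "C", "G", "T"), ndn, replace = TRUE)
      altd <- vapply(refd, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                     character(1))
      truth_dn[[length(truth_dn) + 1L]] <- data.table::data.table(
        trio_id = trio_id[t], sample = child[t], chrom = chs, pos = posd,
        ref = refd, alt = altd)
    }
  }

  truth_dn <- if (length(truth_dn)) data.table::rbindlist(truth_dn) else
    data.table::data.table(trio_id = character(), sample = character(),
                           chrom = character(), pos = integer(),
                           ref = character(), alt = character())
  # drop de novo positions colliding with catalog sites or one another
  if (nrow(truth_dn) > 0) {
    key_sites <- paste(sites$chrom, sites$pos)
    truth_dn <- truth_dn[!paste(chrom, pos) %in% key_sites]
    truth_dn <- truth_dn[!duplicated(paste(chrom, pos))]
  }
  if (nrow(truth_dn) > 0) {
    nd <- nrow(truth_dn)
    extra_sites <- truth_dn[, .(chrom, pos, ref, alt, af = 0, site_type = "de_novo",
                                repeat_class = NA_character_, alignability = NA_real_,
                                in_polyat = FALSE, error_rate = 0)]
    g2 <- matrix(0L, nd, nsamp, dimnames = list(NULL, samples))
    d2 <- matrix(stats::rpois(nd * nsamp, cov), nd, nsamp, dimnames = list(NULL, samples))
    q2 <- matrix(ifelse(stats::runif(nd * nsamp) < rep(callability, each = nd), 99,
                        .runif_int(nd * nsamp, em$gq_range[1L], em$gq_range[2L])),
                 nd, nsamp, dimnames = list(NULL, samples))
    ar2 <- d2; aa2 <- matrix(0, nd, nsamp, dimnames = list(NULL, samples))
    for (i in seq_len(nd)) {
      cs <- truth_dn$sample[i]
      g2[i, cs] <- 1L
      aa2[i, cs] <- stats::rbinom(1L, d2[i, cs], 0.5)
      ar2[i, cs] <- d2[i, cs] - aa2[i, cs]
    }
    sites <- data.table::rbindlist(list(sites, extra_sites), use.names = TRUE)
    geno <- rbind(geno, g2); dp <- rbind(dp, d2); gq <- rbind(gq, q2)
    ad_ref <- rbind(ad_ref, ar2); ad_alt <- rbind(ad_alt, aa2)
    ord <- order(sites$chrom, sites$pos)
    sites <- sites[ord]
    geno <- geno[ord, , drop = FALSE]; dp <- dp[ord, , drop = FALSE]
    gq <- gq[ord, , drop = FALSE]
    ad_ref <- ad_ref[ord, , drop = FALSE]; ad_alt <- ad_alt[ord, , drop = FALSE]
  }
  vc <- classify_variant(sites$ref, sites$alt)
  sites[, var_class := vc$var_class]
  sites[, indel_len := vc$indel_len]

  trios <- data.table::data.table(trio_id = trio_id, child = child,
                                  mother = mother, father = father)
  populations_tab <- data.table::data.table(trio_id = trio_id, population = trio_pop)

  # ancestry PCs: well-separated per-population blobs on PCs 1-3
  centers <- cbind(cos(2 * pi * seq_len(nrow(pops)) / nrow(pops)) * 3,
                   sin(2 * pi * seq_len(nrow(pops)) / nrow(pops)) * 3,
                   seq_len(nrow(pops)) * 0.5)
  samp_pop <- rep(trio_pop, each = 3L)
  pci <- match(samp_pop, pops$label)
  pcs <- centers[pci, , drop = FALSE] +
    matrix(stats::rnorm(nsamp * 3, sd = 0.3), nsamp, 3)
  ancestry_pcs <- data.table::data.table(sample = samples, population = samp_pop,
                                         PC1 = pcs[, 1], PC2 = pcs[, 2],
                                         PC3 = pcs[, 3])

  truth <- list(
    deletions = if (length(truth_del)) data.table::rbindlist(truth_del) else
      data.table::data.table(trio_id = character(), parent = character(),
                             chrom = character(), start = integer(),
                             end = integer(), transmitted = logical()),
    errors = if (length(truth_err)) data.table::rbindlist(truth_err) else
      data.table::data.table(trio_id = character(), sample = character(),
                             member = character(), chrom = character(),
                             pos = integer(), type = character()),
    de_novos = truth_dn,
    callability = callability,
    batch_mult = batch_mult)

  structure(list(sites = sites, geno = geno, dp = dp, gq = gq,
                 ad_ref = ad_ref, ad_alt = ad_alt, samples = samples,
                 trios = trios, populations = populations_tab,
                 ancestry_pcs = ancestry_pcs,
                 coverage = stats::setNames(rep(cov, nsamp), samples),
                 truth = truth, tracks = tracks,
                 log = list(skipped_multiallelic = 0L, skipped_symbolic = 0L,
                            skipped_non_autosomal = 0L)),
            class = "triomic_cohort")
}

#' Attribute detected MIC records to their simulated cause
#'
#' Causes, in priority order: `"error"` (an injected genotype error at the
#' site in any trio member), `"de_novo"` (a simulated true de novo at the
#' position), `"deletion"` (the site lies in a deletion transmitted to the
#' trio's child). Records matching none are `"unexplained"`.
#'
#' @param records MIC table from [detect_mic_cohort()].
#' @param truth the `truth` element of a simulated cohort.
#' @return character vector of causes aligned with `records`.
#' @export
attribute_mic <- function(records, truth) {
  records <- data.table::as.data.table(records)
  key <- paste(records$trio_id, records$chrom, records$pos)
  cause <- rep("unexplained", nrow(records))
  del <- truth$deletions[transmitted == TRUE]
  if (nrow(del) > 0) {
    for (i in seq_len(nrow(del))) {
      hit <- records$trio_id == del$trio_id[i] & records$chrom == del$chrom[i] &
        records$pos > del$start[i] & records$pos <= del$end[i]
      cause[hit] <- "deletion"
    }
  }
  if (nrow(truth$de_novos) > 0) {
    cause[key %in% paste(truth$de_novos$trio_id, truth$de_novos$chrom,
                         truth$de_novos$pos)] <- "de_novo"
  }
  if (nrow(truth$errors) > 0) {
    cause[key %in% paste(truth$errors$trio_id, truth$errors$chrom,
                         truth$errors$pos)] <- "error"
  }
  cause
}
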