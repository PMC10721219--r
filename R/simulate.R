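#' Simulation configuration
#'
#' Defines the synthetic cohort: a DHS catalog with five classes laid out
#' on a small genome, STAT5-high / STAT5-low male and female DNase-seq
#' samples, and the accessibility fold-changes, motif frequencies and
#' STAT5-binding frequencies that characterize each class. Defaults mirror
#' the biology being emulated: dynamic male-biased DHS are 3.8-fold more
#' open in STAT5-high than STAT5-low male livers, static male-biased DHS
#' sit 2.6-fold below the peak dynamic level and are 2.6-fold more open in
#' male than female liver, static female-biased DHS are 2.8-fold
#' female-biased, and canonical STAT5 motifs occur at 81% / 38% / 25% of
#' dynamic male-biased / static male-biased / background DHS.
#'
#' @param seed Integer RNG seed; every simulation product is a pure
#'   function of the config including this seed.
#' @param genome Named vector of chromosome lengths (default one 10-Mb
#'   chromosome).
#' @param n_dhs Named integer vector of DHS counts per class
#'   (`dynamic_male`, `static_male`, `static_female`, `dynamic_indep`,
#'   `background`). `background` is the static sex-independent class.
#' @param dhs_width DHS width in bp.
#' @param fold_dynamic_high_low STAT5-high / STAT5-low accessibility ratio
#'   at dynamic male-biased DHS (male liver).
#' @param fold_dynamic_over_static Peak dynamic (STAT5-high) accessibility
#'   divided by static male-biased accessibility in male liver.
#' @param fold_static_mf Male / female accessibility ratio at static
#'   male-biased DHS.
#' @param fold_static_fm Female / male accessibility ratio at static
#'   female-biased DHS.
#' @param rel_background Accessibility of background (static
#'   sex-independent) DHS relative to the STAT5-low level of dynamic
#'   male-biased DHS. Default 1.44, reflecting that constitutively open
#'   sex-independent sites sit well above the trough level of pulsatile
#'   sites.
#' @param motif_freq Named probabilities that a DHS of each class carries
#'   at least one STAT5 motif.
#' @param bound_freq Named probabilities that a DHS of each class is
#'   STAT5-bound (ChIP-seq emulation).
#' @param n_high,n_low,n_female Samples per group (STAT5-high males,
#'   STAT5-low males, females).
#' @param depth Mean cut sites per sample (library depth scale).
#' @param dispersion Negative-binomial overdispersion of per-DHS counts
#'   (`size = 1/dispersion`; 0 gives Poisson).
#' @param peak_shape_sd Gaussian spread (bp) of cut sites around each DHS
#'   midpoint.
#' @param bg_cut_frac Fraction of each library that is uniform genomic
#'   background rather than DHS-centered signal.
#' @param n_tads Number of TADs tiling the genome.
#' @param genes_per_tad Genes placed in each TAD.
#' @param state_weight_e6 Baseline probability that a chromatin-state
#'   segment is the enhancer-like state E6.
#' @param state_bias_dynamic,state_bias_static Probability that segments
#'   inside a dynamic (resp. static) male-biased DHS are E6 in the male
#'   state map, planting the enhancer-state enrichment of that class.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome = c(chrS = 10e6),
                       n_dhs = c(dynamic_male = 200L, static_male = 400L,
                                 static_female = 200L, dynamic_indep = 0L,
                                 background = 2000L),
                       dhs_width = 400L,
                       fold_dynamic_high_low = 3.8,
                       fold_dynamic_over_static = 2.6,
                       fold_static_mf = 2.6,
                       fold_static_fm = 2.8,
                       rel_background = 1.44,
                       motif_freq = c(dynamic_male = 0.81, static_male = 0.38,
                                      static_female = 0.25, dynamic_indep = 0.25,
                                      background = 0.25),
                       bound_freq = c(dynamic_male = 0.85, static_male = 0.32,
                                      static_female = 0.20, dynamic_indep = 0.90,
                                      background = 0.19),
                       n_high = 8L, n_low = 10L, n_female = 6L,
                       depth = 2e5,
                       dispersion = 0.1,
                       peak_shape_sd = 100,
                       bg_cut_frac = 0.2,
                       n_tads = 50L,
                       genes_per_tad = 4L,
                       state_weight_e6 = 0.37,
                       state_bias_dynamic = 0.72,
                       state_bias_static = 0.55) {
  classes <- c("dynamic_male", "static_male", "static_female",
               "dynamic_indep", "background")
  stopifnot(all(names(n_dhs) %in% classes),
            all(genome > 0), !is.null(names(genome)),
            fold_dynamic_high_low >= 1, fold_static_mf >= 1,
            fold_static_fm >= 1, fold_dynamic_over_static >= 1,
            all(motif_freq >= 0 & motif_freq <= 1),
            all(bound_freq >= 0 & bound_freq <= 1),
            n_high >= 2, n_low >= 2, n_female >= 2,
            depth > 0, dispersion >= 0, peak_shape_sd > 0,
            bg_cut_frac >= 0 && bg_cut_frac < 1)
  n_full <- stats::setNames(rep(0L, length(classes)), classes)
  n_full[names(n_dhs)] <- as.integer(n_dhs)
  cfg <- list(seed = as.integer(seed), genome = genome, n_dhs = n_full,
              dhs_width = as.integer(dhs_width),
              fold_dynamic_high_low = fold_dynamic_high_low,
              fold_dynamic_over_static = fold_dynamic_over_static,
              fold_static_mf = fold_static_mf,
              fold_static_fm = fold_static_fm,
              rel_background = rel_background,
              motif_freq = motif_freq[classes],
              bound_freq = bound_freq[classes],
              n_high = as.integer(n_high), n_low = as.integer(n_low),
              n_female = as.integer(n_female),
              depth = depth, dispersion = dispersion,
              peak_shape_sd = peak_shape_sd, bg_cut_frac = bg_cut_frac,
              n_tads = as.integer(n_tads),
              genes_per_tad = as.integer(genes_per_tad),
              state_weight_e6 = state_weight_e6,
              state_bias_dynamic = state_bias_dynamic,
              state_bias_static = state_bias_static,
              classes = classes)
  class(cfg) <- "sim_config"
  cfg
}

#' Per-class relative accessibility for each sample group
#'
#' Rows are DHS classes, columns the sample groups (`high`, `low`,
#' `female`), on a scale where the STAT5-low level of a dynamic
#' male-biased DHS is 1. Derived from the configured fold-changes:
#' the dynamic class rises to `fold_dynamic_high_low` in STAT5-high
#' livers; static male-biased DHS sit at
#' `fold_dynamic_high_low / fold_dynamic_over_static` in males and
#' `fold_static_mf`-fold lower in females; static female-biased DHS match
#' the background level in females and are `fold_static_fm`-fold lower in
#' males; background DHS are equal everywhere at `rel_background`.
#'
#' @param config A [sim_config()].
#' @return Numeric matrix `classes x groups`.
#' @export
class_intensity <- function(config) {
  sm_male <- config$fold_dynamic_high_low / config$fold_dynamic_over_static
  m <- rbind(
    dynamic_male = c(config$fold_dynamic_high_low, 1, 1),
    static_male = c(sm_male, sm_male, sm_male / config$fold_static_mf),
    static_female = c(config$rel_background / config$fold_static_fm,
                      config$rel_background / config$fold_static_fm,
                      config$rel_background),
    dynamic_indep = c(config$fold_dynamic_high_low, 1,
                      (config$fold_dynamic_high_low + 1) / 2),
    background = rep(config$rel_background, 3)
  )
  colnames(m) <- c("high", "low", "female")
  m
}

# Place n non-overlapping DHS of the given width, away from chromosome
# ends (2-kb profile windows must fit). Deterministic given the RNG state.
.place_dhs <- function(genome, n, width) {
  margin <- 1200L
  usable <- pmax(0, as.numeric(genome) - 2 * margin)
  if (sum(usable) < n * (width + 50))
    stop("genome too small to place ", n, " non-overlapping DHS")
  n_per <- floor(usable / sum(usable) * n)
  rem <- n - sum(n_per)
  if (rem > 0) {
    o <- order(usable, decreasing = TRUE)
    n_per[o[seq_len(rem)]] <- n_per[o[seq_len(rem)]] + 1L
  }
  out <- list()
  for (i in seq_along(genome)) {
    k <- n_per[i]
    if (k == 0L) next
    slot <- floor(usable[i] / k)
    if (slot < width + 50) stop("genome too small to place requested DHS")
    offset <- sample.int(slot - width - 49L, k, replace = TRUE) - 1L
    start <- margin + (seq_len(k) - 1L) * slot + offset
    out[[names(genome)[i]]] <- data.frame(
      chrom = names(genome)[i], start = as.integer(start),
      end = as.integer(start + width), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Tile the genome with chromatin-state segments whose breakpoints include
# every DHS boundary, so each DHS is covered by segments wholly inside or
# outside it. Segments inside male-biased DHS are biased toward E6 in the
# male map.
.simulate_states <- function(config, dhs, classes) {
  states <- paste0("E", 1:14)
  base_w <- c(config$state_weight_e6,
              rep((1 - config$state_weight_e6) / 13, 13))
  names(base_w) <- c("E6", setdiff(states, "E6"))
  base_w <- base_w[states]
  out <- list()
  for (sex in c("M", "F")) {
    segs <- list()
    for (i in seq_along(config$genome)) {
      chr <- names(config$genome)[i]
      len <- config$genome[[i]]
      on_chr <- dhs$chrom == chr
      bp <- sort(unique(c(seq(0, len, by = 2000L), len,
                          dhs$start[on_chr], dhs$end[on_chr])))
      s <- bp[-length(bp)]
      e <- bp[-1L]
      lab <- sample(states, length(s), replace = TRUE, prob = base_w)
      if (sex == "M" && any(on_chr)) {
        for (j in which(on_chr)) {
          p <- switch(classes[j],
                      dynamic_male = config$state_bias_dynamic,
                      static_male = config$state_bias_static,
                      NA_real_)
          if (is.na(p)) next
          inside <- s >= dhs$start[j] & e <= dhs$end[j]
          if (any(inside) && stats::runif(1) < p) lab[inside] <- "E6"
        }
      }
      segs[[chr]] <- data.frame(chrom = chr, start = as.integer(s),
                                end = as.integer(e), state = lab,
                                stringsAsFactors = FALSE)
    }
    out[[sex]] <- do.call(rbind, segs)
  }
  out
}

#' Simulate the annotation universe
#'
#' Generates a non-overlapping DHS catalog with hidden class labels, a
#' TAD tiling, genes with TSS and ground-truth expression classes,
#' per-sex chromatin-state segmentations (14 states, enhancer state E6
#' planted at male-biased DHS in the male map), STAT5 ChIP peak emulation,
#' and planted motif counts. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with elements `dhs` (catalog intervals, named), `genes`,
#'   `tads`, `states` (list `M`/`F`), `tf_peaks`, and `truth` (list with
#'   per-DHS and per-gene ground truth).
#' @export
simulate_annotations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_total <- sum(config$n_dhs)
  dhs <- .place_dhs(config$genome, n_total, config$dhs_width)
  classes <- sample(rep(names(config$n_dhs), config$n_dhs))
  dhs$name <- sprintf("dhs_%05d", seq_len(n_total))
  dhs$score <- 0
  dhs$strand <- "."
  rownames(dhs) <- NULL

  # motif truth: presence by class frequency; dynamic DHS more often carry
  # multiple copies
  has_motif <- stats::rbinom(n_total, 1L, config$motif_freq[classes]) == 1L
  extra <- stats::rpois(n_total, ifelse(classes == "dynamic_male", 0.5, 0.15))
  motif_count <- ifelse(has_motif, 1L + extra, 0L)
  bound <- stats::rbinom(n_total, 1L, config$bound_freq[classes]) == 1L

  # TADs tile each chromosome
  tads <- list()
  tad_per_chr <- pmax(1L, round(config$n_tads * as.numeric(config$genome) /
                                  sum(as.numeric(config$genome))))
  for (i in seq_along(config$genome)) {
    chr <- names(config$genome)[i]
    k <- tad_per_chr[i]
    bp <- round(seq(0, config$genome[[i]], length.out = k + 1L))
    tads[[chr]] <- data.frame(chrom = chr, start = as.integer(bp[-(k + 1L)]),
                              end = as.integer(bp[-1L]),
                              stringsAsFactors = FALSE)
  }
  tads <- do.call(rbind, tads)
  tads$tad_id <- sprintf("tad_%03d", seq_len(nrow(tads)))
  rownames(tads) <- NULL

  # genes: uniform TSS within each TAD; truth labels for expression classes
  g <- tads[rep(seq_len(nrow(tads)), each = config$genes_per_tad), ]
  tss <- g$start + floor(stats::runif(nrow(g)) * (g$end - g$start))
  genes <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(nrow(g))),
    chrom = g$chrom, tss = as.integer(tss),
    strand = sample(c("+", "-"), nrow(g), replace = TRUE),
    biotype = sample(c("refseq", "lncRNA"), nrow(g), replace = TRUE,
                     prob = c(0.85, 0.15)),
    tad_id = g$tad_id, stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  sex_bias <- sample(c("male", "female", "independent", "other"),
                     nrow(genes), replace = TRUE,
                     prob = c(0.10, 0.10, 0.60, 0.20))
  hypox <- ifelse(sex_bias %in% c("male", "female"),
                  sample(c("I", "II", "none"), nrow(genes), replace = TRUE,
                         prob = c(0.5, 0.3, 0.2)),
                  "none")

  states <- .simulate_states(config, dhs, classes)

  # STAT5 "ChIP-seq" peaks: one per bound DHS, plus decoys in open space
  bound_idx <- which(bound)
  mid <- floor((dhs$start + dhs$end) / 2)
  tf <- data.frame(chrom = dhs$chrom[bound_idx],
                   start = as.integer(mid[bound_idx] - 100L),
                   end = as.integer(mid[bound_idx] + 100L),
                   stringsAsFactors = FALSE)
  n_decoy <- 50L
  decoys <- empty_intervals()[, c("chrom", "start", "end")]
  tries <- 0L
  while (nrow(decoys) < n_decoy && tries < 40L) {
    tries <- tries + 1L
    chr_i <- sample.int(length(config$genome), n_decoy, replace = TRUE,
                        prob = as.numeric(config$genome))
    pos <- floor(stats::runif(n_decoy) * (as.numeric(config$genome)[chr_i] - 200))
    cand <- data.frame(chrom = names(config$genome)[chr_i],
                       start = as.integer(pos), end = as.integer(pos + 200L),
                       stringsAsFactors = FALSE)
    pad <- dhs
    pad$start <- pmax(0L, pad$start - 500L)
    pad$end <- pad$end + 500L
    cand <- cand[!overlaps_any(cand, pad), , drop = FALSE]
    decoys <- utils::head(rbind(decoys, cand), n_decoy)
  }
  tf_peaks <- rbind(tf, decoys)
  tf_peaks <- tf_peaks[order(tf_peaks$chrom, tf_peaks$start), , drop = FALSE]
  tf_peaks$name <- sprintf("stat5_%04d", seq_len(nrow(tf_peaks)))
  tf_peaks$score <- 0
  tf_peaks$strand <- "."
  rownames(tf_peaks) <- NULL

  truth <- list(
    dhs = data.frame(name = dhs$name, chrom = dhs$chrom, start = dhs$start,
                     end = dhs$end, class = classes, stat5_bound = bound,
                     motif_count = as.integer(motif_count),
                     stringsAsFactors = FALSE),
    genes = data.frame(gene_id = genes$gene_id, sex_bias = sex_bias,
                       hypox_class = hypox, stringsAsFactors = FALSE)
  )
  list(dhs = dhs, genes = genes, tads = tads, states = states,
       tf_peaks = tf_peaks, truth = truth)
}

#' Simulate per-sample cut-site tracks
#'
#' Draws per-DHS per-sample cut counts from a negative binomial whose mean
#' is the depth-scaled class intensity for the sample's group (see
#' [class_intensity()]), spreads the cuts as a truncated Gaussian around
#' the DHS midpoint, and adds uniform background cuts genome-wide.
#' Library totals therefore differ between groups in proportion to their
#' aggregate accessibility, as they would in real libraries.
#'
#' @param config A [sim_config()].
#' @param truth Truth component of [simulate_annotations()] output (or the
#'   whole annotation list).
#' @return List with `tracks` (named list of [cut_site_track()]) and
#'   `samples` (metadata: `sample_id`, `sex`, `stat5_activity`,
#'   `treatment`, `group`).
#' @export
simulate_cut_tracks <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(truth$truth)) truth <- truth$truth
  td <- truth$dhs
  set.seed(config$seed + 1L)
  inten <- class_intensity(config)
  samples <- data.frame(
    sample_id = c(sprintf("MH%02d", seq_len(config$n_high)),
                  sprintf("ML%02d", seq_len(config$n_low)),
                  sprintf("F%02d", seq_len(config$n_female))),
    sex = c(rep("M", config$n_high + config$n_low),
            rep("F", config$n_female)),
    stat5_activity = c(rep("high", config$n_high), rep("low", config$n_low),
                       rep(NA_character_, config$n_female)),
    treatment = "intact",
    group = c(rep("high", config$n_high), rep("low", config$n_low),
              rep("female", config$n_female)),
    stringsAsFactors = FALSE)

  # depth-scaling unit: the STAT5-low male library carries
  # (1 - bg_cut_frac) * depth expected DHS cuts
  unit <- (1 - config$bg_cut_frac) * config$depth /
    sum(inten[td$class, "low"])
  mid <- floor((td$start + td$end) / 2)
  lo_bound <- pmax(0L, td$start - 500L)
  hi_bound <- td$end + 500L - 1L
  glen <- as.numeric(config$genome)

  tracks <- list()
  for (i in seq_len(nrow(samples))) {
    grp <- samples$group[i]
    mu <- unit * inten[td$class, grp]
    cnt <- if (config$dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
    reps <- rep.int(seq_along(cnt), cnt)
    pos <- round(stats::rnorm(length(reps), mid[reps], config$peak_shape_sd))
    pos <- pmin(pmax(pos, lo_bound[reps]), hi_bound[reps])
    chrom <- td$chrom[reps]
    # uniform genomic background
    n_bg <- stats::rpois(1, config$bg_cut_frac * config$depth)
    chr_i <- sample.int(length(glen), n_bg, replace = TRUE, prob = glen)
    bg_pos <- floor(stats::runif(n_bg) * glen[chr_i])
    chrom <- c(chrom, names(config$genome)[chr_i])
    pos <- c(pos, bg_pos)
    tracks[[samples$sample_id[i]]] <-
      cut_site_track(.positions_to_cuts(chrom, pos),
                     total_mapped_reads = length(pos))
  }
  list(tracks = tracks, samples = samples)
}

#' Simulate a gene expression table consistent with truth labels
#'
#' Emits FPKM, male/female fold-changes and adjusted p-values, and per-sex
#' hypophysectomy responses, constructed so that at `noise = 0` the
#' calling thresholds of [call_sex_bias()] and [call_hypox_class()]
#' recover the truth labels exactly. `noise` applies multiplicative
#' log-normal jitter to all fold-changes.
#'
#' @param config A [sim_config()].
#' @param truth Truth component of [simulate_annotations()] output (or the
#'   whole annotation list).
#' @param noise Standard deviation of log-normal fold-change jitter
#'   (default 0).
#' @return Data frame, one row per gene, with columns `gene_id`,
#'   `biotype`, `fpkm_m`, `fpkm_f`, `fc_mf`, `padj_mf`, `fc_hypox_m`,
#'   `padj_hypox_m`, `fc_hypox_f`, `padj_hypox_f`.
#' @export
simulate_expression <- function(config, truth, noise = 0) {
  stopifnot(inherits(config, "sim_config"))
  genes <- if (!is.null(truth$genes) && !is.null(truth$truth))
    truth$genes else NULL
  if (!is.null(truth$truth)) {
    biotype <- truth$genes$biotype
    truth <- truth$truth
  } else {
    biotype <- rep("refseq", nrow(truth$genes))
  }
  tg <- truth$genes
  n <- nrow(tg)
  set.seed(config$seed + 2L)
  runifn <- function(lo, hi) stats::runif(n, lo, hi)

  fc_mf <- rep(1, n)
  padj_mf <- runifn(0.3, 0.9)
  fpkm_m <- runifn(2, 20)
  fpkm_f <- fpkm_m * exp(stats::rnorm(n, 0, 0.02))
  is_m <- tg$sex_bias == "male"
  is_f <- tg$sex_bias == "female"
  is_o <- tg$sex_bias == "other"
  fc_mf[is_m] <- runifn(2.2, 5)[is_m]
  fc_mf[is_f] <- 1 / runifn(2.2, 5)[is_f]
  fc_mf[is_o] <- runifn(1.3, 1.45)[is_o]
  padj_mf[is_m | is_f] <- runifn(1e-4, 0.01)[is_m | is_f]
  padj_mf[is_o] <- runifn(1e-4, 0.01)[is_o]
  fpkm_f[is_m] <- (fpkm_m / fc_mf)[is_m]
  fpkm_m[is_f] <- (fpkm_f * fc_mf)[is_f]

  fc_hypox_m <- runifn(0.85, 1.15)
  fc_hypox_f <- runifn(0.85, 1.15)
  padj_hypox_m <- runifn(0.3, 0.9)
  padj_hypox_f <- runifn(0.3, 0.9)
  cI <- tg$hypox_class == "I"
  cII <- tg$hypox_class == "II"
  # class I: down in the dominant sex after hypophysectomy
  dom_m <- is_m & cI
  dom_f <- is_f & cI
  fc_hypox_m[dom_m] <- runifn(0.1, 0.45)[dom_m]
  padj_hypox_m[dom_m] <- runifn(1e-4, 0.01)[dom_m]
  fc_hypox_f[dom_f] <- runifn(0.1, 0.45)[dom_f]
  padj_hypox_f[dom_f] <- runifn(1e-4, 0.01)[dom_f]
  # class II: up in the opposite sex after hypophysectomy
  opp_f <- is_m & cII
  opp_m <- is_f & cII
  fc_hypox_f[opp_f] <- runifn(2.2, 4)[opp_f]
  padj_hypox_f[opp_f] <- runifn(1e-4, 0.01)[opp_f]
  fc_hypox_m[opp_m] <- runifn(2.2, 4)[opp_m]
  padj_hypox_m[opp_m] <- runifn(1e-4, 0.01)[opp_m]

  if (noise > 0) {
    j <- function(x) x * exp(stats::rnorm(n, 0, noise))
    fc_mf <- j(fc_mf); fc_hypox_m <- j(fc_hypox_m); fc_hypox_f <- j(fc_hypox_f)
  }
  data.frame(gene_id = tg$gene_id, biotype = biotype,
             fpkm_m = fpkm_m, fpkm_f = fpkm_f,
             fc_mf = fc_mf, padj_mf = padj_mf,
             fc_hypox_m = fc_hypox_m, padj_hypox_m = padj_hypox_m,
             fc_hypox_f = fc_hypox_f, padj_hypox_f = padj_hypox_f,
             stringsAsFactors = FALSE)
}
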