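#' Tile the genome and count cut sites per window per sample
#'
#' Windows of `window_bp` tile each chromosome with the given step
#' (default half-window, giving 50% overlapping sliding windows). Counts
#' are raw cut-site counts -- no read extension. A cut at a window
#' boundary belongs to the window whose half-open span contains it.
#'
#' @param tracks Named list of [cut_site_track()] objects (all samples).
#' @param genome Named vector of chromosome lengths.
#' @param window_bp Window size in bp (default 200).
#' @param step Step between window starts (default `window_bp / 2`).
#' @return List with `windows` (interval data frame), `counts` (matrix,
#'   windows x samples) and `libsize` (per-sample total cut counts).
#' @export
window_counts <- function(tracks, genome, window_bp = 200L,
                          step = window_bp %/% 2L) {
  stopifnot(window_bp > 0L, step > 0L, length(tracks) >= 1L)
  wins <- list()
  for (chr in names(genome)) {
    len <- genome[[chr]]
    if (len < window_bp) next
    starts <- seq.int(0L, len - window_bp, by = step)
    wins[[chr]] <- data.frame(chrom = chr, start = starts,
                              end = starts + window_bp,
                              stringsAsFactors = FALSE)
  }
  windows <- do.call(rbind, wins)
  rownames(windows) <- NULL
  counts <- matrix(0, nrow = nrow(windows), ncol = length(tracks),
                   dimnames = list(NULL, names(tracks)))
  for (j in seq_along(tracks)) {
    counts[, j] <- .cuts_in_intervals(tracks[[j]], windows)
  }
  libsize <- vapply(tracks, track_total_cuts, numeric(1))
  if (all(libsize == 0)) warning("all tracks empty; counts are all zero")
  list(windows = windows, counts = counts, libsize = libsize)
}

#' Windowed two-group differential test
#'
#' For each window, counts are pooled within group and tested with a
#' likelihood-ratio G-test against the library-size-proportional
#' expectation (1 df). Fold-change is the ratio of library-size-normalized
#' pooled counts with a pseudocount of 0.5; p-values are BH-adjusted over
#' all tested windows. Windows with zero counts in both groups are
#' excluded.
#'
#' @param wc Output of [window_counts()].
#' @param groups Character/factor vector along samples with exactly two
#'   levels; the first level encountered is group A (direction `up_in_A`
#'   means more open in A).
#' @return Data frame of window statistics: window coordinates,
#'   `mean_cpm_a`, `mean_cpm_b` (per-sample mean counts per million),
#'   `log2fc`, `pvalue`, `padj`.
#' @export
test_windows <- function(wc, groups) {
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(wc$counts))
  lev <- unique(groups)
  if (length(lev) != 2L)
    stop("test_windows requires exactly two groups, got ", length(lev))
  ia <- groups == lev[1L]
  ib <- groups == lev[2L]
  la <- sum(wc$libsize[ia])
  lb <- sum(wc$libsize[ib])
  if (la == 0 || lb == 0) stop("a group has zero total library size")
  oa <- rowSums(wc$counts[, ia, drop = FALSE])
  ob <- rowSums(wc$counts[, ib, drop = FALSE])
  keep <- (oa + ob) > 0
  windows <- wc$windows[keep, , drop = FALSE]
  oa <- oa[keep]; ob <- ob[keep]
  ea <- (oa + ob) * la / (la + lb)
  eb <- (oa + ob) * lb / (la + lb)
  xlx <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  g <- 2 * (xlx(oa, ea) + xlx(ob, eb))
  p <- stats::pchisq(g, df = 1L, lower.tail = FALSE)
  cpm_a <- rowMeans(sweep(wc$counts[keep, ia, drop = FALSE], 2,
                          pmax(wc$libsize[ia], 1), "/")) * 1e6
  cpm_b <- rowMeans(sweep(wc$counts[keep, ib, drop = FALSE], 2,
                          pmax(wc$libsize[ib], 1), "/")) * 1e6
  fc <- ((oa + 0.5) / la) / ((ob + 0.5) / lb)
  out <- data.frame(windows,
                    mean_cpm_a = cpm_a, mean_cpm_b = cpm_b,
                    log2fc = log2(fc), gstat = g, pvalue = p,
                    padj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call differential regions from window statistics
#'
#' Windows passing `|fold-change| > fc_min` and `padj < fdr_max` are
#' merged per direction (overlapping/book-ended significant windows of the
#' same direction form one region; opposite directions never merge), and
#' regions are retained only if they overlap a DHS peak-union interval by
#' at least 1 bp. Each region reports the best (smallest) adjusted p-value
#' and the fold-change of its best window.
#'
#' @param ws Window statistics from [test_windows()].
#' @param fc_min Minimum fold-change (default 2; applied two-sided).
#' @param fdr_max Maximum BH-adjusted p-value (default 0.05).
#' @param peak_union Merged peak intervals; regions not overlapping it are
#'   dropped. `NULL` skips the overlap filter.
#' @return Interval data frame with `direction` (`up_in_A` / `up_in_B`),
#'   `padj` and `fold_change` columns, sorted by decreasing fold-change of
#'   opening within direction.
#' @export
call_differential_regions <- function(ws, fc_min = 2, fdr_max = 0.05,
                                      peak_union = NULL) {
  stopifnot(fc_min >= 1)
  sig <- ws$padj < fdr_max & abs(ws$log2fc) > log2(fc_min)
  sig[is.na(sig)] <- FALSE
  out <- list()
  for (dir in c("up_in_A", "up_in_B")) {
    rows <- ws[sig & (if (dir == "up_in_A") ws$log2fc > 0 else ws$log2fc < 0),
               , drop = FALSE]
    if (nrow(rows) == 0L) next
    reg <- merge_intervals(rows[, c("chrom", "start", "end")])
    hits <- lapply(seq_len(nrow(reg)), function(i) {
      j <- rows$chrom == reg$chrom[i] & rows$start < reg$end[i] &
        rows$end > reg$start[i]
      w <- rows[j, , drop = FALSE]
      best <- order(w$padj, -abs(w$log2fc), w$start)[1L]
      c(padj = w$padj[best], fold_change = 2^abs(w$log2fc[best]))
    })
    reg$direction <- dir
    reg$padj <- vapply(hits, `[[`, numeric(1), "padj")
    reg$fold_change <- vapply(hits, `[[`, numeric(1), "fold_change")
    out[[dir]] <- reg
  }
  if (length(out) == 0L) {
    res <- empty_intervals()
    res$direction <- character()
    res$padj <- numeric()
    res$fold_change <- numeric()
    return(res)
  }
  res <- do.call(rbind, out)
  if (!is.null(peak_union)) {
    res <- res[overlaps_any(res, peak_union), , drop = FALSE]
  }
  res <- res[order(res$direction, -res$fold_change, res$padj, res$chrom,
                   res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' PCA-based sample outlier detection over top differential regions
#'
#' Computes per-sample reads-per-kilobase-per-million (RPKM) over the top
#' `top_n` opening regions (`up_in_A`, ranked by decreasing fold-change),
#' standardizes the matrix, and takes PC1. A sample is flagged when its
#' PC1 coordinate lies on the far side of the midpoint between the two
#' group medians relative to its own label. The decision is made for each
#' requested `top_n`; a sample flagged at any `top_n` is flagged overall.
#'
#' @param regions Differential regions from [call_differential_regions()].
#' @param tracks Named list of sample tracks (order defines samples).
#' @param groups Two-level group vector along samples (first level = A).
#' @param top_n Integer vector of region-list depths (default
#'   `c(200, 600)`); capped at the number of available opening regions.
#' @return Data frame with one row per sample: `sample`, `group`,
#'   per-`top_n` PC1 coordinates and flags, and the combined `flagged`
#'   column.
#' @export
detect_outliers <- function(regions, tracks, groups, top_n = c(200L, 600L)) {
  groups <- as.character(groups)
  stopifnot(length(groups) == length(tracks))
  lev <- unique(groups)
  stopifnot(length(lev) == 2L)
  if (min(table(groups)) < 3L)
    stop("need at least 3 samples per group for outlier detection")
  up <- regions[regions$direction == "up_in_A", , drop = FALSE]
  up <- up[order(-up$fold_change, up$padj, up$chrom, up$start), , drop = FALSE]
  if (nrow(up) == 0L) stop("no opening (up_in_A) regions available")
  libsize <- vapply(tracks, track_total_cuts, numeric(1))
  out <- data.frame(sample = names(tracks), group = groups,
                    stringsAsFactors = FALSE)
  flag_any <- rep(FALSE, length(tracks))
  for (tn in top_n) {
    k <- min(tn, nrow(up))
    sel <- up[seq_len(k), , drop = FALSE]
    kb <- (sel$end - sel$start) / 1000
    rpkm <- vapply(seq_along(tracks), function(j) {
      .cuts_in_intervals(tracks[[j]], sel) / kb / (libsize[j] / 1e6)
    }, numeric(k))
    rpkm <- t(rpkm)                      # samples x regions
    sdv <- apply(rpkm, 2, stats::sd)
    if (all(sdv == 0)) stop("degenerate region matrix: zero variance")
    z <- scale(rpkm[, sdv > 0, drop = FALSE])
    pc1 <- stats::prcomp(z, center = FALSE, scale. = FALSE)$x[, 1L]
    if (stats::sd(pc1) == 0) stop("degenerate PC1: zero variance")
    med_a <- stats::median(pc1[groups == lev[1L]])
    med_b <- stats::median(pc1[groups == lev[2L]])
    if (med_a == med_b) stop("degenerate PC1: group medians coincide")
    midpoint <- (med_a + med_b) / 2
    own_med <- ifelse(groups == lev[1L], med_a, med_b)
    flag <- sign(pc1 - midpoint) != sign(own_med - midpoint)
    out[[paste0("pc1_top", tn)]] <- pc1
    out[[paste0("flag_top", tn)]] <- flag
    flag_any <- flag_any | flag
  }
  out$flagged <- flag_any
  rownames(out) <- NULL
  out
}
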