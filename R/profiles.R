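#' Build 2-kb windows centered on DHS midpoints
#'
#' The window for a DHS is `[mid - 1000, mid + 1000)` with
#' `mid = floor((start + end) / 2)`. Windows extending past a chromosome
#' end (or below 0) are dropped with a warning.
#'
#' @param dhs Interval data frame.
#' @param genome Named vector of chromosome lengths.
#' @param flank Half-window in bp (default 1000, i.e. 2-kb windows).
#' @return Interval data frame of centered windows.
#' @export
center_windows <- function(dhs, genome, flank = 1000L) {
  validate_intervals(dhs)
  mid <- floor((dhs$start + dhs$end) / 2)
  win <- dhs
  win$start <- as.integer(mid - flank)
  win$end <- as.integer(mid + flank)
  len <- unname(genome[win$chrom])
  keep <- !is.na(len) & win$start >= 0L & win$end <= len
  if (any(!keep))
    warning(sum(!keep), " window(s) extending past chromosome ends dropped")
  out <- win[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalized DNase-I cut-site aggregate profile
#'
#' Sums cut counts at each of the 2000 positions across midpoint-centered
#' windows, normalizes by the per-million count of cuts falling in the
#' reference DHS set and by the number of windows, smooths with LOWESS
#' (robustness iterations 0) and subtracts the baseline estimated from the
#' first 200 positions:
#' `V(t) = S(t) / (R / 1e6) / N`, then `values = lowess(V) - baseline`.
#' Doubling sequencing depth uniformly leaves the profile unchanged, so
#' profiles from different libraries are directly comparable.
#'
#' @param track A [cut_site_track()] (pool replicate libraries with
#'   [pool_tracks()] first for a group profile).
#' @param windows Centered windows from [center_windows()]; all must share
#'   one width, which defines the profile length.
#' @param reference_dhs Reference DHS interval set; `R` is the number of
#'   track cuts falling within it (must be > 0).
#' @param span LOWESS span `f` (default 0.02, about a 40-bp bandwidth on a
#'   2-kb window).
#' @return Object of class `aggregate_profile`: list with `values`
#'   (length = window width), `offsets` (bp relative to window start minus
#'   flank), `peak_value`, `n_regions`, `reference_read_count`, `raw`
#'   (pre-smoothing normalized profile).
#' @export
aggregate_profile <- function(track, windows, reference_dhs, span = 0.02) {
  validate_intervals(windows)
  if (nrow(windows) == 0L) stop("no windows to aggregate")
  width <- unique(windows$end - windows$start)
  if (length(width) != 1L) stop("windows must all have the same width")
  r_total <- sum(.cuts_in_intervals(track, reference_dhs))
  if (r_total == 0) stop("no cut sites in the reference DHS set (R = 0)")
  s <- numeric(width)
  for (chr in intersect(unique(windows$chrom), names(track$cuts))) {
    d <- track$cuts[[chr]]
    if (nrow(d) == 0L) next
    idx <- which(windows$chrom == chr)
    lo <- findInterval(windows$start[idx] - 0.5, d$pos) + 1L
    hi <- findInterval(windows$end[idx] - 0.5, d$pos)
    for (k in seq_along(idx)) {
      if (hi[k] < lo[k]) next
      sel <- lo[k]:hi[k]
      off <- d$pos[sel] - windows$start[idx[k]] + 1L
      s <- s + .tabulate_counts(off, d$count[sel], width)
    }
  }
  v <- s / (r_total / 1e6) / nrow(windows)
  sm <- stats::lowess(seq_len(width), v, f = span, iter = 0)$y
  baseline <- mean(sm[seq_len(min(200L, width))])
  values <- sm - baseline
  structure(list(values = values,
                 offsets = seq_len(width) - 1L - width %/% 2L,
                 peak_value = max(values),
                 n_regions = nrow(windows),
                 reference_read_count = r_total,
                 raw = v),
            class = "aggregate_profile")
}

# weighted tabulate: sum counts per offset bin
.tabulate_counts <- function(bin, w, nbins) {
  as.numeric(rowsum_vec(bin, w, nbins))
}

rowsum_vec <- function(bin, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, group = bin)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' @export
print.aggregate_profile <- function(x, ...) {
  cat("aggregate_profile over", x$n_regions, "regions;",
      "peak", signif(x$peak_value, 4), ";",
      "reference reads", format(x$reference_read_count, big.mark = ","), "\n")
  invisible(x)
}

#' Reads-in-peaks-per-million (RiPPM) scaling factor
#'
#' The factor is the number of track cut sites falling within the peak
#' union divided by one million; raw counts divided by it are RiPPM
#' normalized.
#'
#' @param track A [cut_site_track()].
#' @param peak_union Merged peak intervals (non-overlapping).
#' @return Positive scaling factor.
#' @export
rippm_factor <- function(track, peak_union) {
  validate_intervals(peak_union)
  if (nrow(peak_union) == 0L) stop("empty peak union")
  n <- sum(.cuts_in_intervals(track, peak_union))
  if (n == 0) stop("no reads in peaks; RiPPM factor undefined")
  n / 1e6
}

#' Apply a RiPPM scaling factor
#'
#' @param count Raw count(s).
#' @param factor Factor from [rippm_factor()].
#' @return `count / factor`.
#' @export
rippm_normalize <- function(count, factor) {
  stopifnot(factor > 0)
  count / factor
}

#' Export a profile as a TSV of offset/value pairs
#'
#' @param profile An `aggregate_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(
    data.frame(offset = profile$offsets, value = profile$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
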