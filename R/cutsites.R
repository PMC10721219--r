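#' Cut-site tracks
#'
#' A cut-site track stores, per chromosome, a sparse table of DNase-I cut
#' positions (0-based bp) with integer counts, plus the library's total
#' mapped read count. A DNase-I cut site is the 5'-end of a sequence read:
#' position `start` for a plus-strand read and `end - 1` for a minus-strand
#' read.
#'
#' @param cuts Named list (by chromosome) of data frames with sorted
#'   integer `pos` and positive integer `count` columns.
#' @param total_mapped_reads Total reads in the library (counts sum to at
#'   most this).
#' @return An object of class `cut_site_track`.
#' @export
cut_site_track <- function(cuts = list(), total_mapped_reads = 0L) {
  for (chr in names(cuts)) {
    d <- cuts[[chr]]
    stopifnot(is.data.frame(d), all(c("pos", "count") %in% names(d)))
    if (nrow(d) && (is.unsorted(d$pos, strictly = TRUE)))
      cuts[[chr]] <- d[order(d$pos), , drop = FALSE]
    if (any(d$count < 0)) stop("negative cut count on ", chr)
  }
  total <- sum(vapply(cuts, function(d) sum(d$count), numeric(1)))
  if (total > total_mapped_reads)
    stop("cut counts exceed total_mapped_reads")
  structure(list(cuts = cuts, total_mapped_reads = as.numeric(total_mapped_reads)),
            class = "cut_site_track")
}

#' @export
print.cut_site_track <- function(x, ...) {
  cat("cut_site_track:", length(x$cuts), "chromosome(s),",
      format(track_total_cuts(x), big.mark = ","), "cut sites,",
      format(x$total_mapped_reads, big.mark = ","), "mapped reads\n")
  invisible(x)
}

#' Total number of cut sites in a track
#' @param track A `cut_site_track`.
#' @return Numeric scalar.
#' @export
track_total_cuts <- function(track) {
  sum(vapply(track$cuts, function(d) sum(d$count), numeric(1)))
}

# Build a sparse per-chromosome cut table from raw integer positions.
.positions_to_cuts <- function(chrom, pos) {
  out <- list()
  for (chr in sort(unique(chrom))) {
    p <- sort(pos[chrom == chr])
    r <- rle(p)
    out[[chr]] <- data.frame(pos = r$values, count = r$lengths)
  }
  out
}

#' Extract DNase-I cut sites from aligned reads
#'
#' Each read contributes one cut at its 5' end: `start` for `+` strand
#' reads, `end - 1` for `-` strand reads. When a genome is supplied,
#' reads whose cut site falls off the chromosome (or on an unknown
#' chromosome) are skipped with a warning reporting the skip count.
#'
#' @param reads Data frame with `chrom`, `start`, `end`, `strand`
#'   (strand in `+`/`-`).
#' @param genome Optional named vector of chromosome lengths.
#' @return A [cut_site_track()] with `total_mapped_reads = nrow(reads)`
#'   and attribute `skipped` giving the number of skipped reads.
#' @export
extract_cut_sites <- function(reads, genome = NULL) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(reads)))
  if (nrow(reads) && any(!reads$strand %in% c("+", "-")))
    stop("reads must have strand '+' or '-'")
  if (any(reads$start >= reads$end)) stop("read with start >= end")
  pos <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  chrom <- reads$chrom
  skipped <- 0L
  if (!is.null(genome)) {
    len <- unname(genome[chrom])
    keep <- !is.na(len) & pos >= 0L & pos < len
    skipped <- sum(!keep)
    if (skipped > 0L)
      warning(skipped, " read(s) off chromosome ends skipped")
    pos <- pos[keep]
    chrom <- chrom[keep]
  }
  tr <- cut_site_track(.positions_to_cuts(chrom, pos),
                       total_mapped_reads = nrow(reads))
  attr(tr, "skipped") <- skipped
  tr
}

#' Pool cut-site tracks
#'
#' Sums sparse counts position-wise and adds library totals; the pooled
#' track is what aggregate profiles use for a treatment group (replicate
#' libraries combined before normalization).
#'
#' @param tracks List of `cut_site_track` objects.
#' @return A single pooled `cut_site_track`.
#' @export
pool_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  chroms <- sort(unique(unlist(lapply(tracks, function(t) names(t$cuts)))))
  cuts <- list()
  for (chr in chroms) {
    parts <- lapply(tracks, function(t) t$cuts[[chr]])
    parts <- parts[!vapply(parts, is.null, TRUE)]
    all <- do.call(rbind, parts)
    agg <- rowsum(all$count, group = all$pos)
    cuts[[chr]] <- data.frame(pos = as.integer(rownames(agg)),
                              count = as.numeric(agg[, 1L]))
  }
  cut_site_track(cuts, sum(vapply(tracks, function(t) t$total_mapped_reads,
                                  numeric(1))))
}

# Count cuts falling within each (0-based half-open) interval of one track.
# Intervals may overlap each other; each is counted independently.
.cuts_in_intervals <- function(track, intervals) {
  n <- numeric(nrow(intervals))
  for (chr in intersect(unique(intervals$chrom), names(track$cuts))) {
    d <- track$cuts[[chr]]
    if (nrow(d) == 0L) next
    cs <- cumsum(d$count)
    idx <- which(intervals$chrom == chr)
    hi <- findInterval(intervals$end[idx] - 0.5, d$pos)
    lo <- findInterval(intervals$start[idx] - 0.5, d$pos)
    n[idx] <- c(0, cs)[hi + 1L] - c(0, cs)[lo + 1L]
  }
  n
}

#' Count cut sites per interval
#'
#' @param track A `cut_site_track`.
#' @param intervals Interval data frame (counted independently, so pass a
#'   merged set when a base-level union is intended).
#' @return Numeric vector of cut counts along `intervals` rows.
#' @export
cuts_in_intervals <- function(track, intervals) {
  validate_intervals(intervals)
  .cuts_in_intervals(track, intervals)
}

#' Minimal Poisson peak caller for cut-site tracks
#'
#' Sliding windows (step = half window) whose cut count exceeds a Poisson
#' upper-tail threshold against the larger of the genome-wide mean rate
#' and a local background rate (mean over `local_bg_bp` centered on the
#' window) are merged into peaks. A simple deterministic stand-in for a
#' full-featured caller, adequate for cut-site data where no read
#' extension is wanted.
#'
#' @param track A `cut_site_track`.
#' @param genome Named vector of chromosome lengths.
#' @param window_bp Window width in bp (default 200).
#' @param local_bg_bp Local background span in bp (default 10000); must
#'   exceed `window_bp`.
#' @param p_threshold Poisson upper-tail threshold (default 1e-5).
#' @return Interval data frame of peaks (possibly empty).
#' @export
call_peaks <- function(track, genome, window_bp = 200L, local_bg_bp = 10000L,
                       p_threshold = 1e-5) {
  stopifnot(window_bp < local_bg_bp)
  total <- track_total_cuts(track)
  if (total == 0) return(empty_intervals())
  gsize <- sum(as.numeric(genome))
  lambda_global <- total / gsize * window_bp
  sig <- list()
  for (chr in names(genome)) {
    len <- genome[[chr]]
    d <- track$cuts[[chr]]
    if (is.null(d) || nrow(d) == 0L || len < window_bp) next
    starts <- seq.int(0L, len - window_bp, by = max(1L, window_bp %/% 2L))
    cs <- c(0, cumsum(d$count))
    cnt_between <- function(s, e) {
      cs[findInterval(e - 0.5, d$pos) + 1L] - cs[findInterval(s - 0.5, d$pos) + 1L]
    }
    cnt <- cnt_between(starts, starts + window_bp)
    ctr <- starts + window_bp / 2
    ls <- pmax(0, ctr - local_bg_bp / 2)
    le <- pmin(len, ctr + local_bg_bp / 2)
    lambda_local <- cnt_between(ls, le) / (le - ls) * window_bp
    lambda <- pmax(lambda_global, lambda_local)
    p <- stats::ppois(cnt - 1, lambda, lower.tail = FALSE)
    keep <- cnt > 0 & p <= p_threshold
    if (any(keep))
      sig[[chr]] <- data.frame(chrom = chr, start = starts[keep],
                               end = starts[keep] + window_bp,
                               stringsAsFactors = FALSE)
  }
  if (length(sig) == 0L) return(empty_intervals())
  merge_intervals(do.call(rbind, sig))
}

#' Filter peaks against a blacklist and remove "straight peaks"
#'
#' Removes (1) any peak overlapping a blacklisted region by >= 1 bp and
#' (2) any "straight peak", i.e. a peak whose entire read support is
#' >= 5 copies of a single read signature (identical chrom, start, end,
#' strand) with no other distinct read overlapping the peak.
#'
#' @param peaks Interval data frame of called peaks.
#' @param blacklist Interval data frame of excluded regions (may be empty).
#' @param reads Read data frame (`chrom`, `start`, `end`, `strand`) used
#'   for the straight-peak test; may be `NULL` to skip it.
#' @return The retained peaks, with attribute `removed` giving counts per
#'   filter.
#' @export
filter_peaks <- function(peaks, blacklist = NULL, reads = NULL) {
  validate_intervals(peaks)
  n_bl <- 0L
  if (!is.null(blacklist) && nrow(blacklist)) {
    drop <- overlaps_any(peaks, blacklist)
    n_bl <- sum(drop)
    peaks <- peaks[!drop, , drop = FALSE]
  }
  n_sp <- 0L
  if (!is.null(reads) && nrow(reads) && nrow(peaks)) {
    straight <- vapply(seq_len(nrow(peaks)), function(i) {
      p <- peaks[i, ]
      ov <- reads$chrom == p$chrom & reads$start < p$end & reads$end > p$start
      if (!any(ov)) return(FALSE)
      sig <- paste(reads$chrom[ov], reads$start[ov], reads$end[ov],
                   reads$strand[ov])
      tab <- table(sig)
      length(tab) == 1L && tab[[1L]] >= 5L
    }, logical(1))
    n_sp <- sum(straight)
    peaks <- peaks[!straight, , drop = FALSE]
  }
  rownames(peaks) <- NULL
  attr(peaks, "removed") <- c(blacklist = n_bl, straight = n_sp)
  peaks
}
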