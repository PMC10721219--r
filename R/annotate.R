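#' Assign each DHS its target gene: nearest TSS in the same TAD
#'
#' A DHS belongs to the TAD containing its midpoint; its target is the
#' gene in that TAD whose TSS is closest to the midpoint (ties broken by
#' the smaller TSS coordinate). Returns `NA` for DHS outside all TADs or
#' in TADs without genes. A nearer TSS in a different TAD is never chosen.
#'
#' @param dhs Interval data frame.
#' @param genes Data frame with `gene_id`, `chrom`, `tss`, `tad_id`.
#' @param tads Data frame with `chrom`, `start`, `end`, `tad_id`
#'   (non-overlapping).
#' @return Character vector of gene ids (or `NA`) along `dhs` rows.
#' @export
assign_target_gene <- function(dhs, genes, tads) {
  validate_intervals(dhs)
  stopifnot(all(c("gene_id", "tss", "tad_id") %in% names(genes)),
            all(c("chrom", "start", "end", "tad_id") %in% names(tads)))
  mid <- floor((dhs$start + dhs$end) / 2)
  out <- rep(NA_character_, nrow(dhs))
  genes_by_tad <- split(genes, genes$tad_id)
  for (i in seq_len(nrow(dhs))) {
    in_tad <- tads$chrom == dhs$chrom[i] & tads$start <= mid[i] &
      mid[i] < tads$end
    if (!any(in_tad)) next
    g <- genes_by_tad[[tads$tad_id[which(in_tad)[1L]]]]
    if (is.null(g) || nrow(g) == 0L) next
    d <- abs(g$tss - mid[i])
    best <- order(d, g$tss)[1L]
    out[i] <- g$gene_id[best]
  }
  out
}

#' Assign a chromatin state to each DHS
#'
#' Each DHS takes the state with the largest number of overlapping base
#' pairs (summed across segments of that state). On an exact tie, the
#' state whose overlapping segment has the smaller genomic start
#' coordinate wins. A DHS not fully covered by the segmentation is an
#' error (state maps tile the genome).
#'
#' @param dhs Interval data frame.
#' @param segments Data frame with `chrom`, `start`, `end`, `state` for
#'   one sex's segmentation.
#' @return Character vector of states along `dhs` rows.
#' @export
assign_chrom_state <- function(dhs, segments) {
  validate_intervals(dhs)
  validate_intervals(segments)
  stopifnot("state" %in% names(segments))
  out <- rep(NA_character_, nrow(dhs))
  for (chr in unique(dhs$chrom)) {
    qi <- which(dhs$chrom == chr)
    seg <- segments[segments$chrom == chr, , drop = FALSE]
    if (nrow(seg) == 0L) stop("DHS on ", chr, " uncovered by segmentation")
    hits <- IRanges::findOverlaps(.iranges(dhs[qi, , drop = FALSE]),
                                  .iranges(seg))
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- pmin(dhs$end[qi][qh], seg$end[sh]) -
      pmax(dhs$start[qi][qh], seg$start[sh])
    for (k in seq_along(qi)) {
      rows <- which(qh == k)
      if (length(rows) == 0L || sum(ov[rows]) < dhs$end[qi[k]] - dhs$start[qi[k]])
        stop("DHS ", chr, ":", dhs$start[qi[k]], "-", dhs$end[qi[k]],
             " uncovered by segmentation")
      st <- seg$state[sh[rows]]
      bp <- rowsum(ov[rows], group = st)
      first_start <- vapply(split(seg$start[sh[rows]], st), min, numeric(1))
      cand <- data.frame(state = rownames(bp), bp = bp[, 1L],
                         start = first_start[rownames(bp)])
      best <- cand[order(-cand$bp, cand$start), , drop = FALSE][1L, ]
      out[qi[k]] <- best$state
    }
  }
  out
}

#' Label DHS as transcription-factor bound
#'
#' Bound means >= 1 bp overlap with any TF ChIP peak; a book-ended peak
#' (0 bp shared) does not count.
#'
#' @param dhs Interval data frame.
#' @param tf_peaks TF peak intervals.
#' @return Logical vector along `dhs` rows.
#' @export
label_bound <- function(dhs, tf_peaks) {
  overlaps_any(dhs, tf_peaks)
}

# ---- PWM motif scanning ------------------------------------------------

#' Construct a position weight matrix object
#'
#' @param matrix 4 x L numeric matrix of per-position probabilities; rows
#'   named A, C, G, T, each column summing to 1.
#' @param motif_id Motif identifier.
#' @param background Background nucleotide frequencies (default uniform).
#' @return Object of class `pwm`.
#' @export
pwm <- function(matrix, motif_id = "motif", background = rep(0.25, 4)) {
  stopifnot(nrow(matrix) == 4L, ncol(matrix) >= 4L)
  if (is.null(rownames(matrix))) rownames(matrix) <- c("A", "C", "G", "T")
  matrix <- matrix[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(abs(colSums(matrix) - 1) > 1e-9))
    stop("PWM columns must sum to 1")
  background <- background / sum(background)
  names(background) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, matrix = matrix,
                 background = background), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$motif_id, "of width", ncol(x$matrix), "\n")
  invisible(x)
}

#' Read a motif in MEME minimal format
#'
#' Parses the first motif block (`MOTIF` name plus a
#' `letter-probability matrix` section, alphabet ACGT).
#'
#' @param path Path to a MEME-format motif file.
#' @return A [pwm()].
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  mline <- grep("^MOTIF", lines)
  if (length(mline) == 0L) stop("no MOTIF block in ", path)
  id <- strsplit(trimws(lines[mline[1L]]), "\\s+")[[1L]][2L]
  hline <- grep("letter-probability matrix", lines)
  hline <- hline[hline > mline[1L]][1L]
  if (is.na(hline)) stop("no letter-probability matrix in ", path)
  rows <- list()
  i <- hline + 1L
  while (i <= length(lines) && grepl("^\\s*[0-9.eE+-]", lines[i])) {
    rows[[length(rows) + 1L]] <-
      as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]])
    i <- i + 1L
  }
  m <- t(do.call(rbind, rows))
  rownames(m) <- c("A", "C", "G", "T")
  m <- sweep(m, 2, colSums(m), "/")   # renormalize rounded rows
  pwm(m, motif_id = id)
}

#' Read a motif in TRANSFAC count-matrix format
#'
#' Parses numbered count rows (`01 cA cC cG cT consensus`); counts are
#' converted to probabilities with a pseudocount.
#'
#' @param path Path to a TRANSFAC matrix file.
#' @param pseudocount Added to each count before normalization
#'   (default 0.5).
#' @return A [pwm()].
#' @export
read_transfac <- function(path, pseudocount = 0.5) {
  lines <- readLines(path)
  id_line <- grep("^(ID|NA)\\s", lines, value = TRUE)
  id <- if (length(id_line)) strsplit(id_line[1L], "\\s+")[[1L]][2L]
        else "transfac"
  rows <- grep("^[0-9]+\\s", lines, value = TRUE)
  if (length(rows) == 0L) stop("no count rows in ", path)
  counts <- t(vapply(strsplit(trimws(rows), "\\s+"), function(f)
    as.numeric(f[2:5]), numeric(4)))
  counts <- counts + pseudocount
  m <- t(counts / rowSums(counts))
  rownames(m) <- c("A", "C", "G", "T")
  pwm(m, motif_id = id)
}

# integer-scaled log-likelihood score matrix (positions x 4), floored so
# zero-probability entries stay finite
.pwm_score_matrix <- function(p, scale = 1000) {
  probs <- pmax(p$matrix, 1e-10)
  lo <- log2(probs / p$background)
  round(t(lo) * scale)     # L x 4 integer matrix
}

# exact null distribution of the integer score under the background;
# returns the smallest integer score with upper-tail P <= p_threshold
.pwm_score_threshold <- function(scores, bg, p_threshold) {
  offset <- -sum(apply(scores, 1L, min))
  width <- sum(apply(scores, 1L, max)) + offset + 1L
  dist <- numeric(width)
  dist[offset + 1L] <- 1        # score 0 before any position
  cur_min <- 0L
  cur_max <- 0L
  for (i in seq_len(nrow(scores))) {
    nxt <- numeric(width)
    for (b in 1:4) {
      sft <- scores[i, b]
      src <- (cur_min + offset + 1L):(cur_max + offset + 1L)
      nxt[src + sft] <- nxt[src + sft] + dist[src] * bg[b]
    }
    dist <- nxt
    cur_min <- cur_min + min(scores[i, ])
    cur_max <- cur_max + max(scores[i, ])
  }
  tail_p <- rev(cumsum(rev(dist)))
  ok <- which(tail_p <= p_threshold)
  if (length(ok) == 0L) return(cur_max + 1L)   # nothing passes
  ok[1L] - 1L - offset
}

.revcomp_chars <- function(chars) {
  rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[chars])
}

#' Scan a sequence for PWM matches at an exact p-value threshold
#'
#' Scores every offset on both strands with the log-likelihood ratio of
#' the PWM against a 0-order background, calling hits at the score
#' threshold derived from the exact null score distribution (dynamic
#' programming over positions) at `p <= p_threshold` per offset/strand.
#' Offsets whose window contains `N` are skipped. Sequences shorter than
#' the motif yield zero hits.
#'
#' @param sequence Character scalar over A/C/G/T/N.
#' @param p A [pwm()].
#' @param p_threshold Per-position p-value threshold (default 5e-4).
#' @return Data frame with `position` (0-based offset on the forward
#'   strand), `strand`, `score` (bits). `nrow` is the motif count of the
#'   sequence.
#' @export
scan_motif <- function(sequence, p, p_threshold = 5e-4) {
  stopifnot(inherits(p, "pwm"), is.character(sequence), length(sequence) == 1L)
  L <- ncol(p$matrix)
  chars <- strsplit(toupper(sequence), "")[[1L]]
  empty <- data.frame(position = integer(), strand = character(),
                      score = numeric())
  if (length(chars) < L) return(empty)
  if (any(!chars %in% c("A", "C", "G", "T", "N")))
    stop("sequence contains characters outside A/C/G/T/N")
  scores <- .pwm_score_matrix(p)
  thr <- .pwm_score_threshold(scores, p$background, p_threshold)
  code <- match(chars, c("A", "C", "G", "T"))   # NA for N
  n_off <- length(chars) - L + 1L
  scan_strand <- function(code_vec) {
    vals <- rep(NA_integer_, n_off)
    total <- integer(n_off)
    valid <- rep(TRUE, n_off)
    for (i in seq_len(L)) {
      b <- code_vec[i:(i + n_off - 1L)]
      valid <- valid & !is.na(b)
      total <- total + ifelse(is.na(b), 0L, scores[cbind(i, b)])
    }
    list(score = total, valid = valid)
  }
  fw <- scan_strand(code)
  rc_code <- match(.revcomp_chars(chars), c("A", "C", "G", "T"))
  rv <- scan_strand(rc_code)
  hits_f <- which(fw$valid & fw$score >= thr)
  hits_r_rc <- which(rv$valid & rv$score >= thr)
  # map reverse-complement offsets back to forward coordinates
  hits_r <- length(chars) - L + 1L - hits_r_rc + 1L - 1L  # 0-based below
  out <- rbind(
    if (length(hits_f))
      data.frame(position = hits_f - 1L, strand = "+",
                 score = fw$score[hits_f] / 1000),
    if (length(hits_r_rc))
      data.frame(position = hits_r, strand = "-",
                 score = rv$score[hits_r_rc] / 1000)
  )
  if (is.null(out)) return(empty)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count PWM hits in each of several sequences
#'
#' @param sequences Character vector of sequences.
#' @param p A [pwm()].
#' @param p_threshold Passed to [scan_motif()].
#' @return Integer vector of hit counts.
#' @export
count_motifs <- function(sequences, p, p_threshold = 5e-4) {
  vapply(sequences, function(s) nrow(scan_motif(s, p, p_threshold)),
         integer(1), USE.NAMES = FALSE)
}
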