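# Brute-force oracles and tiny fixtures shared across tests. Oracles are
# deliberately naive (per-base masks, quadratic scans, explicit
# enumerations) and independent of the package's implementations.

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 5000,
                             max_len = 200) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             name = ".", score = 0, strand = ".",
             stringsAsFactors = FALSE)
}

# per-base occupancy oracle for interval merging
oracle_merge <- function(x, max_pos = 10000) {
  out <- list()
  for (chr in sort(unique(x$chrom))) {
    mask <- logical(max_pos)
    part <- x[x$chrom == chr, ]
    for (i in seq_len(nrow(part)))
      mask[(part$start[i] + 1):part$end[i]] <- TRUE
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep))
      out[[chr]] <- data.frame(chrom = chr, start = starts[keep],
                               end = ends[keep], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# quadratic pairwise overlap oracle
oracle_overlaps_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] &
          subject$end > query$start[i])
  }, logical(1))
}

# explicit-enumeration two-sided Fisher oracle via binomial coefficients
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  as <- max(0, c1 - r2):min(r1, c1)
  p <- exp(lchoose(r1, as) + lchoose(r2, c1 - as) - lchoose(n, c1))
  p_obs <- p[as == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# step-up BH oracle from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  padj_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  out <- numeric(m)
  out[o] <- padj_sorted
  out
}

# track with cuts at given positions (counts default 1 each)
track_from_positions <- function(chrom, pos, total = length(pos)) {
  cuts <- list()
  for (chr in sort(unique(chrom))) {
    p <- sort(pos[chrom == chr])
    r <- rle(p)
    cuts[[chr]] <- data.frame(pos = r$values, count = r$lengths)
  }
  cut_site_track(cuts, total_mapped_reads = total)
}

# small, fast simulation setup for closed-loop tests
tiny_sim_config <- function(seed = 7, ...) {
  sim_config(seed = seed, genome = c(chrT = 2e6),
             n_dhs = c(dynamic_male = 40, static_male = 40,
                       static_female = 30, dynamic_indep = 0,
                       background = 200),
             n_high = 4, n_low = 4, n_female = 3,
             depth = 4e4, n_tads = 10, genes_per_tad = 3, ...)
}
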