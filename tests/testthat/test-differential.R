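make_two_group_tracks <- function(counts_a, counts_b, pos = 500L,
                                  chrom = "chr1", extra = NULL) {
  # one informative position; `extra` adds balancing cuts far away so that
  # library sizes can be equalized
  mk <- function(n, lib) {
    pos_all <- c(rep(pos, n), rep(9000L, lib - n))
    track_from_positions(rep(chrom, length(pos_all)), pos_all)
  }
  lib <- max(counts_a, counts_b) + 50L
  c(lapply(counts_a, mk, lib = lib), lapply(counts_b, mk, lib = lib))
}

test_that("window counting respects the half-open convention", {
  tr <- track_from_positions(rep("chr1", 10), rep(150L, 10))
  wc <- window_counts(list(s1 = tr, s2 = tr), c(chr1 = 1000L),
                      window_bp = 200L, step = 200L)
  w_hit <- wc$windows$start <= 150 & wc$windows$end > 150
  expect_equal(unname(wc$counts[w_hit, "s1"]), 10)
  expect_equal(sum(wc$counts[, "s1"]), 10)

  # boundary cut at position 200 belongs to [200, 400), not [0, 200)
  tr2 <- track_from_positions("chr1", 200L)
  wc2 <- window_counts(list(s = tr2), c(chr1 = 1000L), 200L, step = 200L)
  expect_equal(unname(wc2$counts[, "s"]), c(0, 1, 0, 0, 0))
})

test_that("non-overlapping tiling conserves total counts", {
  set.seed(8)
  pos <- sample.int(9800L, 500, replace = TRUE) - 1L
  tr <- track_from_positions(rep("chr1", 500), pos)
  wc <- window_counts(list(a = tr, b = tr), c(chr1 = 10000L),
                      window_bp = 200L, step = 200L)
  expect_equal(sum(wc$counts[, "a"]), 500)
})

test_that("G-test matches the hand-computed example and the null identity", {
  # equal pooled counts, equal library sizes: no change
  tr <- make_two_group_tracks(c(10L, 10L), c(10L, 10L))
  names(tr) <- c("a1", "a2", "b1", "b2")
  wc <- window_counts(tr, c(chr1 = 10000L), 200L, step = 200L)
  ws <- test_windows(wc, c("A", "A", "B", "B"))
  row <- ws[ws$start <= 500 & ws$end > 500, ]
  expect_equal(row$log2fc, 0)
  expect_equal(row$pvalue, 1)

  # pooled A = 33, B = 6, equal library sizes: G = 20.58, p ~ 5.7e-6
  tr <- make_two_group_tracks(c(17L, 16L), c(3L, 3L))
  names(tr) <- c("a1", "a2", "b1", "b2")
  wc <- window_counts(tr, c(chr1 = 10000L), 200L, step = 200L)
  ws <- test_windows(wc, c("A", "A", "B", "B"))
  row <- ws[ws$start <= 500 & ws$end > 500, ]
  expect_equal(row$gstat, 20.58, tolerance = 1e-3)
  expect_equal(row$pvalue, 5.7e-6, tolerance = 0.02)

  expect_error(test_windows(wc, c("A", "A", "A", "A")), "two groups")
})

test_that("G-test significance calls agree with an exact binomial oracle", {
  set.seed(21)
  n_win <- 50
  oa <- rpois(n_win, 20)
  ob <- rpois(n_win, 20)
  hot <- sample(n_win, 10)
  oa[hot] <- oa[hot] + 40      # some truly differential windows
  la <- 1e5; lb <- 1e5
  ea <- la / (la + lb)
  g_p <- vapply(seq_len(n_win), function(i) {
    e_a <- (oa[i] + ob[i]) * ea
    e_b <- (oa[i] + ob[i]) * (1 - ea)
    g <- 2 * (ifelse(oa[i] > 0, oa[i] * log(oa[i] / e_a), 0) +
                ifelse(ob[i] > 0, ob[i] * log(ob[i] / e_b), 0))
    pchisq(g, 1, lower.tail = FALSE)
  }, numeric(1))
  binom_p <- vapply(seq_len(n_win), function(i)
    binom.test(oa[i], oa[i] + ob[i], p = ea)$p.value, numeric(1))
  agreement <- mean((g_p < 0.05) == (binom_p < 0.05))
  expect_gte(agreement, 0.95)
})

test_that("differential regions honour thresholds, union filter and direction", {
  ws <- data.frame(
    chrom = "chr1",
    start = c(100L, 200L, 300L, 5000L),
    end = c(300L, 400L, 500L, 5200L),
    mean_cpm_a = 0, mean_cpm_b = 0,
    log2fc = c(2, 2.5, -2.2, 3),
    gstat = 0,
    pvalue = c(1e-6, 1e-7, 1e-6, 1e-8),
    padj = c(1e-5, 1e-6, 1e-5, 1e-7))
  union <- genomic_intervals("chr1", 0, 1000)
  reg <- call_differential_regions(ws, fc_min = 2, fdr_max = 0.05, union)
  # adjacent opposite directions stay separate; outside-union region dropped
  expect_equal(nrow(reg), 2L)
  expect_setequal(reg$direction, c("up_in_A", "up_in_B"))
  up <- reg[reg$direction == "up_in_A", ]
  expect_equal(c(up$start, up$end), c(100L, 400L))
  expect_equal(up$padj, 1e-6)

  # region count is monotone non-increasing in fc_min
  n1 <- nrow(call_differential_regions(ws, fc_min = 2, fdr_max = 0.05))
  n2 <- nrow(call_differential_regions(ws, fc_min = 5, fdr_max = 0.05))
  expect_lte(n2, n1)
  n3 <- nrow(call_differential_regions(ws, fc_min = 2, fdr_max = 1e-6))
  expect_lte(n3, n1)
})

test_that("BH adjustment is monotone in rank order and capped at 1", {
  set.seed(4)
  p <- runif(100)
  padj <- bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(padj[o]) >= -1e-12))
  expect_true(all(padj <= 1))
  expect_true(all(padj >= p))
})

test_that("outlier detection flags a label-swapped sample", {
  set.seed(17)
  regions <- data.frame(chrom = "chr1",
                        start = seq(0L, 19000L, by = 1000L),
                        end = seq(0L, 19000L, by = 1000L) + 400L,
                        name = ".", score = 0, strand = ".",
                        direction = "up_in_A",
                        padj = 1e-6,
                        fold_change = seq(4, 2.1, length.out = 20))
  mk_sample <- function(level) {
    pos <- unlist(lapply(seq_len(nrow(regions)), function(i)
      rep(regions$start[i] + 200L, rpois(1, level))))
    pos <- c(pos, rep(500000L, 1000L))   # fixed off-region background
    track_from_positions(rep("chr1", length(pos)), pos)
  }
  tracks <- c(lapply(1:4, function(i) mk_sample(40)),
              list(mk_sample(10)),                       # mislabeled "high"
              lapply(1:4, function(i) mk_sample(10)))
  names(tracks) <- paste0("s", 1:9)
  groups <- c(rep("high", 5), rep("low", 4))
  qc <- detect_outliers(regions, tracks, groups, top_n = c(10L, 20L))
  expect_equal(which(qc$flagged), 5L)

  # perfectly separated groups: no flags
  tracks2 <- c(lapply(1:4, function(i) mk_sample(40)),
               lapply(1:4, function(i) mk_sample(10)))
  names(tracks2) <- paste0("t", 1:8)
  qc2 <- detect_outliers(regions, tracks2, rep(c("high", "low"), each = 4),
                         top_n = c(10L, 20L))
  expect_false(any(qc2$flagged))
})
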