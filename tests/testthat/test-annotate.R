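make_tads <- function(breaks, chrom = "chr1") {
  data.frame(chrom = chrom, start = breaks[-length(breaks)],
             end = breaks[-1],
             tad_id = paste0("t", seq_len(length(breaks) - 1L)))
}

test_that("target gene is the nearest TSS within the same TAD", {
  tads <- make_tads(c(0L, 10000L, 20000L))
  genes <- data.frame(gene_id = c("A", "B", "C"),
                      chrom = "chr1", tss = c(2000L, 9000L, 10100L),
                      tad_id = c("t1", "t1", "t2"))
  dhs <- genomic_intervals("chr1", 4900, 5100)   # midpoint 5000
  expect_equal(assign_target_gene(dhs, genes, tads), "A")
  # a nearer TSS in a different TAD is ignored
  dhs2 <- genomic_intervals("chr1", 9800, 10000)  # mid 9900 in t1; C is 200 away
  expect_equal(assign_target_gene(dhs2, genes, tads), "B")
  # empty TAD gives NA
  dhs3 <- genomic_intervals("chr1", 4900, 5100)
  expect_true(is.na(assign_target_gene(dhs3, genes[0, ], tads)))
  # tie breaks to the smaller TSS coordinate
  genes_tie <- data.frame(gene_id = c("L", "R"), chrom = "chr1",
                          tss = c(4000L, 6000L), tad_id = "t1")
  expect_equal(assign_target_gene(dhs, genes_tie, tads), "L")
})

test_that("target-gene assignment matches a brute-force search", {
  set.seed(77)
  tads <- make_tads(sort(c(0L, sample.int(99999L, 15), 100000L)))
  genes <- do.call(rbind, lapply(seq_len(nrow(tads)), function(i) {
    k <- sample(0:4, 1)
    if (k == 0) return(NULL)
    data.frame(gene_id = sprintf("g%d_%d", i, seq_len(k)), chrom = "chr1",
               tss = sort(sample(tads$start[i]:(tads$end[i] - 1L), k)),
               tad_id = tads$tad_id[i])
  }))
  dhs <- random_intervals(300, chroms = "chr1", max_pos = 99000, max_len = 400)
  got <- assign_target_gene(dhs, genes, tads)
  mid <- floor((dhs$start + dhs$end) / 2)
  want <- vapply(seq_len(nrow(dhs)), function(i) {
    ti <- tads$tad_id[tads$start <= mid[i] & mid[i] < tads$end]
    g <- genes[genes$tad_id %in% ti, ]
    if (nrow(g) == 0) return(NA_character_)
    d <- abs(g$tss - mid[i])
    g$gene_id[order(d, g$tss)[1]]
  }, character(1))
  expect_equal(got, want)
})

test_that("chromatin state assignment uses max overlap with the tie rule", {
  segs <- data.frame(chrom = "chr1", start = c(0L, 250L, 500L),
                     end = c(250L, 500L, 1000L),
                     state = c("E6", "E5", "E3"))
  expect_equal(assign_chrom_state(genomic_intervals("chr1", 100, 300), segs),
               "E6")
  # exact tie: the state of the segment with smaller coordinates wins
  segs2 <- data.frame(chrom = "chr1", start = c(0L, 200L),
                      end = c(200L, 400L), state = c("E3", "E9"))
  expect_equal(assign_chrom_state(genomic_intervals("chr1", 100, 300), segs2),
               "E3")
  expect_error(
    assign_chrom_state(genomic_intervals("chr1", 100, 300),
                       data.frame(chrom = "chr1", start = 0L, end = 150L,
                                  state = "E1")),
    "uncovered")
})

test_that("state assignment equals the per-base oracle on random tilings", {
  set.seed(12)
  for (rep in 1:3) {
    breaks <- sort(unique(c(0L, sample.int(9999L, 60), 10000L)))
    segs <- data.frame(chrom = "chr1", start = breaks[-length(breaks)],
                       end = breaks[-1],
                       state = sample(paste0("E", 1:5),
                                      length(breaks) - 1L, replace = TRUE))
    base_state <- rep(segs$state, segs$end - segs$start)
    dhs <- random_intervals(100, chroms = "chr1", max_pos = 9500,
                            max_len = 300)
    got <- assign_chrom_state(dhs, segs)
    want <- vapply(seq_len(nrow(dhs)), function(i) {
      span <- base_state[(dhs$start[i] + 1):dhs$end[i]]
      bp <- table(span)
      top <- names(bp)[bp == max(bp)]
      if (length(top) == 1L) return(top)
      # tie: the state appearing first within the DHS span
      top[which.min(match(top, span))]
    }, character(1))
    expect_equal(got, want)
  }
})

test_that("bound labels need at least one shared base pair", {
  dhs <- genomic_intervals("chr1", c(100, 300), c(200, 400))
  peaks <- genomic_intervals("chr1", c(199, 400), c(250, 500))
  expect_equal(label_bound(dhs, peaks), c(TRUE, FALSE))
  set.seed(9)
  q <- random_intervals(1000)
  s <- random_intervals(100)
  expect_equal(label_bound(q, s), oracle_overlaps_any(q, s))
})

consensus_pwm <- function(seq) {
  m <- matrix(0, 4, nchar(seq), dimnames = list(c("A", "C", "G", "T")))
  for (i in seq_len(nchar(seq))) m[substr(seq, i, i), i] <- 1
  pwm(m, motif_id = seq)
}

test_that("motif scanning finds planted consensus sites on both strands", {
  p <- consensus_pwm("ACGT")
  # exact-match p under uniform background is 4^-4 = 0.0039; ACGT is
  # palindromic, so the site also scores on the minus strand
  hits <- scan_motif("AAACGTAA", p, p_threshold = 0.005)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$position, 2L)
  p_np <- consensus_pwm("ACGG")   # non-palindromic: single forward hit
  hits_np <- scan_motif("AAACGGAA", p_np, p_threshold = 0.005)
  expect_equal(nrow(hits_np), 1L)
  expect_equal(hits_np$strand, "+")
  expect_equal(hits_np$position, 2L)
  # reverse-complement planted site found on the minus strand
  p2 <- consensus_pwm("ACGGT")   # revcomp ACCGT
  hits2 <- scan_motif("TTACCGTTT", p2, p_threshold = 0.002)
  expect_equal(nrow(hits2), 1L)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$position, 2L)
  # hit count invariant under reverse-complementing the sequence
  rc <- function(s) paste(rev(c(A = "T", C = "G", G = "C", T = "A")[
    strsplit(s, "")[[1]]]), collapse = "")
  for (s in c("AAACGTAA", "ACGTACGTAA", "GGGGACGTC")) {
    expect_equal(nrow(scan_motif(s, p, 0.005)),
                 nrow(scan_motif(rc(s), p, 0.005)))
  }
  # N positions are skip-scored; short sequences yield no hits
  expect_equal(nrow(scan_motif("AANCGTAA", p, 0.005)), 0L)
  expect_equal(nrow(scan_motif("ACG", p, 0.005)), 0L)
})

test_that("empirical hit rate on random sequence tracks the threshold", {
  set.seed(33)
  m <- matrix(c(0.7, 0.1, 0.1, 0.1,
                0.1, 0.7, 0.1, 0.1,
                0.1, 0.1, 0.7, 0.1,
                0.1, 0.1, 0.1, 0.7,
                0.7, 0.1, 0.1, 0.1,
                0.1, 0.7, 0.1, 0.1,
                0.25, 0.25, 0.25, 0.25,
                0.1, 0.1, 0.7, 0.1), nrow = 4)
  rownames(m) <- c("A", "C", "G", "T")
  p <- pwm(m)
  thr <- 0.01
  n_seq <- 400
  len <- 60
  hits <- 0
  for (i in seq_len(n_seq)) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    hits <- hits + nrow(scan_motif(s, p, thr))
  }
  n_off <- 2 * (len - 8 + 1) * n_seq
  rate <- hits / n_off
  # the exact-null threshold guarantees a per-offset hit probability of at
  # most thr; the attainable tail can sit well below it on the discrete
  # score lattice, so only the upper bound is sharp
  expect_lte(rate, thr * 1.3)
  expect_gt(hits, 0)
  # and a looser threshold can only add hits
  set.seed(33)
  hits_loose <- 0
  for (i in seq_len(50)) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    expect_gte(nrow(scan_motif(s, p, 0.05)), nrow(scan_motif(s, p, thr)))
  }
})

test_that("MEME and TRANSFAC motif files parse to equivalent PWMs", {
  meme <- withr::local_tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "Background letter frequencies", "A 0.25 C 0.25 G 0.25 T 0.25", "",
    "MOTIF STAT5_TEST", "",
    "letter-probability matrix: alength= 4 w= 4 nsites= 20 E= 0",
    " 0.90 0.03 0.03 0.04",
    " 0.05 0.85 0.05 0.05",
    " 0.05 0.05 0.85 0.05",
    " 0.04 0.03 0.03 0.90"), meme)
  pm <- read_meme(meme)
  expect_s3_class(pm, "pwm")
  expect_equal(pm$motif_id, "STAT5_TEST")
  expect_equal(ncol(pm$matrix), 4L)
  expect_equal(unname(pm$matrix["A", 1]), 0.9)

  tf <- withr::local_tempfile(fileext = ".transfac")
  writeLines(c("ID M_TEST", "P0 A C G T",
               "01 18 0 1 1 A",
               "02 1 17 1 1 C",
               "03 1 1 17 1 G",
               "04 1 0 1 18 T",
               "//"), tf)
  pt <- read_transfac(tf)
  expect_equal(pt$motif_id, "M_TEST")
  expect_equal(colSums(pt$matrix), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unname(which.max(pt$matrix[, 2])), 2L)  # C column dominates
})
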