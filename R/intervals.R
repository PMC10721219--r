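#' Construct a genomic interval table
#'
#' Intervals are plain data frames in BED convention: 0-based half-open
#' coordinates (`start` inclusive, `end` exclusive). This is the coordinate
#' currency used by every function in the package.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start positions.
#' @param end Integer vector, exclusive end positions (`end > start`).
#' @param name Optional labels (recycled; default `"."`).
#' @param score Optional numeric scores (default 0).
#' @param strand Strand, one of `"+"`, `"-"`, `"."` (default `"."`).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @examples
#' genomic_intervals("chr1", 100, 200)
#' @export
genomic_intervals <- function(chrom, start, end, name = ".", score = 0,
                              strand = ".") {
  x <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    score = as.numeric(score),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
  x
}

#' Validate an interval table
#'
#' Checks the invariants `start >= 0`, `start < end` and non-empty
#' chromosome names. Called internally by all interval consumers.
#'
#' @param x Interval data frame (needs `chrom`, `start`, `end`).
#' @return `x`, invisibly; errors on violation.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    stop("interval with empty chromosome name")
  if (any(is.na(x$start)) || any(is.na(x$end)))
    stop("interval with missing coordinates")
  if (any(x$start < 0))
    stop("interval with negative start")
  bad <- which(x$start >= x$end)
  if (length(bad))
    stop("interval with start >= end at row ", bad[1L])
  invisible(x)
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Read a BED file
#'
#' Reads 3- to 6-column tab-separated BED. Coordinates are kept 0-based
#' half-open. Malformed lines (non-integer coordinates, `start >= end`,
#' too few columns) raise an error naming the offending line.
#'
#' @param path Path to a BED file.
#' @return Interval data frame (see [genomic_intervals()]).
#' @seealso [write_bed()]
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#") &
                   !startsWith(lines, "browser")]
  if (length(lines) == 0L) return(empty_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3L))
    stop("BED line ", which(n < 3L)[1L], ": fewer than 3 columns")
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  }
  start <- suppressWarnings(as.integer(get(2L, NA)))
  end <- suppressWarnings(as.integer(get(3L, NA)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("BED line ", bad[1L], ": non-integer coordinates")
  bad <- which(start >= end | start < 0L)
  if (length(bad))
    stop("BED line ", bad[1L], ": invalid interval (start >= end or start < 0)")
  score <- suppressWarnings(as.numeric(get(5L, "0")))
  score[is.na(score)] <- 0
  data.frame(chrom = get(1L, ""), start = start, end = end,
             name = get(4L, "."), score = score, strand = get(6L, "."),
             stringsAsFactors = FALSE)
}

#' Write intervals as BED6
#'
#' @param x Interval data frame.
#' @param path Output path.
#' @return `path`, invisibly. `read_bed(write_bed(x, f))` round-trips.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  x <- as.data.frame(x)
  if (is.null(x$name)) x$name <- "."
  if (is.null(x$score)) x$score <- 0
  if (is.null(x$strand)) x$strand <- "."
  out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, x$start, x$end,
                 x$name, format(x$score, trim = TRUE, scientific = FALSE),
                 x$strand)
  writeLines(out, path)
  invisible(path)
}

#' Read a chromosome-sizes file
#'
#' Two tab-separated columns: chromosome name, length in bp.
#'
#' @param path Path to chrom-sizes file.
#' @return Named integer vector of chromosome lengths (a "genome").
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "integer"))
  if (anyDuplicated(tab$chrom)) stop("duplicate chromosome names")
  if (any(tab$length <= 0)) stop("non-positive chromosome length")
  stats::setNames(tab$length, tab$chrom)
}

# Convert one chromosome's 0-based half-open intervals to IRanges
# (1-based closed) for overlap machinery.
.iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

#' Merge overlapping and book-ended intervals
#'
#' Returns the sorted union: overlapping or book-ended (end == next start)
#' intervals are combined, matching standard `merge` semantics of BED
#' toolkits. Idempotent; preserves covered bases exactly.
#'
#' @param x Interval data frame.
#' @return Merged interval data frame (name/score/strand reset).
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0L) return(empty_intervals())
  out <- lapply(split(x, x$chrom), function(part) {
    r <- IRanges::reduce(.iranges(part))   # merges adjacent (gap 0) too
    data.frame(chrom = part$chrom[1L],
               start = IRanges::start(r) - 1L,
               end = IRanges::end(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[order(names(out))])
  rownames(out) <- NULL
  out$name <- "."
  out$score <- 0
  out$strand <- "."
  out
}

#' Base pairs of overlap between two intervals
#'
#' Vectorized; intervals on different chromosomes overlap by 0.
#'
#' @param a,b Interval data frames (recycled row-wise like vectors).
#' @return Integer vector of overlapping base pairs.
#' @export
overlap_bp <- function(a, b) {
  ov <- pmin(a$end, b$end) - pmax(a$start, b$start)
  as.integer(ifelse(a$chrom == b$chrom, pmax(0L, ov), 0L))
}

#' Which query intervals overlap any subject interval?
#'
#' Overlap means >= 1 shared base pair (book-ended intervals do not
#' overlap).
#'
#' @param query,subject Interval data frames.
#' @return Logical vector along `query` rows.
#' @export
overlaps_any <- function(query, subject) {
  validate_intervals(query)
  validate_intervals(subject)
  hit <- logical(nrow(query))
  if (nrow(query) == 0L || nrow(subject) == 0L) return(hit)
  for (chr in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == chr)
    si <- subject[subject$chrom == chr, , drop = FALSE]
    hit[qi] <- IRanges::overlapsAny(.iranges(query[qi, , drop = FALSE]),
                                    .iranges(si))
  }
  hit
}

#' Count overlapping subject intervals per query interval
#'
#' @inheritParams overlaps_any
#' @return Integer vector along `query` rows.
#' @export
count_overlaps <- function(query, subject) {
  validate_intervals(query)
  validate_intervals(subject)
  n <- integer(nrow(query))
  if (nrow(query) == 0L || nrow(subject) == 0L) return(n)
  for (chr in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == chr)
    si <- subject[subject$chrom == chr, , drop = FALSE]
    n[qi] <- IRanges::countOverlaps(.iranges(query[qi, , drop = FALSE]),
                                    .iranges(si))
  }
  n
}
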