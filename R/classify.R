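#' Label reference DHS by pulse response
#'
#' A reference DHS overlapping (>= 1 bp) a region that opens in group A
#' (STAT5-high) is `dynamic_opened`; one overlapping only a region that
#' opens in group B (STAT5-low) is `dynamic_closed`; all others are
#' `static`. A DHS overlapping both directions resolves to
#' `dynamic_opened` with a warning.
#'
#' @param dhs Reference DHS interval data frame.
#' @param up_in_high Differential regions more open in STAT5-high livers.
#' @param up_in_low Differential regions more open in STAT5-low livers.
#' @return Character vector of response labels along `dhs` rows.
#' @export
label_response <- function(dhs, up_in_high, up_in_low = NULL) {
  validate_intervals(dhs)
  hi <- if (!is.null(up_in_high) && nrow(up_in_high))
    overlaps_any(dhs, up_in_high) else logical(nrow(dhs))
  lo <- if (!is.null(up_in_low) && nrow(up_in_low))
    overlaps_any(dhs, up_in_low) else logical(nrow(dhs))
  both <- hi & lo
  if (any(both))
    warning(sum(both), " DHS overlap differential regions of both ",
            "directions; resolved as dynamic_opened")
  ifelse(hi, "dynamic_opened", ifelse(lo, "dynamic_closed", "static"))
}

#' Cross-classify DHS by pulse response and sex bias
#'
#' Partitions the catalog into the six classes dynamic/static x
#' male/female/independent. Following the discovery convention, only
#' `dynamic_opened` DHS are "dynamic"; DHS that close on STAT5 activation
#' (`dynamic_closed`) are grouped with static sites.
#'
#' @param sex_bias Character vector in `male` / `female` / `independent`.
#' @param response Character vector in `dynamic_opened` /
#'   `dynamic_closed` / `static`.
#' @param names Optional DHS identifiers used in error messages.
#' @return List with `labels` (one of the six class names per DHS) and
#'   `counts` (named table over all six classes; sums to the input size).
#' @export
cross_classify <- function(sex_bias, response, names = NULL) {
  stopifnot(length(sex_bias) == length(response))
  ok_sex <- sex_bias %in% c("male", "female", "independent")
  ok_resp <- response %in% c("dynamic_opened", "dynamic_closed", "static")
  if (any(!ok_sex | !ok_resp)) {
    bad <- which(!ok_sex | !ok_resp)[1L]
    id <- if (!is.null(names)) names[bad] else paste("row", bad)
    stop("missing or invalid label for DHS ", id)
  }
  dyn <- ifelse(response == "dynamic_opened", "dynamic", "static")
  sex <- c(male = "male", female = "female", independent = "indep")[sex_bias]
  labels <- paste(dyn, sex, sep = "_")
  all_classes <- as.vector(outer(c("dynamic", "static"),
                                 c("male", "female", "indep"), paste,
                                 sep = "_"))
  counts <- table(factor(labels, levels = all_classes))
  list(labels = labels, counts = counts)
}

#' Percentage of a count with presentation rounding
#'
#' @param k,n Counts (`n > 0`).
#' @param digits Presentation rounding (default 0, i.e. nearest integer).
#' @return List with `value` (unrounded, `100 * k / n`) and `printed`
#'   (rounded for presentation).
#' @export
class_percentage <- function(k, n, digits = 0) {
  if (any(n == 0)) stop("percentage undefined for n = 0")
  value <- 100 * k / n
  list(value = value, printed = round(value, digits))
}

#' Ratio of two proportions with presentation rounding
#'
#' `(k1/n1) / (k2/n2)`, e.g. the fold-difference between the dynamic
#' fraction of STAT5-bound male-biased DHS and that of STAT5-bound
#' sex-independent DHS.
#'
#' @param k1,n1 Foreground count and total.
#' @param k2,n2 Comparison count and total.
#' @param digits Presentation rounding (default 1 decimal).
#' @return List with `value` (unrounded) and `printed`.
#' @export
proportion_ratio <- function(k1, n1, k2, n2, digits = 1) {
  if (n1 == 0 || n2 == 0 || k2 == 0) stop("ratio undefined (zero denominator)")
  value <- (k1 / n1) / (k2 / n2)
  list(value = value, printed = round(value, digits))
}

#' Summarize class counts as percentages
#'
#' @param counts Named non-negative counts (a table or vector).
#' @return Data frame with `class`, `count`, `percent` (unrounded share of
#'   the total) and `printed` (integer-rounded percent).
#' @export
summarize_classes <- function(counts) {
  nm <- names(counts)
  cnt <- as.numeric(counts)
  if (any(cnt < 0)) stop("negative count")
  n <- sum(cnt)
  if (n == 0) stop("empty classification (n = 0)")
  pct <- class_percentage(cnt, n)
  data.frame(class = if (!is.null(nm)) nm else as.character(seq_along(cnt)),
             count = cnt, percent = pct$value, printed = pct$printed,
             stringsAsFactors = FALSE)
}

#' Label reference DHS by hypophysectomy / GH-replacement response
#'
#' For each comparison (e.g. hypox vs intact per sex, or hypox+GH at 30,
#' 90, 240 min vs hypox), a reference DHS is labeled `open` if it overlaps
#' a region that opened, `close` if it overlaps a region that closed,
#' `static` if it overlaps that comparison's peak union but no
#' differential region, and `none` if it does not overlap the comparison's
#' peak-union sites at all. Labels are independent across comparisons. A
#' DHS overlapping both directions resolves to `open` with a warning.
#'
#' @param dhs Reference DHS interval data frame.
#' @param comparisons Named list; each element a list with interval data
#'   frames `open`, `close` and `union` (the comparison's peak-union
#'   sites).
#' @return Data frame, one column per comparison, rows along `dhs`.
#' @export
label_hypox_responses <- function(dhs, comparisons) {
  validate_intervals(dhs)
  if (is.null(names(comparisons)) || any(!nzchar(names(comparisons))))
    stop("comparisons must be named")
  out <- data.frame(row.names = seq_len(nrow(dhs)))
  for (cmp in names(comparisons)) {
    parts <- comparisons[[cmp]]
    if (!all(c("open", "close", "union") %in% names(parts)))
      stop("unknown comparison structure for '", cmp,
           "': need open, close, union")
    op <- if (nrow(parts$open)) overlaps_any(dhs, parts$open)
          else logical(nrow(dhs))
    cl <- if (nrow(parts$close)) overlaps_any(dhs, parts$close)
          else logical(nrow(dhs))
    un <- if (nrow(parts$union)) overlaps_any(dhs, parts$union)
          else logical(nrow(dhs))
    if (any(op & cl))
      warning(sum(op & cl), " DHS overlap both open and close regions in ",
              cmp, "; resolved as open")
    out[[cmp]] <- ifelse(op, "open",
                         ifelse(cl, "close",
                                ifelse(un, "static", "none")))
  }
  out
}

#' Build the master DHS annotation table
#'
#' Collects interval coordinates, sex bias, pulse response, STAT5 binding,
#' motif count, per-sex chromatin states and target gene into one table,
#' the in-memory analog of a supplementary annotation sheet.
#'
#' @param dhs Reference DHS intervals (with `name`).
#' @param sex_bias,response Character vectors along `dhs`.
#' @param stat5_bound Logical vector along `dhs` (optional).
#' @param motif_count Integer vector along `dhs` (optional).
#' @param state_m,state_f Chromatin state per sex (optional).
#' @param target_gene Gene id or `NA` per DHS (optional).
#' @param hypox Data frame of per-comparison hypox labels (optional).
#' @return Data frame, one row per DHS.
#' @export
dhs_annotation_table <- function(dhs, sex_bias, response,
                                 stat5_bound = NULL, motif_count = NULL,
                                 state_m = NULL, state_f = NULL,
                                 target_gene = NULL, hypox = NULL) {
  out <- data.frame(name = dhs$name, chrom = dhs$chrom, start = dhs$start,
                    end = dhs$end, sex_bias = sex_bias, response = response,
                    stringsAsFactors = FALSE)
  if (!is.null(stat5_bound)) out$stat5_bound <- stat5_bound
  if (!is.null(motif_count)) out$motif_count <- motif_count
  if (!is.null(state_m)) out$state_m <- state_m
  if (!is.null(state_f)) out$state_f <- state_f
  if (!is.null(target_gene)) out$target_gene <- target_gene
  if (!is.null(hypox)) out <- cbind(out, hypox)
  out
}
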