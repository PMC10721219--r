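#' Build a 2x2 contingency table for enrichment scoring
#'
#' `a_in`/`a_out` count foreground DHS with/without the feature;
#' `b_in`/`b_out` count the background set.
#'
#' @param a_in,a_out,b_in,b_out Non-negative counts; each set must be
#'   non-empty.
#' @return Object of class `contingency_table`.
#' @export
contingency_table <- function(a_in, a_out, b_in, b_out) {
  v <- c(a_in = a_in, a_out = a_out, b_in = b_in, b_out = b_out)
  if (any(v < 0)) stop("negative count in contingency table")
  if (a_in + a_out == 0 || b_in + b_out == 0)
    stop("empty foreground or background set")
  structure(as.list(v), class = "contingency_table")
}

#' Ratio-of-ratios enrichment score
#'
#' Two variants of the enrichment score:
#' \describe{
#'   \item{`odds`}{`(a_in/a_out) / (b_in/b_out)` -- the in/not-in ratio
#'     of the foreground over that of the background (equals the sample
#'     odds ratio of the 2x2 table).}
#'   \item{`pct`}{`(a_in/(a_in+a_out)) / (b_in/(b_in+b_out))` -- the
#'     percentage of foreground DHS with the feature over the background
#'     percentage, used for feature-overlap batches.}
#' }
#' No pseudocount is applied by default; zero denominators are an error
#' rather than silently corrected. `haldane = TRUE` adds 0.5 to every
#' cell first.
#'
#' @param t A [contingency_table()].
#' @param variant `"odds"` (default) or `"pct"`.
#' @param haldane Apply the Haldane 0.5 correction (default `FALSE`).
#' @return Numeric enrichment score (unrounded).
#' @export
enrichment_score <- function(t, variant = c("odds", "pct"), haldane = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(t, "contingency_table"))
  a_in <- t$a_in; a_out <- t$a_out; b_in <- t$b_in; b_out <- t$b_out
  if (haldane) {
    a_in <- a_in + 0.5; a_out <- a_out + 0.5
    b_in <- b_in + 0.5; b_out <- b_out + 0.5
  }
  if (variant == "odds") {
    if (a_out == 0 || b_out == 0 || b_in == 0)
      stop("zero denominator in enrichment score (odds variant)")
    (a_in / a_out) / (b_in / b_out)
  } else {
    if (b_in == 0) stop("zero background rate in enrichment score")
    (a_in / (a_in + a_out)) / (b_in / (b_in + b_out))
  }
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Sums the hypergeometric probabilities (margins fixed) of every table
#' whose probability does not exceed that of the observed table, the
#' classic two-sided convention. Computed directly from the
#' hypergeometric density, so it is exact for any table.
#'
#' @param t A [contingency_table()].
#' @return P-value in (0, 1].
#' @export
fisher_two_sided <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  r1 <- t$a_in + t$a_out       # foreground margin
  c1 <- t$a_in + t$b_in        # feature margin
  n <- r1 + t$b_in + t$b_out
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  support <- lo:hi
  d <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- d[support == t$a_in]
  min(1, sum(d[d <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across a batch, delegating to
#' [stats::p.adjust()].
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p-values, order-preserving, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Batch enrichment of DHS sets for features against a common background
#'
#' For each (foreground set, feature) pair, counts feature carriers in
#' the foreground and in the background, computes the enrichment score,
#' Fisher two-sided p-value, and BH adjustment across the whole batch.
#' `es < 1` is reported as depletion. Foregrounds must be disjoint from
#' the background.
#'
#' @param foregrounds Named list of DHS id vectors.
#' @param features Named list of DHS id vectors (ids carrying each
#'   feature), or a logical matrix with DHS ids as rownames and features
#'   as columns.
#' @param background Vector of background DHS ids.
#' @param variant Enrichment-score variant per [enrichment_score()].
#' @param alpha Significance threshold on the adjusted p-value (default
#'   1e-3).
#' @return Data frame with one row per (foreground, feature):
#'   counts, `es`, `pvalue`, `padj`, `direction`, `significant`.
#' @export
enrich_batch <- function(foregrounds, features, background,
                         variant = c("odds", "pct"), alpha = 1e-3) {
  variant <- match.arg(variant)
  stopifnot(is.list(foregrounds), !is.null(names(foregrounds)))
  if (is.matrix(features)) {
    features <- apply(features, 2, function(col)
      rownames(features)[col], simplify = FALSE)
  }
  stopifnot(is.list(features), !is.null(names(features)))
  for (nm in names(foregrounds)) {
    if (length(intersect(foregrounds[[nm]], background)))
      stop("foreground '", nm, "' overlaps the background set")
  }
  rows <- list()
  for (fg in names(foregrounds)) {
    for (ft in names(features)) {
      a_in <- length(intersect(foregrounds[[fg]], features[[ft]]))
      a_out <- length(foregrounds[[fg]]) - a_in
      b_in <- length(intersect(background, features[[ft]]))
      b_out <- length(background) - b_in
      tab <- contingency_table(a_in, a_out, b_in, b_out)
      rows[[length(rows) + 1L]] <- data.frame(
        foreground = fg, feature = ft, a_in = a_in, a_out = a_out,
        b_in = b_in, b_out = b_out,
        es = enrichment_score(tab, variant),
        pvalue = fisher_two_sided(tab), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$pvalue)
  out$direction <- ifelse(out$es > 1, "enrichment", "depletion")
  out$significant <- out$padj < alpha
  rownames(out) <- NULL
  out
}
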