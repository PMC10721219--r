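#' Call sex bias of genes from an expression table
#'
#' Thresholds are keyed by biotype: RefSeq genes need male/female
#' |fold-change| > 1.5, lncRNA genes > 2, both with adjusted p < 0.05 and
#' FPKM > 0.25 in the higher-expressed sex. Stringently sex-independent
#' genes need FPKM > 1 in both sexes, |fold-change| < 1.2 and adjusted
#' p > 0.1. Everything else is `other`. All inequalities are strict, so
#' boundary values fail.
#'
#' @param expr Data frame with `biotype`, `fpkm_m`, `fpkm_f`, `fc_mf`
#'   (male/female ratio) and `padj_mf`.
#' @return Character vector in `male` / `female` / `independent_stringent`
#'   / `other`.
#' @export
call_sex_bias <- function(expr) {
  need <- c("biotype", "fpkm_m", "fpkm_f", "fc_mf", "padj_mf")
  miss <- setdiff(need, names(expr))
  if (length(miss)) stop("missing expression fields: ",
                         paste(miss, collapse = ", "))
  if (anyNA(expr[need])) stop("missing values in expression fields")
  thr <- ifelse(expr$biotype == "lncRNA", 2, 1.5)
  male <- expr$fc_mf > thr & expr$padj_mf < 0.05 & expr$fpkm_m > 0.25
  female <- expr$fc_mf < 1 / thr & expr$padj_mf < 0.05 & expr$fpkm_f > 0.25
  indep <- expr$fpkm_m > 1 & expr$fpkm_f > 1 &
    expr$fc_mf < 1.2 & expr$fc_mf > 1 / 1.2 & expr$padj_mf > 0.1
  ifelse(male, "male",
         ifelse(female, "female",
                ifelse(indep, "independent_stringent", "other")))
}

#' Assign hypophysectomy response classes to sex-biased genes
#'
#' Class I genes are downregulated by hypophysectomy in their dominant
#' sex (fold-change < 0.5, adjusted p < 0.05 in that sex); class II genes
#' are upregulated by hypophysectomy in the opposite sex (fold-change
#' > 2, adjusted p < 0.05). A gene meeting both definitions resolves to
#' class I with a warning. Genes that are not sex-biased get `none`.
#'
#' @param expr Data frame with `fc_hypox_m`, `padj_hypox_m`,
#'   `fc_hypox_f`, `padj_hypox_f` (hypox vs intact, per sex).
#' @param sex_bias Output of [call_sex_bias()] along rows of `expr`.
#' @return Data frame with `hypox_class` (`I` / `II` / `none`) and
#'   `responding_sex` (`M` / `F` / `NA`).
#' @export
call_hypox_class <- function(expr, sex_bias) {
  stopifnot(length(sex_bias) == nrow(expr))
  dom_fc <- ifelse(sex_bias == "male", expr$fc_hypox_m, expr$fc_hypox_f)
  dom_p <- ifelse(sex_bias == "male", expr$padj_hypox_m, expr$padj_hypox_f)
  opp_fc <- ifelse(sex_bias == "male", expr$fc_hypox_f, expr$fc_hypox_m)
  opp_p <- ifelse(sex_bias == "male", expr$padj_hypox_f, expr$padj_hypox_m)
  biased <- sex_bias %in% c("male", "female")
  is1 <- biased & dom_fc < 0.5 & dom_p < 0.05
  is2 <- biased & opp_fc > 2 & opp_p < 0.05
  if (any(is1 & is2))
    warning(sum(is1 & is2), " gene(s) meet both class I and class II ",
            "criteria; assigned class I")
  cls <- ifelse(is1, "I", ifelse(is2, "II", "none"))
  cls[!biased] <- "none"
  resp <- rep(NA_character_, nrow(expr))
  dom_sex <- ifelse(sex_bias == "male", "M", "F")
  opp_sex <- ifelse(sex_bias == "male", "F", "M")
  resp[cls == "I"] <- dom_sex[cls == "I"]
  resp[cls == "II"] <- opp_sex[cls == "II"]
  data.frame(hypox_class = cls, responding_sex = resp,
             stringsAsFactors = FALSE)
}

#' Tabulate hypophysectomy response classes of sex-biased genes
#'
#' @param sex_bias Output of [call_sex_bias()].
#' @param hypox_class `hypox_class` column from [call_hypox_class()].
#' @return Data frame with one row per (sex, class) in male/female x
#'   I/II: `count` and `percent_of_sex` (share of that sex's sex-biased
#'   genes, unrounded).
#' @export
tabulate_classes <- function(sex_bias, hypox_class) {
  stopifnot(length(sex_bias) == length(hypox_class))
  out <- expand.grid(sex = c("male", "female"), class = c("I", "II"),
                     stringsAsFactors = FALSE)
  n_sex <- vapply(out$sex, function(s) sum(sex_bias == s), numeric(1))
  out$count <- mapply(function(s, cl)
    sum(sex_bias == s & hypox_class == cl), out$sex, out$class)
  out$percent_of_sex <- ifelse(n_sex > 0, 100 * out$count / n_sex, NA_real_)
  out
}
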