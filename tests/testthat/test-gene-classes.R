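row_expr <- function(biotype = "refseq", fpkm_m = 5, fpkm_f = 5, fc_mf = 1,
                     padj_mf = 0.5, fc_hypox_m = 1, padj_hypox_m = 0.5,
                     fc_hypox_f = 1, padj_hypox_f = 0.5) {
  data.frame(biotype = biotype, fpkm_m = fpkm_m, fpkm_f = fpkm_f,
             fc_mf = fc_mf, padj_mf = padj_mf, fc_hypox_m = fc_hypox_m,
             padj_hypox_m = padj_hypox_m, fc_hypox_f = fc_hypox_f,
             padj_hypox_f = padj_hypox_f)
}

test_that("sex-bias calls apply biotype-specific strict thresholds", {
  expect_equal(call_sex_bias(row_expr(fc_mf = 3, padj_mf = 0.001,
                                      fpkm_m = 2)), "male")
  # lncRNA needs fold-change > 2
  expect_equal(call_sex_bias(row_expr(biotype = "lncRNA", fc_mf = 1.8,
                                      padj_mf = 0.001)), "other")
  expect_equal(call_sex_bias(row_expr(biotype = "lncRNA", fc_mf = 2.5,
                                      padj_mf = 0.001)), "male")
  # female symmetric
  expect_equal(call_sex_bias(row_expr(fc_mf = 1 / 3, padj_mf = 0.001,
                                      fpkm_f = 2)), "female")
  # stringently sex-independent
  expect_equal(call_sex_bias(row_expr(fpkm_m = 5, fpkm_f = 5, fc_mf = 1,
                                      padj_mf = 0.5)),
               "independent_stringent")
  # boundary values fail (strict inequalities)
  expect_equal(call_sex_bias(row_expr(fc_mf = 1.5, padj_mf = 0.001,
                                      fpkm_m = 2)), "other")
  expect_equal(call_sex_bias(row_expr(fpkm_m = 1, fpkm_f = 5, fc_mf = 1,
                                      padj_mf = 0.5)), "other")
  expect_error(call_sex_bias(data.frame(fc_mf = 1)), "missing")
})

test_that("hypox classes follow the class I / class II definitions", {
  # male gene down in male liver after hypox: class I, responding sex M
  r <- row_expr(fc_mf = 3, padj_mf = 0.001, fc_hypox_m = 0.3,
                padj_hypox_m = 0.01)
  out <- call_hypox_class(r, "male")
  expect_equal(out$hypox_class, "I")
  expect_equal(out$responding_sex, "M")
  # male gene up in female liver after hypox: class II, responding sex F
  r <- row_expr(fc_mf = 3, padj_mf = 0.001, fc_hypox_f = 2.5,
                padj_hypox_f = 0.01)
  out <- call_hypox_class(r, "male")
  expect_equal(out$hypox_class, "II")
  expect_equal(out$responding_sex, "F")
  # nonsignificant responses: none
  r <- row_expr(fc_mf = 3, padj_mf = 0.001, fc_hypox_m = 0.3,
                padj_hypox_m = 0.2)
  expect_equal(call_hypox_class(r, "male")$hypox_class, "none")
  # dual-qualifying genes resolve to class I with a warning
  r <- row_expr(fc_hypox_m = 0.3, padj_hypox_m = 0.01, fc_hypox_f = 3,
                padj_hypox_f = 0.01)
  expect_warning(out <- call_hypox_class(r, "male"), "both")
  expect_equal(out$hypox_class, "I")
})

test_that("class assignment is monotone in the significance threshold", {
  # tightening padj cannot convert none into I/II: a gene with padj above
  # 0.05 is none regardless of fold-change
  r <- row_expr(fc_hypox_m = 0.1, padj_hypox_m = 0.049)
  expect_equal(call_hypox_class(r, "male")$hypox_class, "I")
  r$padj_hypox_m <- 0.051
  expect_equal(call_hypox_class(r, "male")$hypox_class, "none")
})

test_that("tabulation reports counts and responder percentages per sex", {
  sex <- c(rep("male", 40), rep("female", 10))
  cls <- c(rep("I", 10), rep("none", 30), rep("II", 4), rep("none", 6))
  tab <- tabulate_classes(sex, cls)
  m1 <- tab[tab$sex == "male" & tab$class == "I", ]
  expect_equal(m1$count, 10)
  expect_equal(m1$percent_of_sex, 25)
  expect_equal(sum(tab$count), sum(cls != "none"))
})

test_that("zero-noise synthetic expression recovers truth labels exactly", {
  cfg <- tiny_sim_config(seed = 19)
  ann <- simulate_annotations(cfg)
  expr <- simulate_expression(cfg, ann, noise = 0)
  sb <- call_sex_bias(expr)
  truth <- ann$truth$genes
  expect_equal(sb %in% c("male", "female"),
               truth$sex_bias %in% c("male", "female"))
  expect_equal(sb[truth$sex_bias == "male"],
               rep("male", sum(truth$sex_bias == "male")))
  expect_equal(sb[truth$sex_bias == "female"],
               rep("female", sum(truth$sex_bias == "female")))
  expect_equal(sb[truth$sex_bias == "independent"],
               rep("independent_stringent",
                   sum(truth$sex_bias == "independent")))
  hc <- call_hypox_class(expr, sb)
  biased <- truth$sex_bias %in% c("male", "female")
  expect_equal(hc$hypox_class[biased], truth$hypox_class[biased])
})
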