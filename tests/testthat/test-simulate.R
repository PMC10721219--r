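test_that("simulation is deterministic and conserves counts", {
  cfg <- tiny_sim_config(seed = 3)
  a1 <- simulate_annotations(cfg)
  a2 <- simulate_annotations(cfg)
  expect_identical(a1, a2)
  expect_equal(nrow(a1$dhs), sum(cfg$n_dhs))
  expect_equal(nrow(a1$truth$dhs), sum(cfg$n_dhs))
  expect_equal(as.vector(table(a1$truth$dhs$class)[names(cfg$n_dhs)])[
    cfg$n_dhs > 0], unname(cfg$n_dhs[cfg$n_dhs > 0]))

  t1 <- simulate_cut_tracks(cfg, a1)
  t2 <- simulate_cut_tracks(cfg, a1)
  expect_identical(t1, t2)
  expect_equal(length(t1$tracks), cfg$n_high + cfg$n_low + cfg$n_female)

  e1 <- simulate_expression(cfg, a1)
  expect_identical(e1, simulate_expression(cfg, a1))
  expect_equal(nrow(e1), nrow(a1$genes))
})

test_that("DHS placement is non-overlapping and inside the genome", {
  cfg <- tiny_sim_config(seed = 11)
  ann <- simulate_annotations(cfg)
  m <- merge_intervals(ann$dhs)
  expect_equal(nrow(m), nrow(ann$dhs))      # no two DHS touch
  expect_true(all(ann$dhs$end <= cfg$genome[ann$dhs$chrom]))
  # a genome too small to hold the catalog errors
  expect_error(simulate_annotations(
    sim_config(seed = 1, genome = c(c1 = 5e4))), "too small")
})

test_that("planted motif frequencies match configuration within binomial error", {
  cfg <- sim_config(seed = 23, genome = c(chrT = 8e6),
                    n_dhs = c(dynamic_male = 400, static_male = 400,
                              static_female = 0, dynamic_indep = 0,
                              background = 800),
                    n_tads = 20)
  ann <- simulate_annotations(cfg)
  td <- ann$truth$dhs
  for (cl in c("dynamic_male", "static_male", "background")) {
    n <- sum(td$class == cl)
    phat <- mean(td$motif_count[td$class == cl] > 0)
    p0 <- cfg$motif_freq[[cl]]
    expect_lt(abs(phat - p0), 3 * sqrt(p0 * (1 - p0) / n))
  }
})

test_that("group mean cut counts reproduce the configured fold-changes", {
  # near-Poisson noise and deep libraries: law of large numbers
  cfg <- sim_config(seed = 5, genome = c(chrT = 4e6),
                    n_dhs = c(dynamic_male = 150, static_male = 100,
                              static_female = 80, dynamic_indep = 0,
                              background = 400),
                    depth = 3e5, dispersion = 0.01,
                    n_high = 6, n_low = 6, n_female = 4, n_tads = 10)
  ann <- simulate_annotations(cfg)
  sim <- simulate_cut_tracks(cfg, ann)
  td <- ann$truth$dhs
  dhs_iv <- ann$dhs
  group_mean <- function(grp, cl) {
    ids <- sim$samples$sample_id[sim$samples$group == grp]
    sel <- dhs_iv[td$class == cl, ]
    mean(vapply(ids, function(id)
      sum(cuts_in_intervals(sim$tracks[[id]], sel)), numeric(1)))
  }
  r_dyn <- group_mean("high", "dynamic_male") / group_mean("low", "dynamic_male")
  expect_lt(abs(r_dyn - cfg$fold_dynamic_high_low) / cfg$fold_dynamic_high_low,
            0.10)
  r_sm <- group_mean("low", "static_male") / group_mean("female", "static_male")
  expect_lt(abs(r_sm - cfg$fold_static_mf) / cfg$fold_static_mf, 0.10)
  r_sf <- group_mean("female", "static_female") / group_mean("low", "static_female")
  expect_lt(abs(r_sf - cfg$fold_static_fm) / cfg$fold_static_fm, 0.10)
  # background DHS: groups agree
  r_bg <- group_mean("high", "background") / group_mean("low", "background")
  expect_lt(abs(r_bg - 1), 0.05)
})

test_that("expression table rows honour the truth-label contracts", {
  cfg <- tiny_sim_config(seed = 13)
  ann <- simulate_annotations(cfg)
  expr <- simulate_expression(cfg, ann)
  tg <- ann$truth$genes
  m1 <- tg$sex_bias == "male" & tg$hypox_class == "I"
  if (any(m1)) {
    expect_true(all(expr$fc_mf[m1] > 1.5))
    expect_true(all(expr$padj_mf[m1] < 0.05))
    expect_true(all(expr$fc_hypox_m[m1] < 0.5))
    expect_true(all(expr$padj_hypox_m[m1] < 0.05))
  }
  ind <- tg$sex_bias == "independent"
  expect_true(all(abs(log2(expr$fc_mf[ind])) < log2(1.2)))
  expect_true(all(expr$padj_mf[ind] > 0.1))
  expect_true(all(expr$fpkm_m[ind] > 1 & expr$fpkm_f[ind] > 1))
})
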