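test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- null_cohort_config(seed = 31)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(unclass(a$mirna), unclass(b$mirna))
  expect_identical(unclass(a$gene), unclass(b$gene))
  expect_identical(a$sheet, b$sheet)
  expect_identical(generate_tf_layer(a$truth), generate_tf_layer(b$truth))
  expect_identical(generate_target_predictions(a$truth),
                   generate_target_predictions(b$truth))
})

test_that("default design reproduces the reference sample structure", {
  co <- generate_cohort(cohort_config(seed = 3))
  tis_m <- co$sheet$tissue[match(colnames(co$mirna), co$sheet$sample_id)]
  tis_g <- co$sheet$tissue[match(colnames(co$gene), co$sheet$sample_id)]
  expect_equal(as.vector(table(tis_m)[c("N", "T", "M")]), c(23, 31, 24))
  expect_equal(as.vector(table(tis_g)[c("N", "T", "M")]), c(23, 30, 27))
  expect_length(match_samples(co$mirna, co$gene), 77)
  expect_true(all(unclass(co$mirna) >= 0 & unclass(co$mirna) <= 15))
  expect_true(all(unclass(co$gene) >= 0 & unclass(co$gene) <= 15))
  expect_named(co$truth$clipped, c("mirna", "gene"))
})

test_that("planted repressions produce the analytic anti-correlation", {
  # b = 1, noise sd = 0.1: r should be close to -b*sd_m/sqrt(b^2 sd_m^2+s^2)
  cfg <- cohort_config(seed = 17, n_planted_dems = c(TvN = 0, MvT = 0),
                       n_planted_degs = 0, n_planted_repressions = 20,
                       repression_noise_sd = 0.1, n_decoy_predictions = 0,
                       n_planted_circuits = c(TF_driven = 0, miRNA_driven = 0),
                       n_decoy_tfs = 0, n_decoy_tf_edges = 0)
  co <- generate_cohort(cfg)
  matched <- match_samples(co$mirna, co$gene)
  tr <- co$truth$repressions
  r_obs <- vapply(seq_len(nrow(tr)), function(i) {
    cor(unclass(co$mirna)[tr$mirna_id[i], matched],
        unclass(co$gene)[tr$gene_id[i], matched])
  }, 0)
  expect_true(all(r_obs < -0.9))
  expect_equal(r_obs, tr$analytic_r, tolerance = 0.05)
})

test_that("planted differential effects are recovered by class means", {
  cfg <- cohort_config(seed = 23, n_planted_dems = c(TvN = 10, MvT = 0),
                       dem_effect = 2, n_planted_repressions = 0,
                       n_decoy_predictions = 0,
                       n_planted_circuits = c(TF_driven = 0, miRNA_driven = 0),
                       patient_effect_sd = 0)
  co <- generate_cohort(cfg)
  tis <- co$sheet$tissue[match(colnames(co$mirna), co$sheet$sample_id)]
  tr <- co$truth$dems
  for (i in seq_len(nrow(tr))) {
    v <- unclass(co$mirna)[tr$feature_id[i], ]
    diff <- mean(v[tis == "T"]) - mean(v[tis == "N"])
    se <- sqrt(var(v[tis == "T"]) / sum(tis == "T") +
                 var(v[tis == "N"]) / sum(tis == "N"))
    expect_lt(abs(diff - tr$effect[i]), 3 * se)
  }
})

test_that("prediction generation books planted and decoy pairs correctly", {
  cfg <- cohort_config(seed = 9, n_planted_repressions = 30,
                       n_decoy_predictions = 500,
                       n_planted_circuits = c(TF_driven = 0, miRNA_driven = 0))
  co <- generate_cohort(cfg)
  pred <- generate_target_predictions(co$truth, cfg)
  keys <- paste(pred$mirna_id, pred$gene_id)
  expect_false(any(duplicated(keys)))
  expect_equal(nrow(pred), 30 + 500)
  expect_true(all(paste(co$truth$repressions$mirna_id,
                        co$truth$repressions$gene_id) %in% keys))
  # zero decoys: predictions are exactly the planted pairs
  cfg0 <- cohort_config(seed = 9, n_planted_repressions = 30,
                        n_decoy_predictions = 0,
                        n_planted_circuits = c(TF_driven = 0, miRNA_driven = 0))
  co0 <- generate_cohort(cfg0)
  pred0 <- generate_target_predictions(co0$truth, cfg0)
  expect_setequal(paste(pred0$mirna_id, pred0$gene_id),
                  paste(co0$truth$repressions$mirna_id,
                        co0$truth$repressions$gene_id))
  # decoy pairs are uncorrelated on average
  matched <- match_samples(co$mirna, co$gene)
  dec <- pred[!keys %in% paste(co$truth$repressions$mirna_id,
                               co$truth$repressions$gene_id), ]
  r_dec <- vapply(seq_len(nrow(dec)), function(i) {
    cor(unclass(co$mirna)[dec$mirna_id[i], matched],
        unclass(co$gene)[dec$gene_id[i], matched])
  }, 0)
  expect_lt(abs(mean(r_dec)), 0.1)
  # impossible decoy request errors
  expect_error(generate_target_predictions(
    co$truth, cohort_config(seed = 9, n_planted_repressions = 30,
                            n_decoy_predictions = 10^7)), "decoy")
})

test_that("TF layer realizes planted circuits and decoy edges", {
  cfg <- cohort_config(seed = 13)
  co <- generate_cohort(cfg)
  tf <- generate_tf_layer(co$truth, cfg)
  for (k in seq_len(nrow(co$truth$circuits))) {
    ci <- co$truth$circuits[k, ]
    expect_true(any(tf$regulator_id == ci$tf & tf$target_id == ci$gene))
    if (ci$circuit_type == "TF_driven") {
      expect_true(any(tf$regulator_id == ci$tf & tf$target_id == ci$mirna &
                        tf$target_kind == "miRNA"))
    }
  }
  expect_false(any(duplicated(paste(tf$regulator_id, tf$target_id))))
  expect_true(all(co$truth$tf_ids %in% rownames(co$gene)))
})

test_that("survival generation respects the hazard model and censoring", {
  cfg <- cohort_config(seed = 5, n_survival = 300)
  truth0 <- list(survival_beta = c(m1 = 0))
  rec0 <- generate_survival(truth0, cfg)
  # null effect: event times independent of the covariate
  expect_gt(cor.test(rec0$time[rec0$event == 1], rec0$m1[rec0$event == 1],
                     method = "spearman", exact = FALSE)$p.value, 0.01)
  expect_equal(mean(1 - rec0$event), cfg$censoring_rate, tolerance = 0.1)
  # full censoring boundary
  cfg1 <- cohort_config(seed = 5, n_survival = 50, censoring_rate = 1)
  rec1 <- generate_survival(truth0, cfg1)
  expect_true(all(rec1$event == 0))
  expect_error(cox_fit_univariate(rec1, "m1"), "events")
  # no censoring boundary
  cfg2 <- cohort_config(seed = 5, n_survival = 50, censoring_rate = 0)
  expect_true(all(generate_survival(truth0, cfg2)$event == 1))
})
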