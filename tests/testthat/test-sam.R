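test_that("the SAM statistic matches the pooled-SE formula by hand", {
  # a=(1,2,3), b=(4,5,6): s = sqrt((1/3+1/3)*(2+2)/4) = 0.81650, d = -3/s
  expect_equal(sam_statistic(c(1, 2, 3), c(4, 5, 6), s0 = 0),
               -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(round(sam_statistic(c(1, 2, 3), c(4, 5, 6), 0), 3), -3.674)
  expect_equal(sam_statistic(c(2, 4), c(1, 5), 0.5), 0)  # equal means
  # antisymmetry under group swap
  set.seed(2)
  a <- rnorm(5); b <- rnorm(7)
  expect_equal(sam_statistic(a, b, 0.2), -sam_statistic(b, a, 0.2))
  # d -> 0 monotonically as s0 grows
  ds <- sapply(c(0, 1, 10, 100), function(s0) abs(sam_statistic(a, b, s0)))
  expect_true(all(diff(ds) < 0))
  # zero variance with s0 = 0 is undefined
  expect_error(sam_statistic(c(1, 1), c(1, 1), 0), "undefined")
})

test_that("s0 estimation matches an exhaustive percentile grid search", {
  set.seed(7)
  X <- matrix(rnorm(50 * 12, 6, sd = rep(runif(50, 0.2, 2), 12)), nrow = 50)
  rownames(X) <- sprintf("f%02d", 1:50); colnames(X) <- sprintf("s%02d", 1:12)
  labels <- rep(c(TRUE, FALSE), each = 6)
  s0 <- estimate_s0(expression_matrix(X, "gene"), labels)
  # independent re-computation: same CV criterion, straightforward loops
  na <- 6; nb <- 6
  r <- rowMeans(X[, 1:6]) - rowMeans(X[, 7:12])
  s <- apply(X, 1, function(v) {
    sqrt((1 / na + 1 / nb) *
           (sum((v[1:6] - mean(v[1:6]))^2) + sum((v[7:12] - mean(v[7:12]))^2)) /
           (na + nb - 2))
  })
  alphas <- seq(0, 1, by = 0.05)
  win <- cut(rank(s, ties.method = "first"), breaks = 50, labels = FALSE)
  cvs <- sapply(alphas, function(a) {
    d <- r / (s + quantile(s, a, names = FALSE))
    v <- tapply(d, win, mad)
    v <- v[is.finite(v)]
    if (mean(v) == 0) 0 else sd(v) / mean(v)
  })
  expect_equal(s0, quantile(s, alphas[which.min(cvs)], names = FALSE))
  expect_gte(s0, 0)
  # identical s for every feature: s0 equals that shared s, any percentile
  Xc <- t(sapply(1:20, function(i) c(0, 1, 2, 0, 1, 2) + i))
  rownames(Xc) <- sprintf("f%02d", 1:20); colnames(Xc) <- sprintf("s%d", 1:6)
  s0c <- estimate_s0(expression_matrix(Xc, "gene"),
                     rep(c(TRUE, FALSE), each = 3))
  s_shared <- sqrt((1 / 3 + 1 / 3) * (2 + 2) / 4)
  expect_equal(unname(s0c), s_shared)
})

test_that("SAM permutation FDR is calibrated under the null and detects planted shifts", {
  # null cohort: no calls expected at FDR 0.01
  cfg <- null_cohort_config(seed = 61, n_mirnas = 500, n_genes = 10)
  co <- generate_cohort(cfg)
  res <- sam_fdr(co$mirna, co$sheet, c("T", "N"),
                 sam_config(n_permutations = 100, fdr_target = 0.01, seed = 61))
  expect_lte(mean(res$results$called), 0.03)
  expect_true(all(res$results$q >= 0 & res$results$q <= 1))
  # FDR monotone non-increasing in delta
  expect_true(all(diff(res$delta_table$fdr) <= 1e-12))
  # planted shifts: strong recovery
  cfgp <- cohort_config(seed = 62, n_mirnas = 500, n_genes = 10,
                        n_planted_dems = c(TvN = 25, MvT = 0), dem_effect = 2,
                        n_planted_degs = 0, n_planted_repressions = 0,
                        n_decoy_predictions = 0,
                        n_planted_circuits = c(TF_driven = 0, miRNA_driven = 0),
                        n_decoy_tfs = 0, n_decoy_tf_edges = 0)
  cop <- generate_cohort(cfgp)
  resp <- sam_fdr(cop$mirna, cop$sheet, c("T", "N"),
                  sam_config(n_permutations = 100, fdr_target = 0.01, seed = 62))
  called <- resp$results$feature_id[resp$results$called]
  expect_gte(mean(cop$truth$dems$feature_id %in% called), 0.9)
  # called features all satisfy q <= target
  expect_true(all(resp$results$q[resp$results$called] <= 0.01))
})

test_that("SAM d values are location invariant and contrast-antisymmetric", {
  cfg <- null_cohort_config(seed = 77, n_mirnas = 100, n_genes = 10)
  co <- generate_cohort(cfg)
  conf <- sam_config(n_permutations = 50, seed = 5)
  r1 <- sam_fdr(co$mirna, co$sheet, c("T", "N"), conf)
  shifted <- expression_matrix(unclass(co$mirna) + 3, "miRNA")
  r2 <- sam_fdr(shifted, co$sheet, c("T", "N"), conf)
  expect_equal(r1$results$d, r2$results$d, tolerance = 1e-10)
  expect_equal(r1$results$called, r2$results$called)
  r3 <- sam_fdr(co$mirna, co$sheet, c("N", "T"), conf)
  expect_equal(r3$results$d, -r1$results$d, tolerance = 1e-10)
})

test_that("paired SAM runs on within-patient differences and stays null-calibrated", {
  set.seed(3)
  n_pat <- 12
  sheet <- sample_sheet(c(sprintf("p%02d_T", 1:n_pat), sprintf("p%02d_N", 1:n_pat),
                          "extra_T"),
                        c(rep(sprintf("p%02d", 1:n_pat), 2), "p99"),
                        c(rep("T", n_pat), rep("N", n_pat), "T"))
  vals <- matrix(rnorm(80 * (2 * n_pat + 1), 6), nrow = 80)
  rownames(vals) <- sprintf("f%02d", 1:80)
  colnames(vals) <- sheet$sample_id
  x <- expression_matrix(vals, "miRNA")
  expect_warning(
    res <- sam_fdr(x, sheet, c("T", "N"),
                   sam_config(design = "paired", n_permutations = 100, seed = 4)),
    "pair")
  expect_lte(mean(res$results$called), 0.03)
  # a planted within-pair shift is found
  vals2 <- vals
  vals2[1:5, 1:n_pat] <- vals2[1:5, 1:n_pat] + 3
  x2 <- expression_matrix(vals2, "miRNA")
  res2 <- suppressWarnings(
    sam_fdr(x2, sheet, c("T", "N"),
            sam_config(design = "paired", n_permutations = 100, seed = 4)))
  expect_true(all(res2$results$called[1:5]))
})

test_that("DEM selection applies the fold-change and background rules", {
  res <- data.frame(
    feature_id = c("keep", "low_fc", "low_expr", "uncalled"),
    d = c(5, 5, 5, 5),
    log2fc = c(3.2, 2.0, 3.5, 4.0),
    mean_a = c(6, 6, 4.5, 6), mean_b = c(2, 2, 1.0, 2),
    q = c(0.005, 0.005, 0.005, 0.5),
    called = c(TRUE, TRUE, TRUE, FALSE))
  out <- select_dems(res, fc_threshold = 3, background = 5)
  expect_identical(out$feature_id, "keep")
  expect_identical(out$direction, "up")
  # linear-scale reading of the threshold
  out_lin <- select_dems(res, fc_threshold = 3, background = 5, log2_scale = FALSE)
  expect_setequal(out_lin$feature_id, c("keep", "low_fc"))
  # empty results give an empty table
  expect_equal(nrow(select_dems(res[0, ])), 0)
})
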