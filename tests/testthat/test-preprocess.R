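test_that("detection filter applies the count rule and the class exemption", {
  # 3 tissue classes, 30 samples; detection passed explicitly
  sheet <- sample_sheet(sprintf("s%02d", 1:30), sprintf("p%02d", 1:30),
                        rep(c("N", "T", "M"), each = 10))
  vals <- matrix(6, nrow = 4, ncol = 30,
                 dimnames = list(c("everywhere", "enough", "spread", "one_class"),
                                 sprintf("s%02d", 1:30)))
  x <- expression_matrix(vals, "miRNA")
  det <- matrix(TRUE, 4, 30, dimnames = dimnames(vals))
  det["enough", 1:5] <- FALSE            # detected in 25 >= 20
  det["spread", c(1:8, 11:18, 21:26)] <- FALSE   # detected in 8 < 20, all classes
  det["one_class", 21:30] <- FALSE       # detected in 20 N/T; undetected only in M
  out <- filter_mirnas_by_detection(x, sheet, detection = det, min_detected = 20)
  expect_setequal(rownames(out), c("everywhere", "enough", "one_class"))
  # class exemption holds even when the detected total is below the cut:
  # one_class is detected in only 20 samples (< 25) but its undetected
  # samples are confined to class M
  out2 <- filter_mirnas_by_detection(x, sheet, detection = det, min_detected = 25)
  expect_true("one_class" %in% rownames(out2))  # 20 < 25 but M-only absence
  # all detected everywhere: identity
  out3 <- filter_mirnas_by_detection(x, sheet,
                                     detection = matrix(TRUE, 4, 30,
                                                        dimnames = dimnames(vals)))
  expect_identical(rownames(out3), rownames(x))
  expect_error(filter_mirnas_by_detection(x, sheet, detection = matrix(TRUE, 2, 2)),
               "dimensions")
})

test_that("variability filter retains floor((1-f)*n) features, stably", {
  set.seed(4)
  x <- tiny_matrix(matrix(rnorm(10 * 6), 10, 6), kind = "gene")
  out <- filter_genes_by_variability(x, 0.30)
  expect_equal(nrow(out), 7)  # floor(0.7 * 10)
  # retained = top-variance features, in input order
  v <- apply(unclass(x), 1, var)
  expect_identical(rownames(out),
                   rownames(x)[sort(head(order(v, decreasing = TRUE), 7))])
  # all-equal variances: first floor(0.7 n) in input order
  xc <- tiny_matrix(matrix(rep(1:6, each = 10), 10, 6), kind = "gene")
  expect_identical(rownames(filter_genes_by_variability(xc, 0.30)),
                   rownames(xc)[1:7])
  # idempotence at the matrix level: a second pass with drop 0 changes nothing
  expect_identical(unclass(filter_genes_by_variability(out, 0)), unclass(out))
  expect_error(filter_genes_by_variability(x, 1), "drop_fraction")
  # property: retained count over a grid of n and f
  for (n in c(5, 11, 22)) for (f in c(0.1, 0.3, 0.5)) {
    xs <- tiny_matrix(matrix(rnorm(n * 4), n, 4), kind = "gene")
    expect_equal(nrow(filter_genes_by_variability(xs, f)), floor((1 - f) * n))
  }
})

test_that("mean-signal filter thresholds on the arithmetic mean", {
  vals <- rbind(just_over = rep(5.1, 4), just_under = rep(4.9, 4),
                mixed = c(2, 4, 6, 9))  # mean 5.25
  x <- tiny_matrix(vals)
  out <- filter_by_mean_signal(x, floor = 5)
  expect_setequal(rownames(out), c("just_over", "mixed"))
  # hand-computed means drive retention on a random fixture
  set.seed(8)
  xr <- tiny_matrix(matrix(runif(5 * 6, 2, 9), 5, 6))
  keep <- rowMeans(unclass(xr)) > 5
  expect_identical(rownames(filter_by_mean_signal(xr, 5)),
                   rownames(xr)[keep])
  # idempotent
  expect_identical(unclass(filter_by_mean_signal(out, 5)), unclass(out))
  # empty in, empty out
  empty <- subset_matrix(x, features = integer(0))
  expect_equal(nrow(filter_by_mean_signal(empty, 5)), 0)
})

test_that("transition pattern counts classify by class-mean log2FC and conserve totals", {
  sheet <- tiny_sheet(c("N", "N", "T", "T", "M", "M"))
  vals <- rbind(up_tvn = c(6, 6, 8, 8, 8, 8),     # TvN fc +2, MvT 0
                down_mvt = c(6, 6, 6, 6, 4, 4),   # TvN 0, MvT -2
                flat = rep(6, 6))
  x <- tiny_matrix(vals)
  tc <- transition_pattern_counts(x, sheet, fc_threshold = 1)
  expect_equal(tc$up[tc$contrast == "TvN"], 1)
  expect_equal(tc$down[tc$contrast == "TvN"], 0)
  expect_equal(tc$down[tc$contrast == "MvT"], 1)
  expect_true(all(tc$up + tc$down + tc$unchanged == nrow(x)))
  # all-zero matrix: everything unchanged
  x0 <- tiny_matrix(matrix(0, 4, 6))
  tc0 <- transition_pattern_counts(x0, sheet)
  expect_true(all(tc0$unchanged == 4))
  # swapping N and T labels swaps up and down in the TvN contrast
  sheet_sw <- tiny_sheet(c("T", "T", "N", "N", "M", "M"))
  tcs <- transition_pattern_counts(x, sheet_sw, fc_threshold = 1)
  expect_equal(tcs$down[tcs$contrast == "TvN"], tc$up[tc$contrast == "TvN"])
})

test_that("sample clustering separates groups and is order invariant", {
  set.seed(21)
  # two well-separated sample groups over 40 features
  base <- rnorm(40, 6)
  g1 <- sapply(1:5, function(i) base + rnorm(40, sd = 0.3))
  g2 <- sapply(1:5, function(i) base + c(rep(3, 20), rep(-3, 20)) + rnorm(40, sd = 0.3))
  x <- tiny_matrix(cbind(g1, g2))
  cl <- cluster_samples(x, k = 2)
  expect_length(unique(cl$clusters[1:5]), 1)
  expect_length(unique(cl$clusters[6:10]), 1)
  expect_false(cl$clusters[1] == cl$clusters[6])
  # permuting samples leaves cophenetic distances unchanged
  perm <- sample(ncol(x))
  clp <- cluster_samples(subset_matrix(x, samples = perm))
  d1 <- as.matrix(cophenetic(cl$hclust))
  d2 <- as.matrix(cophenetic(clp$hclust))
  expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-10)
})

test_that("patient pairing score is 1 for duplicated T/M profiles and near chance when shuffled", {
  set.seed(33)
  n_pat <- 8
  sheet <- sample_sheet(
    c(sprintf("p%02d_T", 1:n_pat), sprintf("p%02d_M", 1:n_pat)),
    rep(sprintf("p%02d", 1:n_pat), 2),
    rep(c("T", "M"), each = n_pat))
  profiles <- matrix(rnorm(30 * n_pat, 6), nrow = 30)
  vals <- cbind(profiles + rnorm(30 * n_pat, sd = 0.01),
                profiles + rnorm(30 * n_pat, sd = 0.01))
  colnames(vals) <- sheet$sample_id
  rownames(vals) <- sprintf("f%02d", 1:30)
  x <- expression_matrix(vals, "miRNA")
  expect_equal(patient_pairing_score(cluster_samples(x), sheet), 1)
  # shuffling sample labels destroys pairing (score well below 1)
  sheet_shuf <- sample_sheet(sample(sheet$sample_id), sheet$patient_id, sheet$tissue)
  scores <- patient_pairing_score(cluster_samples(x), sheet_shuf)
  expect_lt(scores, 0.5)
  # degenerate input: no patient with both tissues
  sheet_nt <- tiny_sheet(rep("T", 4))
  xs <- tiny_matrix(n_feat = 5, n_samp = 4)
  expect_error(patient_pairing_score(cluster_samples(xs), sheet_nt), "both T and M")
})

test_that("biogenesis balance reports class means and t-test p-values", {
  sheet <- tiny_sheet(rep(c("N", "T", "M"), each = 2))
  vals <- matrix(rep(c(5, 5, 7, 7, 5, 5), each = 3), nrow = 3, byrow = FALSE)
  x <- tiny_matrix(vals)
  bb <- biogenesis_balance(rownames(x), x, sheet)
  expect_equal(unname(bb$means["N"]), 5)
  expect_equal(unname(bb$means["T"]), 7)
  expect_equal(nrow(bb$tests), 3)
  # identical class distributions give p = 1
  x2 <- tiny_matrix(matrix(rep(c(5, 6, 5, 6, 5, 6), each = 3), nrow = 3))
  bb2 <- biogenesis_balance(rownames(x2), x2, sheet)
  expect_true(all(bb2$tests$p == 1))
  # a +2 shifted class is detected at n >= 20 per class
  set.seed(12)
  sheet_big <- tiny_sheet(rep(c("N", "T", "M"), each = 20))
  vb <- matrix(rnorm(3 * 60, 6), nrow = 3)
  vb[, 21:40] <- vb[, 21:40] + 2
  xb <- tiny_matrix(vb)
  bb3 <- biogenesis_balance(rownames(xb), xb, sheet_big)
  p_nt <- bb3$tests$p[bb3$tests$class_a == "N" & bb3$tests$class_b == "T"]
  expect_lt(p_nt, 0.01)
})

test_that("expression entropy matches the histogram definition and its bounds", {
  expect_equal(expression_entropy(rep(4.2, 50)), 0)
  # uniform over 8 occupied bins with equal counts: 3 bits
  prof <- rep(seq(0, 7) + 0.5, each = 5)
  expect_equal(expression_entropy(prof, n_bins = 8), 3)
  # random fixture equals a direct histogram computation
  set.seed(14)
  v <- rnorm(200, 6)
  h <- hist(v, breaks = seq(min(v), max(v), length.out = 11), plot = FALSE)
  p <- h$counts[h$counts > 0] / length(v)
  expect_equal(expression_entropy(v, 10), -sum(p * log2(p)))
  # bounded by log2(n_bins); zero iff constant
  expect_lte(expression_entropy(v, 10), log2(10))
  expect_gt(expression_entropy(v, 10), 0)
})
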