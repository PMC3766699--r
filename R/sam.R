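#' SAM run configuration
#'
#' @param design `"unpaired"` (two independent sample classes) or `"paired"`
#'   (one-sample statistic on within-patient differences with sign-flip
#'   permutations).
#' @param n_permutations number of label permutations (>= 100 for reported
#'   runs; default 1000).
#' @param fdr_target target false discovery rate for delta tuning
#'   (default 0.01).
#' @param delta_resolution number of grid points between 0 and the largest
#'   observed-vs-expected deviation.
#' @param seed integer fixing the permutation stream.
#' @return List of class `sam_config`.
#' @export
sam_config <- function(design = c("unpaired", "paired"),
                       n_permutations = 1000L, fdr_target = 0.01,
                       delta_resolution = 100L, seed = 1L) {
  design <- match.arg(design)
  if (n_permutations < 2) stop("n_permutations must be >= 2")
  if (fdr_target <= 0 || fdr_target >= 1) stop("fdr_target must lie in (0, 1)")
  structure(list(design = design, n_permutations = as.integer(n_permutations),
                 fdr_target = fdr_target,
                 delta_resolution = as.integer(delta_resolution),
                 seed = as.integer(seed)), class = "sam_config")
}

#' SAM relative difference for one feature
#'
#' `d = (mean(a) - mean(b)) / (s + s0)` where `s` is the pooled standard
#' error of the mean difference and `s0` the fudge factor that stabilizes
#' `d` for low-variance features.
#'
#' @param values_a,values_b numeric vectors (>= 2 values each).
#' @param s0 fudge factor (>= 0).
#' @return The relative difference `d`.
#' @export
sam_statistic <- function(values_a, values_b, s0 = 0) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs >= 2 values")
  }
  if (s0 < 0) stop("s0 must be >= 0")
  s <- pooled_se(values_a, values_b)
  if (s + s0 == 0) stop("zero variance with s0 = 0: d undefined")
  (mean(values_a) - mean(values_b)) / (s + s0)
}

pooled_se <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  sqrt((1 / na + 1 / nb) * sp2)
}

# vectorized numerator r and pooled SE s for all features, two-class unpaired
sam_r_s <- function(X, is_a) {
  na <- sum(is_a); nb <- sum(!is_a)
  A <- X[, is_a, drop = FALSE]; B <- X[, !is_a, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  ssa <- rowSums(A * A) - na * ma^2
  ssb <- rowSums(B * B) - nb * mb^2
  s <- sqrt((1 / na + 1 / nb) * pmax(ssa + ssb, 0) / (na + nb - 2))
  list(r = ma - mb, s = s, mean_a = ma, mean_b = mb)
}

#' Estimate the SAM fudge factor s0
#'
#' Follows the canonical percentile search: candidate values are the
#' \{0, 5, ..., 100\} percentiles of the per-feature pooled standard errors
#' `s`; for each candidate the features are windowed into (up to) 100
#' s-quantile groups and the coefficient of variation of the within-window
#' median absolute deviation of `d` is computed. The candidate minimizing
#' this CV wins; ties go to the smallest percentile.
#'
#' @param x `expr_matrix` or plain numeric matrix (features x samples).
#' @param labels logical or two-level vector marking group membership
#'   (TRUE / first level = group a).
#' @return The estimated s0 (>= 0).
#' @export
estimate_s0 <- function(x, labels) {
  X <- unclass(x)
  is_a <- as_group_a(labels, ncol(X))
  rs <- sam_r_s(X, is_a)
  s0_from_r_s(rs$r, rs$s)
}

s0_from_r_s <- function(r, s) {
  alphas <- seq(0, 1, by = 0.05)
  cand <- stats::quantile(s, alphas, names = FALSE, type = 7)
  n_win <- min(100L, max(2L, length(s)))
  win <- cut(rank(s, ties.method = "first"), breaks = n_win, labels = FALSE)
  cvs <- vapply(cand, function(s0c) {
    d <- r / (s + s0c)
    v <- tapply(d, win, function(z) stats::mad(z))
    v <- v[is.finite(v)]
    if (!length(v) || mean(v) == 0) return(0)
    stats::sd(v) / mean(v)
  }, 0)
  cand[which.min(cvs)]  # which.min takes the first (smallest-percentile) tie
}

as_group_a <- function(labels, n) {
  if (is.logical(labels)) {
    if (length(labels) != n) stop("label length mismatch")
    return(labels)
  }
  lv <- unique(labels)
  if (length(lv) != 2) stop("labels must have exactly two levels")
  labels == lv[1]
}

#' Significance Analysis of Microarrays with permutation FDR
#'
#' Computes the SAM relative difference for every feature, compares observed
#' order statistics with their expectation under label permutations, and
#' tunes the threshold delta to a target FDR. For each delta the called set
#' collects features whose sorted `d` deviates from the permutation
#' expectation by more than delta (asymmetric cutoffs found by scanning
#' outward from the origin of the quantile-quantile curve); the FDR estimate
#' is `pi0 * median permuted call count / observed call count`, with `pi0`
#' estimated from the fraction of observed `d` inside the central 50% of the
#' permuted distribution. Feature q-values are the smallest estimated FDR
#' over thresholds at which the feature is called.
#'
#' @param x `expr_matrix`.
#' @param sheet [sample_sheet()].
#' @param contrast length-2 character, e.g. `c("T", "N")`: class a vs
#'   class b; `d` and `log2fc` are oriented a minus b.
#' @param config a [sam_config()].
#' @return List of class `sam_result`: `results` (data.frame: feature_id,
#'   d, log2fc, mean_a, mean_b, q, called), `delta_table` (delta, n_called,
#'   fdr), `delta` (chosen threshold or NA), `s0`, `pi0`, `config`,
#'   `contrast`.
#' @export
sam_fdr <- function(x, sheet, contrast, config = sam_config()) {
  stopifnot(is_expression_matrix(x), inherits(config, "sam_config"))
  if (length(contrast) != 2) stop("contrast must name two classes")
  tiss <- tissue_of(sheet, colnames(x))
  keep <- tiss %in% contrast
  X <- unclass(x)[, keep, drop = FALSE]
  tiss <- tiss[keep]
  if (sum(tiss == contrast[1]) < 2 || sum(tiss == contrast[2]) < 2) {
    stop("each contrast class needs >= 2 samples")
  }
  set.seed(config$seed)
  if (config$design == "unpaired") {
    perm <- sam_perm_unpaired(X, tiss == contrast[1], config$n_permutations)
  } else {
    perm <- sam_perm_paired(X, sheet, colnames(X), tiss, contrast,
                            config$n_permutations)
  }
  d_obs <- perm$d_obs
  D_perm <- perm$D_perm
  m <- length(d_obs)

  ord <- order(d_obs)
  d_sorted <- d_obs[ord]
  D_sorted <- apply(D_perm, 2, sort)
  d_bar <- rowMeans(D_sorted)
  diffs <- d_sorted - d_bar

  # pi0 from the central 50% of the permuted d distribution
  qs <- stats::quantile(D_perm, c(0.25, 0.75))
  pi0 <- min(1, sum(d_obs > qs[1] & d_obs < qs[2]) / (0.5 * m))

  i0 <- which.min(abs(d_bar))
  deltas <- seq(0, max(abs(diffs)), length.out = config$delta_resolution + 1)[-1]
  perm_sorted_all <- sort(as.vector(D_perm))
  n_perm <- ncol(D_perm)

  delta_table <- data.frame(delta = deltas, n_called = 0L, fdr = NA_real_)
  qvals <- rep(1, m)
  called_at_chosen <- rep(FALSE, m)
  fdr_prev <- Inf
  for (j in seq_along(deltas)) {
    delta <- deltas[j]
    up_idx <- which(diffs[i0:m] > delta)
    cutup <- if (length(up_idx)) d_sorted[i0 + min(up_idx) - 1] else Inf
    down_idx <- which(diffs[seq_len(i0)] < -delta)
    cutlow <- if (length(down_idx)) d_sorted[max(down_idx)] else -Inf
    called <- d_obs >= cutup | d_obs <= cutlow
    n_called <- sum(called)
    if (n_called == 0) {
      fdr <- 0
    } else {
      counts <- colSums(D_perm >= cutup) + colSums(D_perm <= cutlow)
      fdr <- min(1, pi0 * stats::median(counts) / n_called)
    }
    fdr <- min(fdr, fdr_prev)  # monotone non-increasing in delta
    fdr_prev <- fdr
    delta_table$n_called[j] <- n_called
    delta_table$fdr[j] <- fdr
    qvals[called] <- pmin(qvals[called], fdr)
  }
  ok <- delta_table$fdr <= config$fdr_target & delta_table$n_called > 0
  chosen <- if (any(ok)) delta_table$delta[which(ok)[1]] else NA_real_
  if (!is.na(chosen)) {
    # call set at the chosen delta
    up_idx <- which(diffs[i0:m] > chosen)
    cutup <- if (length(up_idx)) d_sorted[i0 + min(up_idx) - 1] else Inf
    down_idx <- which(diffs[seq_len(i0)] < -chosen)
    cutlow <- if (length(down_idx)) d_sorted[max(down_idx)] else -Inf
    called_at_chosen <- d_obs >= cutup | d_obs <= cutlow
  }
  results <- data.frame(feature_id = rownames(X), d = d_obs,
                        log2fc = perm$log2fc, mean_a = perm$mean_a,
                        mean_b = perm$mean_b, q = qvals,
                        called = called_at_chosen, stringsAsFactors = FALSE)
  structure(list(results = results, delta_table = delta_table, delta = chosen,
                 s0 = perm$s0, pi0 = pi0, config = config,
                 contrast = contrast), class = "sam_result")
}

sam_perm_unpaired <- function(X, is_a, n_perm) {
  n <- ncol(X); na <- sum(is_a)
  rs <- sam_r_s(X, is_a)
  s0 <- s0_from_r_s(rs$r, rs$s)
  d_obs <- rs$r / (rs$s + s0)

  # sample distinct label assignments (choose which samples play group a)
  seen <- character(0)
  assigns <- matrix(FALSE, nrow = n, ncol = 0)
  guard <- 0
  while (ncol(assigns) < n_perm && guard < 50 * n_perm) {
    guard <- guard + 1
    idx <- sample.int(n, na)
    key <- paste(sort(idx), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    v <- rep(FALSE, n); v[idx] <- TRUE
    assigns <- cbind(assigns, v)
  }
  B <- ncol(assigns)
  nb <- n - na
  X2 <- X * X
  Pa <- assigns * 1
  SA <- X %*% Pa; SA2 <- X2 %*% Pa
  ST <- rowSums(X); ST2 <- rowSums(X2)
  SB <- ST - SA; SB2 <- ST2 - SA2
  ssa <- SA2 - SA^2 / na
  ssb <- SB2 - SB^2 / nb
  S <- sqrt((1 / na + 1 / nb) * pmax(ssa + ssb, 0) / (n - 2))
  D_perm <- (SA / na - SB / nb) / (S + s0)
  list(d_obs = d_obs, D_perm = D_perm, s0 = s0, log2fc = rs$r,
       mean_a = rs$mean_a, mean_b = rs$mean_b)
}

# paired design: one-sample SAM on within-patient (a - b) differences with
# sign-flip permutations; patients lacking either sample are dropped
sam_perm_paired <- function(X, sheet, sample_ids, tiss, contrast, n_perm) {
  pid <- sheet$patient_id[match(sample_ids, sheet$sample_id)]
  pa <- pid[tiss == contrast[1]]; pb <- pid[tiss == contrast[2]]
  pts <- intersect(pa, pb)
  if (length(pts) < 2) stop("paired design needs >= 2 complete pairs")
  dropped <- setdiff(union(pa, pb), pts)
  if (length(dropped)) {
    warning(length(dropped), " patient(s) without a complete pair dropped")
  }
  ia <- match(paste(pts, contrast[1]), paste(pid, tiss))
  ib <- match(paste(pts, contrast[2]), paste(pid, tiss))
  Dx <- X[, ia, drop = FALSE] - X[, ib, drop = FALSE]
  k <- ncol(Dx)
  r <- rowMeans(Dx)
  ss <- rowSums(Dx * Dx) - k * r^2
  s <- sqrt(pmax(ss, 0) / (k - 1)) / sqrt(k)
  s0 <- s0_from_r_s(r, s)
  d_obs <- r / (s + s0)

  signs <- matrix(sample(c(-1, 1), k * n_perm, replace = TRUE), nrow = k)
  Rp <- (Dx %*% signs) / k
  SS <- rowSums(Dx * Dx)  # invariant under sign flips
  Sp <- sqrt(pmax(SS - k * Rp^2, 0) / (k - 1)) / sqrt(k)
  D_perm <- Rp / (Sp + s0)
  ma <- rowMeans(X[, ia, drop = FALSE]); mb <- rowMeans(X[, ib, drop = FALSE])
  list(d_obs = d_obs, D_perm = D_perm, s0 = s0, log2fc = r,
       mean_a = ma, mean_b = mb)
}

#' Select differential miRNAs by fold change and background expression
#'
#' From a SAM result, keeps called features with `|log2fc| > fc_threshold`
#' and mean expression above `background` in at least one of the contrasted
#' groups. The default `fc_threshold = 3` is on the log2 scale (an 8-fold
#' linear change); set `log2_scale = FALSE` to read the threshold as a
#' linear ratio instead.
#'
#' @param sam a `sam_result` (or its `results` data.frame).
#' @param fc_threshold fold-change threshold (default 3 log2 units).
#' @param background background expression level (default 5).
#' @param log2_scale interpret `fc_threshold` in log2 units (default TRUE).
#' @return data.frame of selected features with a `direction` column.
#' @export
select_dems <- function(sam, fc_threshold = 3.0, background = 5.0,
                        log2_scale = TRUE) {
  res <- if (inherits(sam, "sam_result")) sam$results else sam
  if (!nrow(res)) return(cbind(res, direction = character(0)))
  thr <- if (log2_scale) fc_threshold else log2(fc_threshold)
  keep <- res$called & abs(res$log2fc) > thr &
    (res$mean_a > background | res$mean_b > background)
  out <- res[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}
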