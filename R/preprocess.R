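#' Filter miRNAs by detection across samples
#'
#' A miRNA is retained when it is detected in at least `min_detected` samples
#' or when all of its undetected samples fall within a single tissue class
#' (a class-restricted absence — for example a miRNA silent only in
#' metastases — is biology, not background, and is exempt from the filter).
#'
#' @param x miRNA `expr_matrix`.
#' @param sheet [sample_sheet()]; required for the class-exemption rule.
#'   With `sheet = NULL` only the count rule applies.
#' @param detection optional logical matrix, same dimensions as `x`, TRUE
#'   where the miRNA was called detected. When absent, detection defaults to
#'   `x > detection_floor`.
#' @param min_detected minimum number of detected samples (default 20).
#' @param detection_floor log2 signal above which a value counts as detected
#'   when no detection matrix is supplied (default 1.0, near array
#'   background).
#' @return Filtered `expr_matrix`, feature order preserved.
#' @export
filter_mirnas_by_detection <- function(x, sheet = NULL, detection = NULL,
                                       min_detected = 20, detection_floor = 1.0) {
  stopifnot(is_expression_matrix(x))
  if (is.null(detection)) {
    detection <- unclass(x) > detection_floor
  } else {
    if (!is.logical(detection) || !identical(dim(detection), dim(x))) {
      stop("detection matrix must be logical with the same dimensions as x")
    }
  }
  n_det <- rowSums(detection)
  keep <- n_det >= min_detected
  if (!is.null(sheet)) {
    tiss <- tissue_of(sheet, colnames(x))
    one_class <- apply(!detection, 1, function(und) {
      length(unique(tiss[und])) <= 1
    })
    keep <- keep | one_class
  } else {
    keep <- keep | n_det == ncol(x)
  }
  subset_matrix(x, features = which(keep))
}

#' Filter genes by expression-profile variability
#'
#' Ranks features by variance of log2 values across all samples and retains
#' the `floor((1 - drop_fraction) * n)` most variable features, in their
#' original order. Ties are broken by input order (stable), so an all-equal
#' matrix retains its leading features.
#'
#' @param x `expr_matrix`.
#' @param drop_fraction fraction of least variable features to drop
#'   (default 0.30).
#' @return Filtered `expr_matrix`.
#' @export
filter_genes_by_variability <- function(x, drop_fraction = 0.30) {
  stopifnot(is_expression_matrix(x))
  if (!is.numeric(drop_fraction) || drop_fraction < 0 || drop_fraction >= 1) {
    stop("drop_fraction must lie in [0, 1)")
  }
  if (ncol(x) < 2) stop("variability filter needs >= 2 samples")
  v <- apply(unclass(x), 1, stats::var)
  keep_n <- floor((1 - drop_fraction) * nrow(x))
  keep <- sort(utils::head(order(v, decreasing = TRUE), keep_n))
  subset_matrix(x, features = keep)
}

#' Filter features by mean log2 signal
#'
#' Retains features whose mean signal exceeds `floor` (default 5, the
#' conventional mid-scale cut separating moderately expressed features from
#' the weakly expressed majority on a 0-15 log2 scale).
#'
#' @param x `expr_matrix`.
#' @param floor signal threshold (log2 units).
#' @param sheet optional sample sheet; with `scope = "per_class"` a feature
#'   is kept if its mean exceeds the floor in at least one tissue class.
#' @param scope `"all"` (mean over all samples) or `"per_class"`.
#' @return Filtered `expr_matrix`.
#' @export
filter_by_mean_signal <- function(x, floor = 5.0, sheet = NULL,
                                  scope = c("all", "per_class")) {
  stopifnot(is_expression_matrix(x))
  scope <- match.arg(scope)
  if (nrow(x) == 0) return(x)
  if (scope == "all") {
    keep <- rowMeans(unclass(x)) > floor
  } else {
    if (is.null(sheet)) stop("per-class scope requires a sample sheet")
    tiss <- tissue_of(sheet, colnames(x))
    keep <- Reduce(`|`, lapply(unique(tiss), function(cl) {
      rowMeans(unclass(x)[, tiss == cl, drop = FALSE]) > floor
    }))
  }
  subset_matrix(x, features = which(keep))
}

#' Count up-/down-/unchanged features across the two progression transitions
#'
#' For the T-vs-N and M-vs-T contrasts, computes per-feature log2 fold change
#' as the difference of tissue-class means and classifies each feature as
#' up-modulated, down-modulated, or unchanged at `|log2FC| > fc_threshold`
#' (the default 1 corresponds to a two-fold linear change).
#'
#' @param x `expr_matrix`.
#' @param sheet [sample_sheet()].
#' @param fc_threshold absolute log2 fold-change threshold (default 1).
#' @return data.frame with columns contrast, up, down, unchanged; the three
#'   counts sum to `nrow(x)` in each contrast.
#' @export
transition_pattern_counts <- function(x, sheet, fc_threshold = 1.0) {
  stopifnot(is_expression_matrix(x))
  tiss <- tissue_of(sheet, colnames(x))
  class_mean <- function(cl) {
    idx <- tiss == cl
    if (!any(idx)) stop("no samples of class ", cl)
    rowMeans(unclass(x)[, idx, drop = FALSE])
  }
  mN <- class_mean("N"); mT <- class_mean("T"); mM <- class_mean("M")
  one <- function(contrast, fc) {
    data.frame(contrast = contrast,
               up = sum(fc > fc_threshold),
               down = sum(fc < -fc_threshold),
               unchanged = sum(abs(fc) <= fc_threshold))
  }
  rbind(one("TvN", mT - mN), one("MvT", mM - mT))
}

#' Unsupervised hierarchical clustering of samples
#'
#' Samples are clustered on correlation distance (1 - Pearson correlation of
#' their expression profiles) with average linkage by default; both are
#' configurable since neither is canonical.
#'
#' @param x `expr_matrix`.
#' @param metric `"correlation"` or `"euclidean"`.
#' @param linkage linkage method passed to [stats::hclust()].
#' @param k optional number of flat clusters to cut.
#' @return List of class `clustering_result`: `hclust` (the merge tree),
#'   `clusters` (named vector or NULL), `metric`, `linkage`.
#' @export
cluster_samples <- function(x, metric = c("correlation", "euclidean"),
                            linkage = "average", k = NULL) {
  stopifnot(is_expression_matrix(x))
  metric <- match.arg(metric)
  if (ncol(x) < 2) stop("need >= 2 samples to cluster")
  d <- if (metric == "correlation") {
    stats::as.dist(1 - stats::cor(unclass(x)))
  } else {
    stats::dist(t(unclass(x)))
  }
  hc <- stats::hclust(d, method = linkage)
  clusters <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  structure(list(hclust = hc, clusters = clusters, metric = metric,
                 linkage = linkage), class = "clustering_result")
}

#' Per-patient tumor/metastasis pairing fraction
#'
#' Among patients contributing both a T and an M sample to the clustered
#' matrix, counts those whose two samples are mutual nearest neighbors in
#' cophenetic distance on the dendrogram. The returned fraction quantifies
#' how strongly the clustering pairs a patient's metastasis with its own
#' primary tumor rather than with other metastases.
#'
#' @param clustering a `clustering_result` from [cluster_samples()].
#' @param sheet [sample_sheet()].
#' @return Fraction in \[0, 1\].
#' @export
patient_pairing_score <- function(clustering, sheet) {
  stopifnot(inherits(clustering, "clustering_result"))
  coph <- as.matrix(stats::cophenetic(clustering$hclust))
  diag(coph) <- Inf
  samples <- rownames(coph)
  sub <- sheet[sheet$sample_id %in% samples & sheet$tissue %in% c("T", "M"), ]
  tab <- table(sub$patient_id)
  pts <- names(tab)[vapply(names(tab), function(p) {
    all(c("T", "M") %in% sub$tissue[sub$patient_id == p])
  }, TRUE)]
  if (!length(pts)) stop("no patient has both T and M samples in the clustering")
  paired <- vapply(pts, function(p) {
    ts <- sub$sample_id[sub$patient_id == p & sub$tissue == "T"]
    ms <- sub$sample_id[sub$patient_id == p & sub$tissue == "M"]
    nn_t <- samples[which.min(coph[ts, ])]
    nn_m <- samples[which.min(coph[ms, ])]
    nn_t == ms && nn_m == ts
  }, TRUE)
  mean(paired)
}

#' Biogenesis-balance summary of differential-miRNA expression
#'
#' Pools the expression values of a set of differentially expressed miRNAs
#' within each tissue class and tests pairwise mean equality with two-sided
#' Welch t-tests. A balanced biogenesis (no global gain or loss of miRNA
#' output across progression) shows near-identical class means and large
#' p-values.
#'
#' @param dem_ids character vector of miRNA feature IDs.
#' @param x miRNA `expr_matrix`.
#' @param sheet [sample_sheet()].
#' @return List with `means` (named per-class means) and `tests`
#'   (data.frame: class_a, class_b, p).
#' @export
biogenesis_balance <- function(dem_ids, x, sheet) {
  stopifnot(is_expression_matrix(x))
  miss <- setdiff(dem_ids, rownames(x))
  if (length(miss)) stop("DEM(s) absent from matrix: ", paste(miss, collapse = ", "))
  tiss <- tissue_of(sheet, colnames(x))
  vals <- lapply(c(N = "N", T = "T", M = "M"), function(cl) {
    as.vector(unclass(x)[dem_ids, tiss == cl, drop = FALSE])
  })
  means <- vapply(vals, mean, 0)
  pairs <- utils::combn(c("N", "T", "M"), 2)
  tests <- data.frame(class_a = pairs[1, ], class_b = pairs[2, ], p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    a <- vals[[pairs[1, i]]]; b <- vals[[pairs[2, i]]]
    tests$p[i] <- if (identical(a, b)) 1
    else if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # both classes degenerate: means either coincide or differ exactly
      as.numeric(mean(a) == mean(b))
    } else stats::t.test(a, b)$p.value
  }
  list(means = means, tests = tests)
}

#' Shannon entropy of an expression profile
#'
#' Discretizes the profile into `n_bins` equal-width bins over its observed
#' range and returns `H = -sum p_i log2 p_i` in bits. Used to pick
#' minimum-variability reference features (housekeeping controls): a constant
#' profile has zero entropy by definition, and entropy is bounded above by
#' `log2(n_bins)`.
#'
#' @param profile numeric vector of log2 values.
#' @param n_bins number of equal-width bins (default 10).
#' @return Entropy in bits.
#' @export
expression_entropy <- function(profile, n_bins = 10) {
  if (!length(profile)) stop("empty profile")
  if (any(!is.finite(profile))) stop("profile must be finite")
  rng <- range(profile)
  if (rng[1] == rng[2]) return(0)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(findInterval(profile, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  p <- counts[counts > 0] / length(profile)
  -sum(p * log2(p))
}
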