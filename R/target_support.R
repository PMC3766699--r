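#' Samples assayed on both the miRNA and the gene platform
#'
#' @param mirna_matrix,gene_matrix expression matrices.
#' @param sheet optional [sample_sheet()]; when given, matched samples are
#'   additionally restricted to samples listed in the sheet.
#' @return Character vector of matched sample IDs, in the order they appear
#'   in the miRNA matrix.
#' @export
match_samples <- function(mirna_matrix, gene_matrix, sheet = NULL) {
  stopifnot(is_expression_matrix(mirna_matrix), is_expression_matrix(gene_matrix))
  matched <- intersect(colnames(mirna_matrix), colnames(gene_matrix))
  if (!is.null(sheet)) matched <- intersect(matched, sheet$sample_id)
  if (!length(matched)) stop("no matched samples between the two matrices")
  matched
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' `p` is derived from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom. Perfect correlation gives `p = 0`.
#'
#' @param x,y numeric vectors, length >= 4, non-constant.
#' @return List with `r`, `p`, `n`.
#' @export
correlate <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("need >= 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment `q_(i) = min_(j>=i) m p_(j) / j`, capped at 1 and
#' mapped back to input order.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Storey-style q-values with pi0 estimation
#'
#' A less conservative alternative to [bh_adjust()]: BH scaled by an
#' estimate of the null fraction `pi0 = #\{p > lambda\} / ((1 - lambda) m)`.
#'
#' @param pvalues numeric vector.
#' @param lambda tuning parameter (default 0.5).
#' @return q-values.
#' @export
storey_adjust <- function(pvalues, lambda = 0.5) {
  m <- length(pvalues)
  if (!m) return(numeric(0))
  pi0 <- min(1, sum(pvalues > lambda) / ((1 - lambda) * m))
  pmin(1, pi0 * stats::p.adjust(pvalues, method = "BH"))
}

#' Expression-supported miRNA-target relations
#'
#' Tests every predicted (miRNA, gene) pair whose members are present in the
#' (pre-filtered) matrices for Pearson correlation across matched samples,
#' corrects the p-values over all performed tests, and retains relations
#' that are significant (`q <= q_max`) and negatively correlated (under the
#' default `direction = "negative"`; miRNA repression destabilizes target
#' mRNA, so a true target anti-correlates with its miRNA).
#'
#' @param mirna_matrix,gene_matrix expression matrices; the miRNA matrix is
#'   expected to be signal-floor filtered already.
#' @param predictions prediction data.frame (mirna_id, gene_id, plus
#'   optional score, conserved); duplicate pairs are collapsed to one test.
#' @param sheet optional sample sheet restricting matched samples.
#' @param q_max FDR threshold (default 0.01).
#' @param direction `"negative"` (r < 0 required) or `"both"`.
#' @param method `"bh"` (default, deterministic and conservative) or
#'   `"storey"`.
#' @return data.frame of class `supported_relations`: mirna_id, gene_id, r,
#'   p, q, conserved, n, sorted by r ascending. Attributes: `n_tested`,
#'   `n_skipped` (predictions whose miRNA or gene is absent), `r_cut` (the
#'   realized largest — least negative — supported correlation).
#' @export
support_targets <- function(mirna_matrix, gene_matrix, predictions,
                            sheet = NULL, q_max = 0.01,
                            direction = c("negative", "both"),
                            method = c("bh", "storey")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  matched <- match_samples(mirna_matrix, gene_matrix, sheet)
  if (length(matched) < 4) stop("need >= 4 matched samples")
  if (is.null(predictions$conserved)) predictions$conserved <- NA
  predictions <- predictions[!duplicated(paste(predictions$mirna_id,
                                               predictions$gene_id)), , drop = FALSE]
  present <- predictions$mirna_id %in% rownames(mirna_matrix) &
    predictions$gene_id %in% rownames(gene_matrix)
  tested <- predictions[present, , drop = FALSE]
  n_skipped <- sum(!present)
  empty <- data.frame(mirna_id = character(), gene_id = character(),
                      r = numeric(), p = numeric(), q = numeric(),
                      conserved = logical(), n = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(tested)) {
    return(structure(empty, n_tested = 0L, n_skipped = n_skipped,
                     r_cut = NA_real_, class = c("supported_relations", "data.frame")))
  }
  Mm <- unclass(mirna_matrix)[, matched, drop = FALSE]
  Mg <- unclass(gene_matrix)[, matched, drop = FALSE]
  n <- length(matched)
  # row-standardize once; r for a pair is then a scaled dot product
  zs <- function(M) {
    mu <- rowMeans(M)
    sd <- sqrt(rowSums((M - mu)^2))
    sweep(M - mu, 1, pmax(sd, .Machine$double.eps), "/")
  }
  Zm <- zs(Mm); Zg <- zs(Mg)
  const_m <- apply(Mm, 1, function(v) stats::sd(v) == 0)
  const_g <- apply(Mg, 1, function(v) stats::sd(v) == 0)
  bad <- const_m[tested$mirna_id] | const_g[tested$gene_id]
  n_skipped <- n_skipped + sum(bad)
  tested <- tested[!bad, , drop = FALSE]
  if (!nrow(tested)) {
    return(structure(empty, n_tested = 0L, n_skipped = n_skipped,
                     r_cut = NA_real_, class = c("supported_relations", "data.frame")))
  }
  r <- rowSums(Zm[tested$mirna_id, , drop = FALSE] *
                 Zg[tested$gene_id, , drop = FALSE])
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(-abs(r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))),
                            df = n - 2))
  q <- if (method == "bh") bh_adjust(p) else storey_adjust(p)
  keep <- q <= q_max & (if (direction == "negative") r < 0 else TRUE)
  out <- data.frame(mirna_id = tested$mirna_id, gene_id = tested$gene_id,
                    r = r, p = p, q = q, conserved = tested$conserved,
                    n = n, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(out$r), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_tested = nrow(tested), n_skipped = n_skipped,
            r_cut = if (nrow(out)) max(out$r) else NA_real_,
            class = c("supported_relations", "data.frame"))
}

#' Summarize a supported-relation table
#'
#' @param relations output of [support_targets()].
#' @return List: `n_relations`, `n_mirnas`, `n_genes`, `targets_per_mirna`
#'   (min/mean/max), `conserved_fraction`.
#' @export
summarize_support <- function(relations) {
  if (!nrow(relations)) {
    return(list(n_relations = 0L, n_mirnas = 0L, n_genes = 0L,
                targets_per_mirna = c(min = 0, mean = 0, max = 0),
                conserved_fraction = NA_real_))
  }
  counts <- table(relations$mirna_id)
  list(n_relations = nrow(relations),
       n_mirnas = length(unique(relations$mirna_id)),
       n_genes = length(unique(relations$gene_id)),
       targets_per_mirna = c(min = min(counts), mean = mean(counts),
                             max = max(counts)),
       conserved_fraction = mean(relations$conserved, na.rm = TRUE))
}
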