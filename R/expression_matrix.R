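#' Construct a validated expression matrix
#'
#' An expression matrix holds log2 intensity values with features in rows and
#' samples in columns. All downstream statistics assume a complete matrix on
#' the log2 scale (typical array signal lies in \[0, 15\]); missing or
#' non-finite values are rejected at construction.
#'
#' @param values numeric matrix, features x samples, log2 intensities.
#' @param feature_kind `"miRNA"` or `"gene"`.
#' @param feature_ids,sample_ids identifiers; default to `dimnames(values)`.
#' @return An object of class `expr_matrix`: the numeric matrix with
#'   `feature_kind` attribute and validated unique dimnames.
#' @export
expression_matrix <- function(values, feature_kind = c("miRNA", "gene"),
                              feature_ids = rownames(values),
                              sample_ids = colnames(values)) {
  feature_kind <- match.arg(feature_kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("expression values must be numeric")
  }
  if (is.null(feature_ids) && nrow(values) == 0) feature_ids <- character(0)
  if (is.null(sample_ids) && ncol(values) == 0) sample_ids <- character(0)
  if (is.null(feature_ids) || is.null(sample_ids)) {
    stop("feature and sample identifiers are required")
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  dup_f <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup_f)) {
    stop("duplicate feature IDs: ", paste(dup_f, collapse = ", "))
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop("duplicate sample IDs: ", paste(dup_s, collapse = ", "))
  }
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-finite expression value at feature '%s', sample '%s'",
                 feature_ids[bad[1, 1]], sample_ids[bad[1, 2]]))
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(values, feature_kind = feature_kind, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %s: %d features x %d samples, log2 range [%.2f, %.2f]\n",
              attr(x, "feature_kind"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x object to test.
#' @export
is_expression_matrix <- function(x) inherits(x, "expr_matrix")

feature_kind <- function(x) attr(x, "feature_kind")

#' Subset an expression matrix, preserving class and kind
#'
#' @param x an `expr_matrix`.
#' @param features,samples character or integer indices; `NULL` keeps all.
#' @return An `expr_matrix`.
#' @export
subset_matrix <- function(x, features = NULL, samples = NULL) {
  stopifnot(is_expression_matrix(x))
  if (is.null(features)) features <- seq_len(nrow(x))
  if (is.null(samples)) samples <- seq_len(ncol(x))
  expression_matrix(x[features, samples, drop = FALSE],
                    feature_kind = feature_kind(x))
}

#' Construct a sample sheet
#'
#' Maps each sample to its patient and tissue class: normal colon mucosa (N),
#' primary tumor (T) or liver metastasis (M). Per assay, a patient contributes
#' at most one sample per tissue class.
#'
#' @param sample_id,patient_id,tissue character vectors of equal length;
#'   tissue values must be in `{N, T, M}`.
#' @return A `data.frame` of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, patient_id, tissue) {
  sample_id <- as.character(sample_id)
  patient_id <- as.character(patient_id)
  tissue <- as.character(tissue)
  if (length(sample_id) != length(patient_id) || length(sample_id) != length(tissue)) {
    stop("sample_id, patient_id and tissue must have equal length")
  }
  bad <- setdiff(unique(tissue), c("N", "T", "M"))
  if (length(bad)) {
    stop("unknown tissue class(es): ", paste(bad, collapse = ", "),
         " (expected N, T or M)")
  }
  dup <- unique(sample_id[duplicated(sample_id)])
  if (length(dup)) {
    stop("duplicate sample IDs: ", paste(dup, collapse = ", "))
  }
  key <- paste(patient_id, tissue, sep = "\r")
  dupk <- unique(key[duplicated(key)])
  if (length(dupk)) {
    stop("patient/tissue pair duplicated: ",
         paste(gsub("\r", "/", dupk), collapse = ", "))
  }
  out <- data.frame(sample_id = sample_id, patient_id = patient_id,
                    tissue = tissue, stringsAsFactors = FALSE)
  class(out) <- c("sample_sheet", "data.frame")
  out
}

# tissue labels for a set of sample ids, in that order
tissue_of <- function(sheet, sample_ids) {
  idx <- match(sample_ids, sheet$sample_id)
  if (anyNA(idx)) {
    stop("samples absent from sheet: ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  }
  sheet$tissue[idx]
}
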