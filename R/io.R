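#' Read a log2 expression matrix from TSV
#'
#' Expected layout: tab-delimited, UTF-8, one header row of sample IDs, first
#' column feature IDs, numeric body. Missing or non-numeric cells are a hard
#' error (downstream statistics assume complete matrices), as are duplicate
#' feature or sample identifiers. Column order is preserved.
#'
#' @param path file path.
#' @param feature_kind `"miRNA"` or `"gene"`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, feature_kind = c("miRNA", "gene")) {
  feature_kind <- match.arg(feature_kind)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("expression TSV needs a feature-ID column plus >= 1 sample")
  ids <- tab[[1]]
  samples <- colnames(tab)[-1]
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s)) {
    stop("duplicate sample IDs in header: ", paste(dup_s, collapse = ", "))
  }
  body <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or missing value at row '%s', column '%s'",
                 ids[bad[1, 1]], samples[bad[1, 2]]))
  }
  dimnames(num) <- list(ids, samples)
  expression_matrix(num, feature_kind = feature_kind)
}

#' Write an expression matrix to TSV
#'
#' @param x an `expr_matrix`.
#' @param path output file.
#' @param digits significant digits written (default 6; reader round-trips at
#'   this precision).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, digits = 6) {
  stopifnot(is_expression_matrix(x))
  tab <- data.frame(feature_id = rownames(x),
                    signif(unclass(x), digits),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' Columns: `sample_id`, `patient_id`, `tissue` (N/T/M).
#'
#' @param path file path.
#' @return A [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", colClasses = "character")
  need <- c("sample_id", "patient_id", "tissue")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  sample_sheet(tab$sample_id, tab$patient_id, tab$tissue)
}

#' @rdname read_sample_sheet
#' @param sheet a `sample_sheet`.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read miRNA target predictions from TSV
#'
#' Columns: `mirna_id`, `gene_id`, `score` (prediction score; for
#' miRSVR-style input more negative means stronger predicted repression),
#' `conserved` (TRUE/FALSE). Duplicate (miRNA, gene) pairs are an error: each
#' pair is one statistical test downstream.
#'
#' @param path file path.
#' @return data.frame with the four columns above.
#' @export
read_target_predictions <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("mirna_id", "gene_id", "score", "conserved")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("prediction table missing column(s): ", paste(miss, collapse = ", "))
  tab$mirna_id <- as.character(tab$mirna_id)
  tab$gene_id <- as.character(tab$gene_id)
  tab$score <- as.numeric(tab$score)
  tab$conserved <- as.logical(tab$conserved)
  if (any(!is.finite(tab$score))) stop("non-finite prediction score")
  key <- paste(tab$mirna_id, tab$gene_id, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    stop("duplicated prediction pair(s): ", paste(gsub("\r", "->", dup), collapse = ", "))
  }
  tab[, need]
}

#' @rdname read_target_predictions
#' @param predictions prediction data.frame.
#' @export
write_target_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read validated TF interactions from TSV
#'
#' Columns: `regulator_id` (a transcription factor), `target_id`,
#' `target_kind` (`gene` or `miRNA`) and optionally `source_label`.
#' Rows must be unique on (regulator, target).
#'
#' @param path file path.
#' @return data.frame of interactions.
#' @export
read_interactions <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("regulator_id", "target_id", "target_kind")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("interaction table missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(tab$source_label)) tab$source_label <- ""
  bad <- setdiff(unique(tab$target_kind), c("gene", "miRNA"))
  if (length(bad)) stop("unknown target_kind: ", paste(bad, collapse = ", "))
  key <- paste(tab$regulator_id, tab$target_id, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    stop("duplicated interaction(s): ", paste(gsub("\r", "->", dup), collapse = ", "))
  }
  tab[, c(need, "source_label")]
}

#' @rdname read_interactions
#' @param interactions interaction data.frame.
#' @export
write_interactions <- function(interactions, path) {
  utils::write.table(interactions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Sets must be non-empty (a line with fewer than three fields is
#' rejected); duplicate members within a set are collapsed.
#'
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (!length(sets)) stop("GMT file contains no gene sets")
  empty <- names(sets)[vapply(sets, length, 1L) == 0]
  if (length(empty)) {
    stop("GMT line with fewer than 3 fields (empty set): ",
         paste(empty, collapse = ", "))
  }
  lapply(sets, unique)
}

#' @rdname read_gene_sets
#' @param sets named list of member vectors.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read survival records from TSV
#'
#' Columns: `patient_id`, `time` (months, > 0), `event` (1 = death by
#' disease, 0 = censored at last follow-up); any further numeric columns are
#' covariates (for example per-patient miRNA expression levels).
#'
#' @param path file path.
#' @return data.frame with patient_id, time, event plus covariate columns.
#' @export
read_survival <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("patient_id", "time", "event")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("survival table missing column(s): ", paste(miss, collapse = ", "))
  tab$patient_id <- as.character(tab$patient_id)
  tab$time <- as.numeric(tab$time)
  tab$event <- as.integer(as.logical(as.numeric(tab$event)))
  if (any(!is.finite(tab$time)) || any(tab$time <= 0)) {
    stop("survival time must be a positive number")
  }
  covs <- setdiff(colnames(tab), need)
  for (cv in covs) {
    tab[[cv]] <- as.numeric(tab[[cv]])
    if (any(!is.finite(tab[[cv]]))) stop("non-finite covariate value in '", cv, "'")
  }
  tab[, c(need, covs)]
}

#' @rdname read_survival
#' @param records survival data.frame.
#' @export
write_survival <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
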