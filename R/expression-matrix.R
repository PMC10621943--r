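#' Expression matrix with stage labels
#'
#' The pipeline's primary container: a non-negative samples x transcripts
#' matrix of FPKM-like values plus one binary stage label per sample
#' ("early" = AJCC I-II, "late" = III-IV).
#'
#' @param values numeric matrix, samples in rows, features in columns.
#'   Row names are sample ids, column names feature ids (generated when
#'   missing).
#' @param stage_labels character or factor, one of `"early"`/`"late"` per
#'   sample.
#' @param require_both_classes if `TRUE` (default) a single-class cohort is an
#'   error; if `FALSE` it is flagged with a warning (used when re-reading
#'   files, where downstream stages decide whether a single class is fatal).
#' @return an object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `stage` (a factor with levels early, late).
#' @export
expression_matrix <- function(values, stage_labels, require_both_classes = TRUE) {
  check_that(is.matrix(values) && is.numeric(values),
             "`values` must be a numeric matrix (samples x features)")
  check_that(!anyNA(values), "expression values must not contain missing values")
  check_that(all(values >= 0), "expression values must be non-negative (FPKM-like)")
  check_that(length(stage_labels) == nrow(values),
             "need exactly one stage label per sample (matrix row)")
  stage <- as_stage_factor(stage_labels)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%04d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("G%06d", seq_len(ncol(values)))
  check_that(!anyDuplicated(rownames(values)), "sample ids must be unique")
  check_that(!anyDuplicated(colnames(values)), "feature ids must be unique")
  if (length(unique(stage)) < 2L) {
    msg <- "cohort contains a single stage class"
    if (require_both_classes) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  structure(list(values = values, stage = stage), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d samples x %d features (early: %d, late: %d)\n",
              nrow(x$values), ncol(x$values),
              sum(x$stage == "early"), sum(x$stage == "late")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

sample_ids <- function(em) rownames(em$values)
feature_ids <- function(em) colnames(em$values)

#' Write an expression table to tab-separated text
#'
#' Layout: header row, first column `sample_id`, one column per feature id,
#' last column `stage`.
#'
#' @param em an [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(em, path) {
  check_that(inherits(em, "expr_matrix"), "`em` must be an expr_matrix")
  df <- data.table::data.table(sample_id = sample_ids(em))
  df <- cbind(df, data.table::as.data.table(em$values))
  df[["stage"]] <- as.character(em$stage)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read an expression table written by [write_expression_table()]
#'
#' Validates the layout and values; parse problems are reported with the
#' 1-based file line they occur on (line 1 is the header). A single-class
#' cohort is flagged with a warning rather than an error, so callers can
#' decide how to proceed.
#'
#' @param path path to a tab-separated expression table.
#' @return an `expr_matrix`.
#' @export
read_expression_table <- function(path) {
  check_that(file.exists(path), sprintf("file not found: %s", path))
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = TRUE, fill = FALSE,
                      data.table = TRUE, showProgress = FALSE),
    error = function(e) stop(sprintf("parse error in '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  cols <- names(dt)
  check_that("sample_id" %in% cols,
             "expression table lacks the required 'sample_id' column")
  check_that("stage" %in% cols,
             "expression table lacks the required 'stage' column")
  feat <- setdiff(cols, c("sample_id", "stage"))
  check_that(length(feat) >= 1L, "expression table has no feature columns")
  vals <- as.matrix(dt[, feat, with = FALSE])
  if (!is.numeric(vals))
    stop("feature columns must be numeric", call. = FALSE)
  bad <- which(rowSums(is.na(vals)) > 0L)
  if (length(bad))
    stop(sprintf("missing/non-numeric value at line %d", bad[1] + 1L), call. = FALSE)
  neg <- which(rowSums(vals < 0) > 0L)
  if (length(neg))
    stop(sprintf("negative expression value at line %d", neg[1] + 1L), call. = FALSE)
  rownames(vals) <- dt[["sample_id"]]
  labels <- dt[["stage"]]
  check_that(all(labels %in% STAGE_LEVELS),
             "stage column must contain only 'early'/'late'")
  expression_matrix(vals, labels, require_both_classes = FALSE)
}
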