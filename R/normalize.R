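#' Mask features that are constant on a training index set
#'
#' Cleaning is training-fold-only: a feature is dropped when its values are
#' identical across the given training rows, regardless of its behaviour on
#' held-out rows.
#'
#' @param values numeric samples x features matrix.
#' @param train_idx non-empty training row indices (at least 2 rows, otherwise
#'   every feature would be "constant").
#' @return a logical `feature_mask` vector, `TRUE` = keep, named by feature,
#'   with the producing index set stored in attribute `train_idx`.
#' @export
remove_constant_features <- function(values, train_idx) {
  check_that(length(train_idx) >= 2L,
             "need at least 2 training rows to assess constancy")
  tr <- values[train_idx, , drop = FALSE]
  first <- tr[rep(1L, nrow(tr)), , drop = FALSE]
  keep <- colSums(tr != first) > 0L
  names(keep) <- colnames(values)
  structure(keep, train_idx = train_idx, class = c("feature_mask", "logical"))
}

#' Fit z-score parameters on training rows
#'
#' @param values numeric samples x features matrix (constant features must be
#'   removed first for the same training rows).
#' @param train_idx training row indices.
#' @return `scaler_params` with per-feature `center` (mean) and `scale`
#'   (sample standard deviation, n-1 denominator).
#' @export
zscore_fit <- function(values, train_idx) {
  check_that(length(train_idx) >= 2L, "need at least 2 training rows")
  center <- col_means_sub(values, train_idx)
  scale <- col_sds_sub(values, train_idx)
  if (any(scale == 0))
    stop("zero training standard deviation; run remove_constant_features() first",
         call. = FALSE)
  structure(list(center = center, scale = scale, train_idx = train_idx,
                 method = "zscore"), class = "scaler_params")
}

#' Apply fitted z-score parameters
#'
#' Held-out rows are transformed with the training parameters unchanged (no
#' refit), so their mean/sd are not forced to (0, 1).
#'
#' @param values numeric samples x features matrix.
#' @param params a `scaler_params` from [zscore_fit()].
#' @param idx row indices to transform (default: all rows).
#' @return scaled matrix for the requested rows.
#' @export
zscore_apply <- function(values, params, idx = seq_len(nrow(values))) {
  check_that(inherits(params, "scaler_params") && params$method == "zscore",
             "`params` must come from zscore_fit()")
  x <- values[idx, , drop = FALSE]
  nr <- nrow(x)
  (x - rep(params$center, each = nr)) / rep(params$scale, each = nr)
}

#' Fit min-max parameters on a fit index set
#'
#' @param values numeric samples x features matrix.
#' @param fit_idx rows used to determine per-feature min and max.
#' @return `scaler_params` with `min` and `max` per feature.
#' @export
minmax_fit <- function(values, fit_idx = seq_len(nrow(values))) {
  x <- values[fit_idx, , drop = FALSE]
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  if (any(hi == lo))
    stop("constant feature in min-max fit; run remove_constant_features() first",
         call. = FALSE)
  structure(list(min = lo, max = hi, train_idx = fit_idx, method = "minmax"),
            class = "scaler_params")
}

#' Apply min-max parameters, clipping to [0, 1]
#'
#' @param values numeric samples x features matrix.
#' @param params a `scaler_params` from [minmax_fit()].
#' @param idx row indices to transform (default: all rows).
#' @return matrix of values in `[0, 1]`.
#' @export
minmax_apply <- function(values, params, idx = seq_len(nrow(values))) {
  check_that(inherits(params, "scaler_params") && params$method == "minmax",
             "`params` must come from minmax_fit()")
  x <- values[idx, , drop = FALSE]
  nr <- nrow(x)
  out <- (x - rep(params$min, each = nr)) /
    rep(params$max - params$min, each = nr)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Min-max scale a matrix into [0, 1]
#'
#' Convenience wrapper: fits on `fit_idx` and transforms all rows, mapping
#' each feature's fit-set minimum to 0 and maximum to 1, clipping out-of-range
#' applied values.
#'
#' @inheritParams minmax_fit
#' @return matrix of values in `[0, 1]`, all rows.
#' @export
minmax_scale <- function(values, fit_idx = seq_len(nrow(values))) {
  minmax_apply(values, minmax_fit(values, fit_idx))
}
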