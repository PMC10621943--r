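#' Rank-based ROC AUC
#'
#' Mann-Whitney formulation: the probability that a random late-stage sample
#' scores above a random early-stage sample, with ties counted half. The late
#' stage is the positive class throughout the package. Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores numeric decision scores, higher = late.
#' @param labels stage labels aligned with `scores`; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_stage_factor(labels)
  check_that(length(scores) == length(y), "scores and labels must align")
  n1 <- sum(y == "late"); n0 <- sum(y == "early")
  check_that(n1 > 0 && n0 > 0, "both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == "late"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts for binary stage prediction
#'
#' Positive class = late stage: `tp` = late predicted late, `tn` = early
#' predicted early.
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return a `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  for (v in list(tp, fp, fn, tn))
    check_that(is_count(v), "confusion counts must be non-negative integers")
  structure(list(tp = as.double(tp), fp = as.double(fp),
                 fn = as.double(fn), tn = as.double(tn)),
            class = "confusion_counts")
}

#' Tabulate confusion counts from predicted and true labels
#'
#' @param predicted,truth stage label vectors of equal length.
#' @return a `confusion_counts` object.
#' @export
tabulate_confusion <- function(predicted, truth) {
  p <- as_stage_factor(predicted); y <- as_stage_factor(truth)
  check_that(length(p) == length(y), "predicted and truth must align")
  confusion_counts(tp = sum(p == "late" & y == "late"),
                   fp = sum(p == "late" & y == "early"),
                   fn = sum(p == "early" & y == "late"),
                   tn = sum(p == "early" & y == "early"))
}

#' Threshold-based classification metrics from confusion counts
#'
#' Accuracy is reported as a percentage; sensitivity is late-stage recall and
#' specificity early-stage recall; F1 is computed per class from that class's
#' precision and recall (0 when undefined); MCC uses the determinant formula
#' and is defined as 0 when any marginal is zero.
#'
#' @param counts a [confusion_counts()] object.
#' @return one-row data.frame with `accuracy`, `f1_early`, `f1_late`, `mcc`,
#'   `sn`, `sp`.
#' @export
confusion_metrics <- function(counts) {
  check_that(inherits(counts, "confusion_counts"),
             "`counts` must be a confusion_counts object")
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  total <- tp + fp + fn + tn
  check_that(total > 0, "cannot compute metrics from zero scored samples")
  f1 <- function(two_tp, fp_, fn_) {
    den <- two_tp + fp_ + fn_
    if (den == 0) 0 else two_tp / den
  }
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den2 == 0) 0 else (tp * tn - fp * fn) / sqrt(den2)
  data.frame(
    accuracy = 100 * (tp + tn) / total,
    f1_early = f1(2 * tn, fn, fp),
    f1_late = f1(2 * tp, fp, fn),
    mcc = mcc,
    sn = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    sp = if (tn + fp == 0) NA_real_ else tn / (tn + fp))
}

# full metric row (AUC + threshold metrics) from scores
metric_row <- function(scores, labels, threshold) {
  pred <- ifelse(scores >= threshold, "late", "early")
  cbind(data.frame(auc_roc = roc_auc(scores, labels)),
        confusion_metrics(tabulate_confusion(pred, labels)))
}

#' Evaluate a selected feature set across the nested folds
#'
#' For each classifier and outer fold: z-score parameters are fit on the outer
#' training rows (features constant there are dropped for that fold), the
#' model is fit on the scaled training rows, and metrics are reported for the
#' training split, the inner validation folds (refit per inner partition) and
#' the outer test split. Rows are averages over folds: 10 outer folds for
#' train/test, all inner partitions for validation, at default settings.
#'
#' @param em an [expression_matrix()].
#' @param feature_set character vector of feature ids to evaluate.
#' @param plan a [build_nested_folds()] plan.
#' @param classifiers named list of [new_classifier()] objects
#'   (default [default_classifier_roster()]).
#' @param seed seed for classifiers with stochastic fits (e.g. random forest).
#' @return data.frame with one row per (classifier, split) holding mean
#'   `accuracy` (%), `auc_roc`, `f1_early`, `f1_late`, `mcc`, `sn`, `sp`.
#' @export
evaluate_feature_set <- function(em, feature_set, plan,
                                 classifiers = default_classifier_roster(),
                                 seed = 1L) {
  check_that(inherits(em, "expr_matrix"), "`em` must be an expr_matrix")
  check_that(all(feature_set %in% feature_ids(em)),
             "all requested features must exist in the matrix")
  check_that(length(feature_set) >= 1L, "feature set must be non-empty")
  values <- em$values[, feature_set, drop = FALSE]
  y <- em$stage

  rows <- list()
  with_seed(seed, {
    for (ci in seq_along(classifiers)) {
      clf <- classifiers[[ci]]
      per_split <- list(train = list(), validation = list(), test = list())
      for (i in seq_len(plan$k_outer)) {
        tr <- outer_train_idx(plan, i)
        te <- plan$outer[[i]]
        keep <- remove_constant_features(values, tr)
        v <- values[, keep, drop = FALSE]
        zs <- zscore_fit(v, tr)
        xtr <- zscore_apply(v, zs, tr)
        model <- tryCatch(clf$fit(xtr, y[tr]), error = function(e)
          stop(sprintf("classifier '%s' failed on outer fold %d: %s",
                       clf$name, i, conditionMessage(e)), call. = FALSE))
        per_split$train[[length(per_split$train) + 1L]] <-
          metric_row(clf$score(model, xtr), y[tr], clf$threshold)
        per_split$test[[length(per_split$test) + 1L]] <-
          metric_row(clf$score(model, zscore_apply(v, zs, te)), y[te], clf$threshold)
        for (j in seq_len(plan$k_inner)) {
          itr <- inner_train_idx(plan, i, j)
          iva <- plan$inner[[i]][[j]]
          ikeep <- remove_constant_features(v, itr)
          iv <- v[, ikeep, drop = FALSE]
          izs <- zscore_fit(iv, itr)
          im <- clf$fit(zscore_apply(iv, izs, itr), y[itr])
          per_split$validation[[length(per_split$validation) + 1L]] <-
            metric_row(clf$score(im, zscore_apply(iv, izs, iva)), y[iva],
                       clf$threshold)
        }
      }
      for (split in names(per_split)) {
        m <- do.call(rbind, per_split[[split]])
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(classifier = clf$name, split = split,
                     stringsAsFactors = FALSE),
          as.data.frame(t(colMeans(m))))
      }
    }
  })
  out <- do.call(rbind, rows)
  out$split <- factor(out$split, levels = c("train", "validation", "test"))
  out[order(match(out$classifier, vapply(classifiers, `[[`, "", "name")),
            out$split), , drop = FALSE]
}

#' Project an external cohort onto a reference feature vector, zero-filling
#'
#' When validating on an external cohort measured on a different platform,
#' features absent there are filled with exact zeros so the fitted model's
#' feature vector is preserved.
#'
#' @param feature_set reference feature ids (output column order).
#' @param available_ids feature ids present in `values` (defaults to its
#'   column names).
#' @param values numeric matrix whose columns are `available_ids`.
#' @return matrix with `length(feature_set)` columns in that order; missing
#'   features are all-zero columns.
#' @export
zero_fill_projection <- function(feature_set, available_ids = colnames(values),
                                 values) {
  check_that(length(available_ids) == ncol(values),
             "available_ids must match the columns of `values`")
  common <- intersect(feature_set, available_ids)
  if (length(common) == 0)
    stop(sprintf("no overlap: 0 of %d requested features are available",
                 length(feature_set)), call. = FALSE)
  out <- matrix(0, nrow = nrow(values), ncol = length(feature_set),
                dimnames = list(rownames(values), feature_set))
  out[, common] <- values[, match(common, available_ids), drop = FALSE]
  out
}
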