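#' Plug-in classifier contract
#'
#' Every classifier used in the wrapper search and the evaluation roster is a
#' small object with `fit(x, y)` (numeric matrix, stage factor) returning a
#' model, and `score(model, x)` returning one real score per row with higher
#' values favouring the late stage. `type` declares the decision threshold
#' semantics for label metrics: `"margin"` thresholds at 0, `"prob"` at 0.5
#' (predicted late when score >= threshold). Any external classifier — e.g. a
#' deep autoencoder — can be wrapped in the same contract and plugged in.
#'
#' @param name display name.
#' @param fit function(x, y) -> model.
#' @param score function(model, x) -> numeric scores, higher = late.
#' @param type `"margin"` or `"prob"`.
#' @return a `stage_classifier` object.
#' @export
new_classifier <- function(name, fit, score, type = c("margin", "prob")) {
  type <- match.arg(type)
  check_that(is.function(fit) && is.function(score),
             "`fit` and `score` must be functions")
  structure(list(name = name, fit = fit, score = score, type = type,
                 threshold = if (type == "margin") 0 else 0.5),
            class = "stage_classifier")
}

#' @export
print.stage_classifier <- function(x, ...) {
  cat(sprintf("<stage_classifier> %s (%s scores)\n", x$name, x$type))
  invisible(x)
}

#' Linear discriminant classifier (default wrapper classifier)
#'
#' A fast margin-based linear classifier: Fisher's linear discriminant via
#' \code{MASS::lda}, scored by the posterior probability of the late stage.
#' Chosen as the default for the genetic wrapper search because it fits in
#' milliseconds, keeping tens of thousands of fitness evaluations tractable;
#' a linear SVM ([classifier_svm_linear()]) is interchangeable through the
#' same contract.
#'
#' @return a `stage_classifier`.
#' @export
classifier_lda <- function() {
  new_classifier(
    name = "LDA",
    fit = function(x, y) suppressWarnings(MASS::lda(x, grouping = y)),
    score = function(model, x) {
      unname(stats::predict(model, x)$posterior[, "late"])
    },
    type = "prob")
}

#' Linear support vector machine classifier
#'
#' @param cost soft-margin cost parameter.
#' @return a `stage_classifier` scoring by the signed margin (higher = late).
#' @export
classifier_svm_linear <- function(cost = 1) {
  new_classifier(
    name = "SVM",
    fit = function(x, y) e1071::svm(x, y, kernel = "linear", cost = cost,
                                    scale = FALSE),
    score = function(model, x) {
      dv <- attr(stats::predict(model, x, decision.values = TRUE),
                 "decision.values")
      # libsvm orients the decision value toward the first training label
      if (startsWith(colnames(dv)[1], "late")) dv[, 1] else -dv[, 1]
    },
    type = "margin")
}

#' Random forest classifier
#' @param ntree number of trees.
#' @return a `stage_classifier` scoring by the late-stage vote fraction.
#' @export
classifier_rf <- function(ntree = 200L) {
  new_classifier(
    name = "RF",
    fit = function(x, y) randomForest::randomForest(x, y, ntree = ntree),
    score = function(model, x)
      unname(stats::predict(model, x, type = "prob")[, "late"]),
    type = "prob")
}

#' Gaussian naive Bayes classifier
#' @return a `stage_classifier` scoring by the late-stage posterior.
#' @export
classifier_nb <- function() {
  new_classifier(
    name = "NB",
    fit = function(x, y) e1071::naiveBayes(x, y),
    score = function(model, x)
      unname(stats::predict(model, x, type = "raw")[, "late"]),
    type = "prob")
}

#' k-nearest-neighbour classifier
#'
#' Lazy learner: `fit` stores the training data, `score` runs `class::knn`
#' with `use.all = TRUE` (all tied neighbours used, no random tie sampling)
#' and returns the fraction of neighbours voting late.
#'
#' @param k neighbourhood size (odd values avoid vote ties).
#' @return a `stage_classifier`.
#' @export
classifier_knn <- function(k = 5L) {
  new_classifier(
    name = "KNN",
    fit = function(x, y) list(x = x, y = y),
    score = function(model, x) {
      pred <- class::knn(model$x, x, model$y, k = k, prob = TRUE, use.all = TRUE)
      pr <- attr(pred, "prob")
      ifelse(pred == "late", pr, 1 - pr)
    },
    type = "prob")
}

#' Default evaluation roster
#'
#' SVM, KNN, NB and RF — the standard supervised panel for checking the
#' discriminative power of a selected transcript set.
#'
#' @return named list of `stage_classifier` objects.
#' @export
default_classifier_roster <- function() {
  list(SVM = classifier_svm_linear(), KNN = classifier_knn(),
       NB = classifier_nb(), RF = classifier_rf())
}
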