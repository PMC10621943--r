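#' Build a nested cross-validation fold plan
#'
#' Outer folds estimate generalization; inner folds (drawn from each outer
#' fold's training samples) drive feature selection and model tuning so that
#' outer test samples never influence any fitted quantity. Splitting is
#' stratified by stage by default: per-class counts per fold differ by at most
#' one, and class remainders are spread so total fold sizes also differ by at
#' most one.
#'
#' @param stage_labels per-sample stage labels ("early"/"late").
#' @param k_outer,k_inner fold counts for the outer and inner loops.
#' @param seed integer seed for the shuffles.
#' @param stratified stratify fold assignment by stage (default `TRUE`).
#' @return a `nested_fold_plan`: `outer` is a list of `k_outer` test-index
#'   vectors; `inner[[i]]` is a list of `k_inner` validation-index vectors
#'   partitioning outer fold `i`'s training samples.
#' @export
build_nested_folds <- function(stage_labels, k_outer = 10L, k_inner = 5L,
                               seed = 1L, stratified = TRUE) {
  y <- as_stage_factor(stage_labels)
  n <- length(y)
  check_that(is_count(k_outer, 2L) && is_count(k_inner, 2L),
             "k_outer and k_inner must be integers >= 2")
  check_that(n >= k_outer, sprintf("cannot split %d samples into %d outer folds", n, k_outer))
  check_that(length(unique(y)) == 2L, "both stage classes must be present")
  if (stratified)
    check_that(min(table(y)) >= k_outer,
               "each class needs at least k_outer samples for stratified splitting")

  with_seed(seed, {
    outer <- partition_folds(seq_len(n), y, k_outer, stratified)
    inner <- lapply(outer, function(test_idx) {
      tr <- setdiff(seq_len(n), test_idx)
      partition_folds(tr, y[tr], k_inner, stratified)
    })
    structure(list(k_outer = as.integer(k_outer), k_inner = as.integer(k_inner),
                   n = n, outer = outer, inner = inner, seed = as.integer(seed),
                   stratified = stratified),
              class = "nested_fold_plan")
  })
}

# split `idx` into k disjoint folds; per-class extras go to the folds with the
# smallest running totals so overall fold sizes stay within +/-1
partition_folds <- function(idx, y, k, stratified) {
  sizes <- integer(k)
  folds <- vector("list", k)
  groups <- if (stratified) split(idx, droplevels(factor(y))) else list(all = idx)
  for (g in groups) {
    g <- g[sample.int(length(g))]
    base <- length(g) %/% k
    extra <- length(g) - base * k
    cnt <- rep(base, k)
    if (extra > 0) {
      take <- order(sizes, seq_len(k))[seq_len(extra)]
      cnt[take] <- cnt[take] + 1L
    }
    fold_id <- rep.int(seq_len(k), cnt)
    pieces <- split(g, fold_id)
    for (f in names(pieces)) {
      fi <- as.integer(f)
      folds[[fi]] <- c(folds[[fi]], pieces[[f]])
    }
    sizes <- sizes + cnt
  }
  lapply(folds, sort)
}

#' Training indices for an outer fold
#' @param plan a `nested_fold_plan`.
#' @param i outer fold index.
#' @return integer sample indices.
#' @export
outer_train_idx <- function(plan, i) {
  setdiff(seq_len(plan$n), plan$outer[[i]])
}

#' Training indices for an inner partition
#'
#' The inner training set of partition (i, j) is outer fold i's training set
#' minus inner validation fold j.
#'
#' @param plan a `nested_fold_plan`.
#' @param i outer fold index.
#' @param j inner fold index.
#' @return integer sample indices.
#' @export
inner_train_idx <- function(plan, i, j) {
  setdiff(outer_train_idx(plan, i), plan$inner[[i]][[j]])
}

#' @export
print.nested_fold_plan <- function(x, ...) {
  cat(sprintf("<nested_fold_plan> %d samples, %d outer x %d inner folds (%s, seed %d)\n",
              x$n, x$k_outer, x$k_inner,
              if (x$stratified) "stratified" else "unstratified", x$seed))
  invisible(x)
}
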