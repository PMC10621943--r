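#' Rank features by a per-feature Welch t-test on training rows
#'
#' Computes the unequal-variance two-sample statistic (late minus early) and
#' two-sided p-value for every feature, vectorized across columns. Features
#' that are constant with equal group means score t = 0, p = 1. Output is
#' sorted by (p ascending, |t| descending, feature id ascending) so top-k
#' selection is reproducible across platforms.
#'
#' @param values numeric samples x features matrix.
#' @param stage_labels per-sample stage labels.
#' @param train_idx training row indices; both classes must be present.
#' @return a data.frame (`feature_scores`) with columns `feature_id`, `t`, `p`.
#' @export
ttest_rank <- function(values, stage_labels, train_idx) {
  y <- as_stage_factor(stage_labels)[train_idx]
  check_that(length(unique(y)) == 2L,
             "both stage classes must be present in the training rows")
  x <- values[train_idx, , drop = FALSE]
  g1 <- x[y == "early", , drop = FALSE]
  g2 <- x[y == "late", , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2)
  m1 <- colMeans(g1); m2 <- colMeans(g2)
  v1 <- colSums((g1 - rep(m1, each = n1))^2) / (n1 - 1)
  v2 <- colSums((g2 - rep(m2, each = n2))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  diff <- m2 - m1
  t <- diff / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate columns: zero variance in both groups
  zero <- se2 == 0
  if (any(zero)) {
    t[zero] <- ifelse(diff[zero] == 0, 0, sign(diff[zero]) * Inf)
    p[zero] <- ifelse(diff[zero] == 0, 1, 0)
  }
  fid <- colnames(values) %||% as.character(seq_len(ncol(values)))
  ord <- order(p, -abs(t), fid)
  structure(data.frame(feature_id = fid[ord], t = t[ord], p = p[ord],
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("feature_scores", "data.frame"))
}

#' Take the top-k features from a score table
#'
#' @param scores a `feature_scores` data.frame from [ttest_rank()].
#' @param k number of features to keep (>= 1). When fewer than `k` features
#'   are available all are returned with a warning.
#' @return character vector of feature ids.
#' @export
select_top_k <- function(scores, k) {
  check_that(is.data.frame(scores) && nrow(scores) >= 1L,
             "`scores` must be a non-empty score table")
  check_that(is_count(k, 1L), "`k` must be an integer >= 1")
  if (k > nrow(scores)) {
    warning(sprintf("requested top %d of %d scored features; returning all",
                    k, nrow(scores)), call. = FALSE)
    k <- nrow(scores)
  }
  scores$feature_id[seq_len(k)]
}

#' Pool top-k filter selections across all inner training partitions
#'
#' Runs [ttest_rank()] + [select_top_k()] once per inner training partition
#' (`k_outer * k_inner` runs). Within each outer fold, constant-feature masks
#' are computed per inner training fold and intersected, so a feature constant
#' on any inner training fold of that outer fold is excluded there. The
#' returned pool is the union of all selections with per-feature selection
#' counts.
#'
#' @param em an [expression_matrix()].
#' @param plan a [build_nested_folds()] plan.
#' @param k_top features kept per partition (default 15).
#' @param scope `"global"` (one pooled list, default) or `"per_outer"`
#'   (a list of pools, one per outer fold).
#' @return a `candidate_pool` data.frame with `feature_id` and `count`
#'   (number of inner partitions selecting the feature), sorted by count
#'   descending then id; or a list of such pools when `scope = "per_outer"`.
#' @export
pool_candidates <- function(em, plan, k_top = 15L, scope = c("global", "per_outer")) {
  scope <- match.arg(scope)
  check_that(inherits(em, "expr_matrix"), "`em` must be an expr_matrix")
  check_that(inherits(plan, "nested_fold_plan"), "`plan` must be a nested_fold_plan")
  values <- em$values
  pools <- vector("list", plan$k_outer)
  for (i in seq_len(plan$k_outer)) {
    masks <- lapply(seq_len(plan$k_inner), function(j)
      remove_constant_features(values, inner_train_idx(plan, i, j)))
    keep <- Reduce(`&`, masks)
    sub <- values[, keep, drop = FALSE]
    counts <- integer(0)
    for (j in seq_len(plan$k_inner)) {
      tr <- inner_train_idx(plan, i, j)
      ids <- select_top_k(ttest_rank(sub, em$stage, tr), k_top)
      hit <- ids %in% names(counts)
      counts[ids[hit]] <- counts[ids[hit]] + 1L
      counts <- c(counts, stats::setNames(rep(1L, sum(!hit)), ids[!hit]))
    }
    pools[[i]] <- counts
  }
  if (scope == "per_outer") return(lapply(pools, as_candidate_pool, k_top = k_top))
  total <- integer(0)
  for (cnt in pools) {
    hit <- names(cnt) %in% names(total)
    total[names(cnt)[hit]] <- total[names(cnt)[hit]] + cnt[hit]
    total <- c(total, cnt[!hit])
  }
  as_candidate_pool(total, k_top = k_top)
}

as_candidate_pool <- function(counts, k_top) {
  ord <- order(-counts, names(counts))
  structure(data.frame(feature_id = names(counts)[ord],
                       count = unname(counts[ord]),
                       row.names = NULL, stringsAsFactors = FALSE),
            k_top = k_top, class = c("candidate_pool", "data.frame"))
}
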