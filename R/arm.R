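#' Association-rule-mining configuration
#'
#' Defaults are the workflow's published thresholds: minimum support 0.3,
#' maximum frequent-itemset length 4 (antecedent plus consequent), minimum
#' lift 1.1. All thresholds are inclusive (kept when the value is no less
#' than the threshold). `min_confidence` defaults to 0 — support, length and
#' lift are the operative filters.
#'
#' @param min_support minimum itemset support in (0, 1].
#' @param max_len maximum itemset length (>= 2).
#' @param min_lift minimum rule lift (>= 0).
#' @param min_confidence minimum rule confidence in [0, 1].
#' @return an `arm_config` list.
#' @export
arm_config <- function(min_support = 0.3, max_len = 4L, min_lift = 1.1,
                       min_confidence = 0) {
  check_that(is_prob(min_support) && min_support > 0, "min_support must be in (0,1]")
  check_that(is_count(max_len, 2L), "max_len must be an integer >= 2")
  check_that(is.numeric(min_lift) && min_lift >= 0, "min_lift must be >= 0")
  check_that(is_prob(min_confidence), "min_confidence must be in [0,1]")
  structure(list(min_support = min_support, max_len = as.integer(max_len),
                 min_lift = min_lift, min_confidence = min_confidence),
            class = "arm_config")
}

#' Discretize min-max-scaled expression into equal-frequency tertiles
#'
#' Per feature, samples are split on average ranks: the lowest third of ranks
#' becomes `low`, the middle `medium`, the top `high`. Rank-based cuts make
#' the assignment invariant to monotone transforms and deterministic under
#' ties (a tie group shares one average rank, so it lands on one side of a
#' cut as a whole).
#'
#' @param values numeric samples x features matrix (e.g. from
#'   [minmax_scale()]); no constant features.
#' @return character matrix of levels `low`/`medium`/`high`, same dimnames.
#' @export
discretize_tertiles <- function(values) {
  check_that(is.matrix(values) && is.numeric(values), "`values` must be numeric")
  n <- nrow(values)
  check_that(n >= 3L, "need at least 3 samples for tertiles")
  out <- matrix(NA_character_, n, ncol(values), dimnames = dimnames(values))
  for (jcol in seq_len(ncol(values))) {
    x <- values[, jcol]
    if (max(x) == min(x))
      stop(sprintf("feature %s is constant; remove constant features first",
                   colnames(values)[jcol] %||% jcol), call. = FALSE)
    r <- rank(x, ties.method = "average")
    lev <- ifelse(r <= n / 3, "low", ifelse(r > 2 * n / 3, "high", "medium"))
    out[, jcol] <- lev
  }
  out
}

#' Encode discretized expression plus stage labels as transactions
#'
#' One transaction per sample: one `feature=level` item per feature plus a
#' single `stage=early`/`stage=late` item. The alphabet is the full grid of
#' 3 x features level items plus the two stage items.
#'
#' @param levels character level matrix from [discretize_tertiles()].
#' @param stage_labels per-sample stage labels aligned with the rows.
#' @return a `transaction_set`.
#' @export
build_transactions <- function(levels, stage_labels) {
  check_that(is.matrix(levels) && is.character(levels),
             "`levels` must be a character matrix")
  check_that(length(stage_labels) == nrow(levels),
             "need one stage label per sample row")
  y <- as_stage_factor(stage_labels)
  feats <- colnames(levels) %||% sprintf("G%06d", seq_len(ncol(levels)))
  tx <- lapply(seq_len(nrow(levels)), function(i)
    c(paste0(feats, "=", levels[i, ]), paste0("stage=", y[i])))
  alphabet <- c(as.vector(outer(feats, c("low", "medium", "high"),
                                function(f, l) paste0(f, "=", l))),
                paste0("stage=", STAGE_LEVELS))
  new_transaction_set(tx, sort(alphabet))
}

#' Generate association rules from frequent itemsets
#'
#' Every bipartition of each frequent itemset of size >= 2 into a non-empty
#' antecedent and consequent is scored on exact transaction counts:
#' confidence = count(A and C)/count(A), lift = confidence/support(C). Rules
#' are kept when confidence >= `min_confidence` and lift >= `min_lift`
#' (inclusive, to within floating-point tolerance). Because every subset of a
#' frequent itemset is frequent and within `max_len`, all needed counts come
#' from the itemset table itself.
#'
#' @param itemsets a `frequent_itemsets` table mined at the same
#'   `min_support`/`max_len`.
#' @param tx the `transaction_set` the itemsets were mined from.
#' @param config an [arm_config()].
#' @return an `assoc_rules` data.frame: list-columns `antecedent` and
#'   `consequent`, display strings `lhs`/`rhs`, and `support`, `confidence`,
#'   `lift`, `count`; alphabet and transaction count kept as attributes.
#' @export
rules_from_itemsets <- function(itemsets, tx, config) {
  check_that(inherits(itemsets, "frequent_itemsets"),
             "`itemsets` must come from an itemset miner")
  n <- attr(itemsets, "n_transactions")
  check_that(identical(n, tx$n_transactions),
             "itemsets and transactions disagree on the number of transactions")
  count_of <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(itemsets)))
    count_of[[paste(itemsets$items[[i]], collapse = "\x1f")]] <- itemsets$count[i]

  eps <- 1e-9
  rules <- list()
  big <- which(itemsets$size >= 2L)
  for (i in big) {
    items <- itemsets$items[[i]]
    n_full <- itemsets$count[i]
    sz <- length(items)
    for (a_sz in seq_len(sz - 1L)) {
      combos <- utils::combn(sz, a_sz)
      for (c_i in seq_len(ncol(combos))) {
        A <- items[combos[, c_i]]
        C <- items[-combos[, c_i]]
        n_a <- count_of[[paste(A, collapse = "\x1f")]]
        n_c <- count_of[[paste(C, collapse = "\x1f")]]
        conf <- n_full / n_a
        lift <- (n_full * n) / (n_a * n_c)
        if (conf >= config$min_confidence - eps && lift >= config$min_lift - eps)
          rules[[length(rules) + 1L]] <- list(
            antecedent = A, consequent = C, count = n_full,
            support = n_full / n, confidence = conf, lift = lift)
      }
    }
  }
  as_assoc_rules(rules, n, tx$alphabet)
}

as_assoc_rules <- function(rules, n, alphabet) {
  if (length(rules) == 0L) {
    df <- data.frame(lhs = character(0), rhs = character(0),
                     support = numeric(0), confidence = numeric(0),
                     lift = numeric(0), count = numeric(0),
                     stringsAsFactors = FALSE)
    df$antecedent <- list()
    df$consequent <- list()
  } else {
    lhs <- vapply(rules, function(r) paste(r$antecedent, collapse = " & "),
                  character(1))
    rhs <- vapply(rules, function(r) paste(r$consequent, collapse = " & "),
                  character(1))
    ord <- order(lhs, rhs)
    df <- data.frame(
      lhs = lhs[ord], rhs = rhs[ord],
      support = vapply(rules, `[[`, numeric(1), "support")[ord],
      confidence = vapply(rules, `[[`, numeric(1), "confidence")[ord],
      lift = vapply(rules, `[[`, numeric(1), "lift")[ord],
      count = vapply(rules, `[[`, numeric(1), "count")[ord],
      stringsAsFactors = FALSE)
    df$antecedent <- lapply(rules, `[[`, "antecedent")[ord]
    df$consequent <- lapply(rules, `[[`, "consequent")[ord]
  }
  structure(df, n_transactions = n, alphabet = alphabet,
            class = c("assoc_rules", "data.frame"))
}

#' Mine association rules from a transaction set
#'
#' Convenience wrapper: [fpgrowth_frequent_itemsets()] followed by
#' [rules_from_itemsets()].
#'
#' @param tx a `transaction_set`.
#' @param config an [arm_config()].
#' @return an `assoc_rules` data.frame.
#' @export
mine_rules <- function(tx, config = arm_config()) {
  rules_from_itemsets(fpgrowth_frequent_itemsets(tx, config), tx, config)
}
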