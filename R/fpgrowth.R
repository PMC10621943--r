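# Frequent-itemset mining: FP-Growth and its brute-force oracle.

new_transaction_set <- function(transactions, alphabet) {
  check_that(is.list(transactions), "transactions must be a list of item vectors")
  check_that(length(alphabet) > 0 && !anyDuplicated(alphabet),
             "alphabet must be non-empty and unique")
  transactions <- lapply(transactions, function(t) sort(unique(as.character(t))))
  extra <- setdiff(unique(unlist(transactions)), alphabet)
  check_that(length(extra) == 0,
             sprintf("transaction items outside the alphabet: %s",
                     paste(utils::head(extra, 3), collapse = ", ")))
  structure(list(transactions = transactions, alphabet = alphabet,
                 n_transactions = length(transactions)),
            class = "transaction_set")
}

#' @export
print.transaction_set <- function(x, ...) {
  cat(sprintf("<transaction_set> %d transactions over %d items\n",
              x$n_transactions, length(x$alphabet)))
  invisible(x)
}

# smallest integer count c with c/n >= min_support
min_count_for <- function(min_support, n) max(1L, as.integer(ceiling(min_support * n - 1e-9)))

#' Mine frequent itemsets with FP-Growth
#'
#' Builds an FP-tree over support-ordered items (global support descending,
#' item name ascending for ties) and mines it by recursive conditional
#' pattern bases. Returns exactly the itemsets with support >= `min_support`
#' and size <= `max_len`, each with its exact support, in canonical order
#' (size ascending, then lexicographic).
#'
#' @param tx a `transaction_set`.
#' @param config an [arm_config()] (only `min_support` and `max_len` used).
#' @return a `frequent_itemsets` data.frame: list-column `items`, plus
#'   `itemset` (display string), `size`, `count`, `support`; the number of
#'   transactions is kept in attribute `n_transactions`.
#' @export
fpgrowth_frequent_itemsets <- function(tx, config) {
  check_that(inherits(tx, "transaction_set"), "`tx` must be a transaction_set")
  check_that(tx$n_transactions > 0, "transaction set is empty")
  check_that(is_prob(config$min_support, 0, 1) && config$min_support > 0,
             "min_support must be in (0, 1]")
  n <- tx$n_transactions
  min_count <- min_count_for(config$min_support, n)

  # global frequent items, support-ordered
  all_items <- unlist(tx$transactions, use.names = FALSE)
  counts <- table(factor(all_items, levels = sort(unique(all_items))))
  freq_items <- names(counts)[counts >= min_count]
  if (length(freq_items) == 0L)
    return(as_frequent_itemsets(list(), n))
  ord <- order(-as.integer(counts[freq_items]), freq_items)
  freq_items <- freq_items[ord]                 # rank 1 = most frequent
  rank_of <- stats::setNames(seq_along(freq_items), freq_items)

  # encode transactions as integer rank vectors, most frequent first
  enc <- lapply(tx$transactions, function(t) {
    r <- rank_of[t[t %in% freq_items]]
    sort(unname(r))
  })
  enc <- enc[lengths(enc) > 0L]
  found <- fpg_mine(enc, rep(1, length(enc)), integer(0), min_count,
                    config$max_len)
  found <- lapply(found, function(f) {
    f$items <- sort(freq_items[f$item_ranks])
    f$item_ranks <- NULL
    f
  })
  as_frequent_itemsets(found, n)
}

# one FP-Growth recursion level: build the tree for this (conditional)
# pattern base, then mine each item's conditional base, least frequent first
fpg_mine <- function(paths, weights, suffix_ranks, min_count, max_len) {
  if (length(paths) == 0L || length(suffix_ranks) >= max_len) return(list())
  # conditional item counts
  wc <- tapply(rep(weights, lengths(paths)), unlist(paths), sum)
  items <- as.integer(names(wc))[wc >= min_count]
  if (length(items) == 0L) return(list())
  keep <- sort(items)  # rank order = global support order

  tree <- fptree_build(paths, weights, keep)
  out <- list()
  for (a in rev(keep)) {
    nodes <- which(tree$item == a)
    cnt <- sum(tree$cnt[nodes])
    itemset <- c(a, suffix_ranks)
    out[[length(out) + 1L]] <- list(item_ranks = itemset, count = cnt)
    if (length(itemset) < max_len) {
      base <- vector("list", length(nodes))
      bw <- numeric(length(nodes))
      for (k in seq_along(nodes)) {
        path <- integer(0)
        cur <- tree$parent[nodes[k]]
        while (cur > 0L) {
          path <- c(tree$item[cur], path)
          cur <- tree$parent[cur]
        }
        base[[k]] <- path
        bw[k] <- tree$cnt[nodes[k]]
      }
      nonempty <- lengths(base) > 0L
      out <- c(out, fpg_mine(base[nonempty], bw[nonempty], itemset,
                             min_count, max_len))
    }
  }
  out
}

# prefix-tree over support-ordered transactions; nodes as parallel vectors,
# child lookup through a hashed environment keyed parent.item
fptree_build <- function(paths, weights, keep) {
  parent <- integer(0); item <- integer(0); cnt <- numeric(0)
  children <- new.env(hash = TRUE, parent = emptyenv())
  for (t in seq_along(paths)) {
    p <- paths[[t]]
    p <- p[p %in% keep]
    cur <- 0L
    for (it in p) {
      key <- paste0(cur, ".", it)
      nd <- children[[key]]
      if (is.null(nd)) {
        parent <- c(parent, cur); item <- c(item, it); cnt <- c(cnt, 0)
        nd <- length(item)
        children[[key]] <- nd
      }
      cnt[nd] <- cnt[nd] + weights[t]
      cur <- nd
    }
  }
  list(parent = parent, item = item, cnt = cnt)
}

as_frequent_itemsets <- function(found, n) {
  if (length(found) == 0L) {
    df <- data.frame(itemset = character(0), size = integer(0),
                     count = numeric(0), support = numeric(0),
                     stringsAsFactors = FALSE)
    df$items <- list()
  } else {
    items <- lapply(found, `[[`, "items")
    keys <- vapply(items, paste, character(1), collapse = "\x1f")
    sizes <- lengths(items)
    ord <- order(sizes, keys)
    df <- data.frame(
      itemset = vapply(items, paste, character(1), collapse = " & ")[ord],
      size = sizes[ord],
      count = vapply(found, `[[`, numeric(1), "count")[ord],
      stringsAsFactors = FALSE)
    df$support <- df$count / n
    df$items <- items[ord]
  }
  structure(df, n_transactions = n,
            class = c("frequent_itemsets", "data.frame"))
}

#' Brute-force frequent-itemset oracle
#'
#' Exhaustive level-wise enumeration of every itemset over the alphabet up to
#' `max_len`, counting supports by direct scan. Guarded to alphabets of at
#' most 20 items; intended as an independent oracle for
#' [fpgrowth_frequent_itemsets()], with an identical output contract.
#'
#' @inheritParams fpgrowth_frequent_itemsets
#' @return a `frequent_itemsets` data.frame.
#' @export
bruteforce_frequent_itemsets <- function(tx, config) {
  check_that(inherits(tx, "transaction_set"), "`tx` must be a transaction_set")
  check_that(length(tx$alphabet) <= 20L,
             "brute-force oracle is guarded to alphabets of <= 20 items")
  check_that(is_prob(config$min_support, 0, 1) && config$min_support > 0,
             "min_support must be in (0, 1]")
  n <- tx$n_transactions
  min_count <- min_count_for(config$min_support, n)
  alpha <- sort(tx$alphabet)
  # incidence matrix
  inc <- vapply(alpha, function(a)
    vapply(tx$transactions, function(t) a %in% t, logical(1)),
    logical(n))
  if (n == 1L) inc <- matrix(inc, nrow = 1, dimnames = list(NULL, alpha))
  found <- list()
  for (sz in seq_len(min(config$max_len, length(alpha)))) {
    combos <- utils::combn(length(alpha), sz)
    for (c_i in seq_len(ncol(combos))) {
      cols <- combos[, c_i]
      cnt <- sum(rowSums(inc[, cols, drop = FALSE]) == sz)
      if (cnt >= min_count)
        found[[length(found) + 1L]] <- list(items = alpha[cols], count = cnt)
    }
  }
  as_frequent_itemsets(found, n)
}
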