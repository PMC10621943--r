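#' Configuration for planted-rule transaction sets
#'
#' Direct fixtures for the rule-mining stage: each planted rule
#' `A => c` is emitted so that, as the number of transactions grows, the
#' empirical support of `A union {c}` approaches `target_support` and the
#' empirical confidence P(c | A) approaches `target_confidence`
#' (the antecedent is planted with probability support/confidence, then the
#' consequent with probability confidence). Items not involved in any planted
#' rule appear independently with `background_item_prob`.
#'
#' @param n_transactions number of transactions to emit.
#' @param item_alphabet character vector of item names (non-empty).
#' @param planted_rules list of rules, each a list with `antecedent`
#'   (character), `consequent` (single item), `confidence` in (0,1],
#'   `support` in (0,1] with support <= confidence.
#' @param background_item_prob inclusion probability for background items.
#' @param seed integer seed.
#' @return a `transaction_config` list.
#' @export
transaction_config <- function(n_transactions, item_alphabet,
                               planted_rules = list(),
                               background_item_prob = 0.1, seed = 1L) {
  check_that(is_count(n_transactions, 1L), "n_transactions must be >= 1")
  check_that(is.character(item_alphabet) && length(item_alphabet) > 0,
             "item_alphabet must be a non-empty character vector")
  check_that(!anyDuplicated(item_alphabet), "item_alphabet must be unique")
  check_that(is_prob(background_item_prob), "background_item_prob must be in [0,1]")
  for (r in planted_rules) {
    check_that(is.list(r) && all(c("antecedent", "consequent", "confidence",
                                   "support") %in% names(r)),
               "each planted rule needs antecedent/consequent/confidence/support")
    check_that(length(r$consequent) == 1L, "planted consequent must be one item")
    check_that(!r$consequent %in% r$antecedent,
               "planted antecedent and consequent must be disjoint")
    check_that(all(c(r$antecedent, r$consequent) %in% item_alphabet),
               "planted rule items must be in the alphabet")
    check_that(is_prob(r$confidence) && r$confidence > 0,
               "target confidence must be in (0,1]")
    check_that(is_prob(r$support) && r$support > 0,
               "target support must be in (0,1]")
    check_that(r$support <= r$confidence,
               "target support must not exceed target confidence (P(A) <= 1)")
  }
  structure(list(n_transactions = as.integer(n_transactions),
                 item_alphabet = item_alphabet,
                 planted_rules = planted_rules,
                 background_item_prob = background_item_prob,
                 seed = as.integer(seed)),
            class = "transaction_config")
}

#' Generate a transaction set with planted association rules
#'
#' @param config a [transaction_config()].
#' @return a list with `transactions` (a `transaction_set`) and
#'   `planted` (the rule list from the config).
#' @export
generate_planted_transactions <- function(config) {
  check_that(inherits(config, "transaction_config"),
             "`config` must be a transaction_config")
  planted_items <- unique(unlist(lapply(config$planted_rules, function(r)
    c(r$antecedent, r$consequent))))
  background <- setdiff(config$item_alphabet, planted_items)
  n <- config$n_transactions

  with_seed(config$seed, {
    tx <- vector("list", n)
    for (i in seq_len(n)) {
      items <- character(0)
      for (r in config$planted_rules) {
        if (stats::runif(1) < r$support / r$confidence) {
          items <- c(items, r$antecedent)
          if (stats::runif(1) < r$confidence) items <- c(items, r$consequent)
        }
      }
      if (length(background)) {
        keep <- stats::runif(length(background)) < config$background_item_prob
        items <- c(items, background[keep])
      }
      tx[[i]] <- sort(unique(items))
    }
    list(transactions = new_transaction_set(tx, config$item_alphabet),
         planted = config$planted_rules)
  })
}
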