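# shared fixture builders; everything is generated in code, seeded

small_cohort <- function(seed = 7, n_early = 80, n_late = 40, n_features = 300,
                         n_informative = 8, effect_size = 2.5, n_constant = 3,
                         block_spec = list(c(4, 0.9))) {
  generate_cohort(cohort_config(
    n_early = n_early, n_late = n_late, n_features = n_features,
    n_informative = n_informative, effect_size = effect_size,
    n_constant = n_constant, block_spec = block_spec, seed = seed))
}

# random transaction set over the first K letters
random_tx <- function(K, n) {
  alpha <- LETTERS[seq_len(K)]
  tx <- lapply(seq_len(n), function(i) sample(alpha, sample(0:K, 1)))
  stagemine:::new_transaction_set(tx, alpha)
}

# the 5-transaction worked example used across the ARM tests
worked_tx <- function() {
  stagemine:::new_transaction_set(
    list(c("A", "B", "e"), c("A", "B", "e"), c("A", "l"),
         c("B", "e"), c("A", "B", "l")),
    c("A", "B", "e", "l"))
}

# canonical comparable signature of an itemset table
itemset_key <- function(fi) {
  sort(paste(vapply(fi$items, paste, character(1), collapse = "|"),
             fi$count, sep = "#"))
}

# construct a score/label vector with an exact AUC of `target` (granularity
# 1/(n1*n0)): `wins` of the n1*n0 positive-negative pairs are won
auc_fixture <- function(target, n1 = 10, n0 = 10) {
  wins <- round(target * n1 * n0)
  full <- wins %/% n0          # positives above every negative
  part <- wins %% n0           # one positive above exactly `part` negatives
  neg <- seq_len(n0)
  pos <- c(rep(n0 + 1, full), rep(0, n1 - full))
  if (part > 0) pos[full + 1] <- part + 0.5
  list(scores = c(pos, neg),
       labels = c(rep("late", n1), rep("early", n0)))
}

# independent pairwise AUC (enumeration oracle)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == "late"]
  neg <- scores[labels == "early"]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# iterative-peeling front oracle, independent of the Deb-style implementation
fronts_bruteforce <- function(obj) {
  remaining <- seq_len(nrow(obj))
  fronts <- list()
  while (length(remaining)) {
    nd <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) {
        if (i == j) return(FALSE)
        all(obj[j, ] <= obj[i, ]) && any(obj[j, ] < obj[i, ])
      }, logical(1)))
    }, logical(1))]
    fronts[[length(fronts) + 1L]] <- sort(nd)
    remaining <- setdiff(remaining, nd)
  }
  fronts
}
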