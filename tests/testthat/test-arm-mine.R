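test_that("tertile discretization is balanced, deterministic and rank-based", {
  v <- matrix(c(9, 3, 7, 1, 5, 8, 2, 6, 4), 9, 1, dimnames = list(NULL, "G1"))
  lev <- discretize_tertiles(v)
  expect_equal(sum(lev == "low"), 3)
  expect_equal(sum(lev == "medium"), 3)
  expect_equal(sum(lev == "high"), 3)
  expect_identical(lev[v[, 1] <= 3], rep("low", 3))
  # monotone transform leaves the assignment unchanged
  expect_identical(discretize_tertiles(sqrt(v)), lev)
  # a tie group straddling a cut moves as one block, deterministically
  vt <- matrix(c(1, 1, 1, 1, 2, 3, 4, 5, 6), 9, 1)
  lt <- discretize_tertiles(vt)
  expect_identical(lt[1:4], rep("low", 4))
  expect_identical(discretize_tertiles(vt), lt)
  expect_error(discretize_tertiles(matrix(2, 5, 1)), "constant")
})

test_that("transactions carry one level item per feature plus one stage item", {
  set.seed(4)
  v <- matrix(runif(60), 12, 5, dimnames = list(NULL, paste0("G", 1:5)))
  y <- rep(c("early", "late"), each = 6)
  tx <- build_transactions(discretize_tertiles(v), y)
  expect_equal(tx$n_transactions, 12)
  expect_true(all(lengths(tx$transactions) == 6))   # 5 features + 1 stage
  expect_length(tx$alphabet, 3 * 5 + 2)
  for (t in tx$transactions) {
    expect_equal(sum(startsWith(t, "stage=")), 1)
    feats <- sub("=.*$", "", t[!startsWith(t, "stage=")])
    expect_false(anyDuplicated(feats) > 0)
  }
})

test_that("FP-Growth reproduces exact supports on the worked transaction set", {
  fi <- fpgrowth_frequent_itemsets(worked_tx(),
                                   arm_config(min_support = 0.3, max_len = 4))
  ab <- fi[fi$itemset == "A & B", ]
  expect_equal(ab$support, 3 / 5)
  expect_equal(ab$count, 3)
  # min_support = 1 keeps only items present everywhere
  all_tx <- stagemine:::new_transaction_set(
    list(c("A", "B"), c("A", "C"), c("A", "B", "C")), c("A", "B", "C"))
  fi1 <- fpgrowth_frequent_itemsets(all_tx, arm_config(min_support = 1))
  expect_identical(fi1$itemset, "A")
  # max_len caps itemset size
  fi2 <- fpgrowth_frequent_itemsets(worked_tx(),
                                    arm_config(min_support = 0.2, max_len = 2))
  expect_true(all(fi2$size <= 2))
  expect_true(any(fi2$size == 2))
})

test_that("FP-Growth equals the brute-force oracle on random transaction sets", {
  set.seed(19)
  for (rep in 1:30) {
    tx <- random_tx(K = sample(3:10, 1), n = sample(5:40, 1))
    cfg <- arm_config(min_support = sample(c(0.1, 0.3, 0.5), 1),
                      max_len = sample(2:4, 1))
    expect_identical(itemset_key(fpgrowth_frequent_itemsets(tx, cfg)),
                     itemset_key(bruteforce_frequent_itemsets(tx, cfg)))
  }
  expect_error(bruteforce_frequent_itemsets(random_tx(5, 5),
                                            structure(list(min_support = 2, max_len = 3),
                                                      class = "arm_config")),
               "min_support")
})

test_that("oracle supports are exact multiples of 1/n and anti-monotone", {
  set.seed(23)
  tx <- random_tx(8, 30)
  cfg <- arm_config(min_support = 0.2, max_len = 3)
  fi <- fpgrowth_frequent_itemsets(tx, cfg)
  expect_true(all(abs(fi$support * 30 - round(fi$support * 30)) < 1e-12))
  keys <- vapply(fi$items, paste, character(1), collapse = "\x1f")
  sup <- setNames(fi$support, keys)
  for (i in which(fi$size >= 2)) {
    items <- fi$items[[i]]
    for (drop in seq_along(items)) {
      sub_key <- paste(items[-drop], collapse = "\x1f")
      expect_true(sub_key %in% keys)              # every subset is frequent
      expect_gte(sup[[sub_key]], fi$support[i])   # support anti-monotone
    }
  }
})

test_that("rule generation applies exact counts and inclusive thresholds", {
  tx <- worked_tx()
  cfg <- arm_config(min_support = 0.3, max_len = 4, min_lift = 1.1)
  rules <- mine_rules(tx, cfg)
  r <- rules[rules$lhs == "A & B" & rules$rhs == "e", ]
  expect_equal(nrow(r), 1)
  expect_equal(r$support, 2 / 5, tolerance = 1e-12)
  expect_equal(r$confidence, 2 / 3, tolerance = 1e-12)
  expect_equal(r$lift, 10 / 9, tolerance = 1e-12)
  # lift exactly 1.0 is excluded at min_lift 1.1
  all_rules <- mine_rules(tx, arm_config(min_support = 0.2, max_len = 4,
                                         min_lift = 0))
  unit <- all_rules[abs(all_rules$lift - 1) < 1e-12, ]
  kept <- mine_rules(tx, cfg)
  if (nrow(unit) > 0)
    expect_false(any(paste(unit$lhs, unit$rhs) %in% paste(kept$lhs, kept$rhs)))
  # a consequent present in every transaction makes lift equal confidence
  tx2 <- stagemine:::new_transaction_set(
    list(c("A", "E"), c("A", "E"), c("B", "E")), c("A", "B", "E"))
  r2 <- mine_rules(tx2, arm_config(min_support = 0.3, max_len = 3, min_lift = 0))
  to_e <- r2[r2$rhs == "E", ]
  expect_true(nrow(to_e) > 0)
  expect_equal(to_e$lift, to_e$confidence, tolerance = 1e-12)
})

test_that("rule identities hold on mined random sets", {
  set.seed(29)
  tx <- random_tx(7, 40)
  rules <- mine_rules(tx, arm_config(min_support = 0.15, max_len = 3, min_lift = 0))
  expect_gt(nrow(rules), 0)
  fi <- fpgrowth_frequent_itemsets(tx, arm_config(min_support = 0.15, max_len = 3))
  sup <- setNames(fi$support,
                  vapply(fi$items, paste, character(1), collapse = "\x1f"))
  for (i in seq_len(nrow(rules))) {
    sa <- sup[[paste(rules$antecedent[[i]], collapse = "\x1f")]]
    sc <- sup[[paste(rules$consequent[[i]], collapse = "\x1f")]]
    expect_lte(rules$support[i], min(sa, sc) + 1e-12)
    expect_gte(rules$confidence[i], rules$support[i] - 1e-12)
    # lift symmetry: same itemset split the other way has the same lift
    rev_i <- which(rules$lhs == rules$rhs[i] & rules$rhs == rules$lhs[i])
    if (length(rev_i))
      expect_equal(rules$lift[i], rules$lift[rev_i[1]], tolerance = 1e-12)
  }
})

test_that("planted rules are recovered above the lift threshold", {
  cfg <- transaction_config(
    n_transactions = 1000,
    item_alphabet = c("A=high", "stage=early", "B=low", "C=medium", "D=high"),
    planted_rules = list(list(antecedent = "A=high", consequent = "stage=early",
                              confidence = 0.9, support = 0.4)),
    background_item_prob = 0.3, seed = 77)
  tx <- generate_planted_transactions(cfg)$transactions
  rules <- mine_rules(tx, arm_config(min_support = 0.3, max_len = 4, min_lift = 1.1))
  hit <- rules[rules$lhs == "A=high" & rules$rhs == "stage=early", ]
  expect_equal(nrow(hit), 1)
  expect_gt(hit$lift, 1.1)
  expect_gt(hit$confidence, 0.85)
})
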