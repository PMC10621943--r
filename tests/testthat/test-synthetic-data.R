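test_that("cohort generation is a pure function of its config", {
  cc <- cohort_config(n_early = 20, n_late = 12, n_features = 50,
                      n_informative = 5, effect_size = 2, n_constant = 2,
                      block_spec = list(c(3, 0.5)), seed = 11)
  a <- generate_cohort(cc)
  b <- generate_cohort(cc)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)
  # a different seed changes the draw
  cc2 <- cc; cc2$seed <- 12L
  expect_false(identical(generate_cohort(cc2)$matrix$values, a$matrix$values))
})

test_that("planted log-scale shift matches the generating effect size", {
  noise_sd <- 0.8
  g <- generate_cohort(cohort_config(
    n_early = 100, n_late = 100, n_features = 400, n_informative = 12,
    effect_size = 3, noise_sd = noise_sd, seed = 3))
  lv <- log(g$matrix$values)
  late <- g$matrix$stage == "late"
  for (fid in g$truth$informative_ids) {
    diff <- mean(lv[late, fid]) - mean(lv[!late, fid])
    expected <- g$truth$direction[[fid]] * 3 * noise_sd
    expect_lt(abs(diff - expected), 0.2 * abs(expected))
  }
})

test_that("feature roles: constants have exactly zero variance, ids disjoint", {
  g <- small_cohort()
  v <- g$matrix$values
  expect_true(all(v >= 0))
  for (fid in g$truth$constant_ids)
    expect_identical(var(v[, fid]), 0)
  ids <- list(g$truth$informative_ids, g$truth$constant_ids,
              names(g$truth$block_membership))
  expect_equal(length(unlist(ids)), length(unique(unlist(ids))))
  expect_true(all(unlist(ids) %in% colnames(v)))
  # correlated block really is correlated on the log scale
  blk <- names(g$truth$block_membership)
  cors <- cor(log(v[, blk]))
  expect_true(all(cors[upper.tri(cors)] > 0.7))
})

test_that("null effect size leaves planted features at the nominal type-I rate", {
  g <- generate_cohort(cohort_config(
    n_early = 60, n_late = 60, n_features = 1500, n_informative = 200,
    effect_size = 0, seed = 5))
  scores <- ttest_rank(g$matrix$values, g$matrix$stage, seq_len(120))
  rate <- mean(scores$p < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("inconsistent cohort configs are rejected with the violated constraint", {
  expect_error(cohort_config(n_early = 1, n_late = 10, n_features = 5), "n_early")
  expect_error(cohort_config(10, 10, 5, n_informative = 4, n_constant = 3),
               "exceed n_features")
  expect_error(cohort_config(10, 10, 50, effect_size = -1), "effect_size")
  expect_error(cohort_config(10, 10, 50, block_spec = list(c(3, 1))), "rho")
  expect_error(cohort_preset("nope"), "unknown")
})

test_that("planted transactions hit their target support and confidence", {
  cfg <- transaction_config(
    n_transactions = 10000,
    item_alphabet = c("A_high", "early", "X", "Y", "Z"),
    planted_rules = list(list(antecedent = "A_high", consequent = "early",
                              confidence = 0.9, support = 0.4)),
    background_item_prob = 0.2, seed = 2)
  out <- generate_planted_transactions(cfg)
  tx <- out$transactions$transactions
  has_a <- vapply(tx, function(t) "A_high" %in% t, logical(1))
  has_both <- vapply(tx, function(t) all(c("A_high", "early") %in% t), logical(1))
  conf <- sum(has_both) / sum(has_a)
  expect_gt(conf, 0.87)
  expect_lt(conf, 0.93)
  expect_gt(mean(has_both), 0.37)
  expect_lt(mean(has_both), 0.43)
})

test_that("transaction generator honours count and determinism contracts", {
  cfg <- transaction_config(50, LETTERS[1:6], seed = 9)
  a <- generate_planted_transactions(cfg)
  expect_length(a$transactions$transactions, 50)
  expect_identical(a$transactions,
                   generate_planted_transactions(cfg)$transactions)
  expect_error(transaction_config(10, character(0)), "non-empty")
  expect_error(transaction_config(
    10, c("A", "B"),
    planted_rules = list(list(antecedent = "A", consequent = "A",
                              confidence = 0.5, support = 0.2))),
    "disjoint")
})

test_that("expression tables round-trip through TSV", {
  g <- small_cohort(n_early = 3, n_late = 2, n_features = 4,
                    n_informative = 0, n_constant = 0, block_spec = list())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(g$matrix, path)
  back <- read_expression_table(path)
  expect_identical(rownames(back$values), rownames(g$matrix$values))
  expect_identical(colnames(back$values), colnames(g$matrix$values))
  expect_identical(back$stage, g$matrix$stage)
  expect_equal(back$values, g$matrix$values, tolerance = 1e-12)
})

test_that("malformed expression tables fail with informative errors", {
  g <- small_cohort(n_early = 3, n_late = 2, n_features = 3,
                    n_informative = 0, n_constant = 0, block_spec = list())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(g$matrix, path)

  # drop the stage column
  lines <- readLines(path)
  trimmed <- vapply(strsplit(lines, "\t"), function(x)
    paste(head(x, -1), collapse = "\t"), character(1))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(trimmed, p2)
  expect_error(read_expression_table(p2), "stage")

  # negative value reported with its line number
  fields <- strsplit(lines, "\t")
  fields[[3]][2] <- "-1.5"
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(vapply(fields, paste, character(1), collapse = "\t"), p3)
  expect_error(read_expression_table(p3), "line 3")
})

test_that("a single-class cohort is flagged on re-read but still loads", {
  vals <- matrix(runif(12), 3, 4,
                 dimnames = list(paste0("S", 1:3), paste0("G", 1:4)))
  em <- suppressWarnings(expression_matrix(vals, rep("late", 3),
                                           require_both_classes = FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(em, path)
  expect_warning(back <- read_expression_table(path), "single stage class")
  expect_identical(as.character(back$stage), rep("late", 3))
})
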