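# a pass-through classifier: scores are the single feature's values, so the
# validation AUC is whatever ordering the fixture encodes
passthrough_classifier <- function() {
  new_classifier("passthrough",
                 fit = function(x, y) NULL,
                 score = function(model, x) x[, 1],
                 type = "margin")
}

fixture_folds <- function(targets) {
  lapply(targets, function(a) {
    fx <- auc_fixture(a)
    list(xtr = matrix(0, 2, 1), ytr = factor(c("early", "late"), c("early", "late")),
         xva = matrix(fx$scores, ncol = 1), yva = factor(fx$labels, c("early", "late")),
         usable = TRUE)
  })
}

test_that("Eq-1 objectives summarize validation AUCs as 1 - mean + sample sd", {
  folds <- fixture_folds(c(1, 1, 1))
  o <- eval_objectives(TRUE, folds, passthrough_classifier())
  expect_equal(o$eq1, 0)

  o <- eval_objectives(TRUE, fixture_folds(rep(0.5, 5)), passthrough_classifier())
  expect_equal(o$eq1, 0.5)

  aucs <- c(0.8, 0.7, 0.9, 0.75, 0.85)
  o <- eval_objectives(TRUE, fixture_folds(aucs), passthrough_classifier())
  expect_equal(o$mean_auc, 0.8, tolerance = 1e-12)
  expect_equal(o$sd_auc, sd(aucs), tolerance = 1e-12)
  expect_equal(o$eq1, 1 - 0.8 + 0.07905694, tolerance = 1e-7)

  worst <- eval_objectives(FALSE, folds, passthrough_classifier())
  expect_equal(worst$eq1, 2)
  expect_equal(worst$n_selected, 0)
})

test_that("fast non-dominated sort produces the exact Pareto stratification", {
  obj <- rbind(c(1, 2), c(2, 1), c(2, 2), c(3, 3))
  fronts <- fast_nondominated_sort(obj)
  expect_identical(fronts, list(c(1L, 2L), 3L, 4L))
  # all identical -> one front; singleton -> one front
  expect_length(fast_nondominated_sort(rbind(c(1, 1), c(1, 1), c(1, 1))), 1)
  expect_identical(fast_nondominated_sort(rbind(c(2, 3))), list(1L))
  expect_identical(fast_nondominated_sort(matrix(numeric(0), 0, 2)), list())
})

test_that("non-dominated sorting matches the peeling oracle on random populations", {
  set.seed(8)
  for (rep in 1:40) {
    n <- sample(2:40, 1)
    obj <- matrix(sample(0:5, n * 2, replace = TRUE), n, 2)  # ties common
    expect_identical(fast_nondominated_sort(obj), fronts_bruteforce(obj))
  }
})

test_that("crowding distance follows the boundary and zero-range conventions", {
  expect_identical(crowding_distance(rbind(c(0, 1), c(1, 0))), c(Inf, Inf))
  d <- crowding_distance(rbind(c(0, 1), c(0.5, 0.5), c(1, 0)))
  expect_identical(d[c(1, 3)], c(Inf, Inf))
  expect_equal(d[2], 2)
  # one objective constant: contributes nothing to interior distances
  d2 <- crowding_distance(rbind(c(0, 5), c(0.5, 5), c(1, 5)))
  expect_equal(d2[2], 1)
})

test_that("offspring creation respects size, cloning limit and seeding", {
  set.seed(5)
  genomes <- matrix(runif(10 * 8) < 0.5, 10, 8)
  rank <- rep(1L, 10); crowd <- runif(10)
  clone_cfg <- nsga2_config(pop_size = 10, n_generations = 1,
                            crossover_prob = 0, mutation_prob = 0)
  off <- withr::with_seed(3, make_offspring(genomes, rank, crowd, clone_cfg))
  expect_identical(dim(off), dim(genomes))
  parent_keys <- apply(genomes, 1, paste, collapse = "")
  expect_true(all(apply(off, 1, paste, collapse = "") %in% parent_keys))
  cfg <- nsga2_config(pop_size = 10, n_generations = 1)
  o1 <- withr::with_seed(4, make_offspring(genomes, rank, crowd, cfg))
  o2 <- withr::with_seed(4, make_offspring(genomes, rank, crowd, cfg))
  expect_identical(o1, o2)
})

test_that("the wrapper search finds a perfectly separating feature", {
  hits <- 0L
  for (seed in 1:5) {
    g <- small_cohort(seed = 40 + seed, n_early = 40, n_late = 30,
                      n_features = 40, n_informative = 1, effect_size = 8,
                      n_constant = 0, block_spec = list())
    plan <- build_nested_folds(g$matrix$stage, 3, 3, seed = seed)
    pool_ids <- colnames(g$matrix$values)[1:12]
    if (!g$truth$informative_ids %in% pool_ids)
      pool_ids <- c(pool_ids[-1], g$truth$informative_ids)
    res <- nsga2_run(g$matrix, plan, 1, pool_ids,
                     config = nsga2_config(pop_size = 20, n_generations = 10,
                                           seed = seed))
    hits <- hits + (g$truth$informative_ids %in% res$best$feature_set)
    # elitism: best eq1 never worsens over generations
    expect_true(all(diff(res$history) <= 1e-12))
    expect_equal(nrow(res$population$genomes), 20)
    # Eq-1 identity holds for every survivor
    ob <- res$population$objectives
    expect_true(all(abs(ob$eq1 - (1 - ob$mean_auc + ob$sd_auc)) < 1e-12))
  }
  expect_gte(hits, 4)
})

test_that("front 0 of a bi-objective run is mutually non-dominated", {
  g <- small_cohort(seed = 50, n_early = 40, n_late = 30, n_features = 30,
                    n_informative = 2, effect_size = 3, n_constant = 0,
                    block_spec = list())
  plan <- build_nested_folds(g$matrix$stage, 3, 3, seed = 2)
  res <- nsga2_run(g$matrix, plan, 1, colnames(g$matrix$values)[1:15],
                   config = nsga2_config(pop_size = 12, n_generations = 5, seed = 2))
  ob <- as.matrix(res$population$objectives[, c("eq1", "n_selected")])
  front0 <- fronts_bruteforce(ob)[[1]]
  for (i in front0) for (j in front0) {
    if (i == j) next
    expect_false(all(ob[j, ] <= ob[i, ]) && any(ob[j, ] < ob[i, ]))
  }
  # identical seed, identical run
  res2 <- nsga2_run(g$matrix, plan, 1, colnames(g$matrix$values)[1:15],
                    config = nsga2_config(pop_size = 12, n_generations = 5, seed = 2))
  expect_identical(res$best$genome, res2$best$genome)
})

test_that("finalize_selection unions per-fold genomes with fold counts", {
  ids <- paste0("G", 1:8)
  same <- lapply(1:10, function(i)
    setNames(c(rep(TRUE, 6), FALSE, FALSE), ids))
  out <- finalize_selection(same)
  expect_equal(nrow(out), 6)
  expect_true(all(out$n_outer == 10))

  disjoint <- lapply(1:4, function(i) {
    g <- setNames(rep(FALSE, 8), ids)
    g[(2 * i - 1):(2 * i)] <- TRUE
    g
  })
  out2 <- finalize_selection(disjoint)
  expect_equal(nrow(out2), 8)
  expect_true(all(out2$n_outer == 1))
  expect_error(finalize_selection(list()), "at least one")
})
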