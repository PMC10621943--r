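#' Configuration for the binary NSGA-II wrapper search
#'
#' Defaults follow the published settings of the workflow this package
#' implements: population 40, 50 generations. The search is elitist
#' (mu + lambda survival over combined parents and offspring) with binary
#' tournaments on the crowded-comparison order, uniform crossover and
#' independent per-bit mutation.
#'
#' In `bi_objective` mode (default) the search minimizes
#' `(eq1, n_selected)` where `eq1 = 1 - mean(AUC) + sd(AUC)` over the inner
#' validation folds — the explicit parsimony objective drives compact feature
#' subsets. `scalar` mode minimizes `eq1` alone (a single-objective
#' degenerate run); `eq1` is the reported fitness either way.
#'
#' @param pop_size population size N (even, >= 4).
#' @param n_generations number of generations.
#' @param crossover_prob probability a parent pair undergoes uniform crossover.
#' @param mutation_prob per-bit flip probability; `NULL` (default) means 1/L
#'   where L is the genome length.
#' @param init_bit_prob probability a bit is set in the initial population.
#' @param objective_mode `"bi_objective"` or `"scalar"`.
#' @param seed integer seed.
#' @return an `nsga2_config` list.
#' @export
nsga2_config <- function(pop_size = 40L, n_generations = 50L,
                         crossover_prob = 0.9, mutation_prob = NULL,
                         init_bit_prob = 0.25,
                         objective_mode = c("bi_objective", "scalar"),
                         seed = 1L) {
  objective_mode <- match.arg(objective_mode)
  check_that(is_count(pop_size, 4L) && pop_size %% 2 == 0,
             "pop_size must be an even integer >= 4")
  check_that(is_count(n_generations, 1L), "n_generations must be >= 1")
  check_that(is_prob(crossover_prob), "crossover_prob must be in [0,1]")
  check_that(is.null(mutation_prob) || is_prob(mutation_prob),
             "mutation_prob must be NULL or in [0,1]")
  check_that(is_prob(init_bit_prob), "init_bit_prob must be in [0,1]")
  structure(list(pop_size = as.integer(pop_size),
                 n_generations = as.integer(n_generations),
                 crossover_prob = crossover_prob, mutation_prob = mutation_prob,
                 init_bit_prob = init_bit_prob, objective_mode = objective_mode,
                 seed = as.integer(seed)),
            class = "nsga2_config")
}

#' Per-fold training/validation data for wrapper fitness
#'
#' Precomputes, for one outer fold, the z-scored candidate-pool matrices of
#' every inner partition (parameters fit on the inner training rows only), so
#' a genome evaluation reduces to a column subset. Features constant on an
#' inner training fold are flagged unusable for that fold.
#'
#' @param em an [expression_matrix()].
#' @param plan a [build_nested_folds()] plan.
#' @param outer_index outer fold index.
#' @param pool_ids candidate feature ids (genome bit order).
#' @return list of inner-fold records `(xtr, ytr, xva, yva, usable)`.
#' @export
inner_fold_data <- function(em, plan, outer_index, pool_ids) {
  check_that(all(pool_ids %in% feature_ids(em)),
             "all pool features must exist in the matrix")
  values <- em$values[, pool_ids, drop = FALSE]
  y <- em$stage
  lapply(seq_len(plan$k_inner), function(j) {
    itr <- inner_train_idx(plan, outer_index, j)
    iva <- plan$inner[[outer_index]][[j]]
    sds <- col_sds_sub(values, itr)
    usable <- sds > 0
    center <- col_means_sub(values, itr)
    scl <- ifelse(usable, sds, 1)
    sc <- function(idx) {
      x <- values[idx, , drop = FALSE]
      (x - rep(center, each = length(idx))) / rep(scl, each = length(idx))
    }
    list(xtr = sc(itr), ytr = y[itr], xva = sc(iva), yva = y[iva],
         usable = usable)
  })
}

#' Evaluate the Eq-1 objectives of one genome
#'
#' Trains the classifier on each inner training partition restricted to the
#' genome's set bits, scores its validation partition, and summarizes the
#' validation AUCs: `eq1 = 1 - mean(AUC) + sd(AUC)` (sample sd, 0 for a
#' single fold). An empty genome (or one with no usable features on some
#' fold) is assigned the worst objectives (`mean_auc` 0, `sd_auc` 1,
#' `eq1` 2) rather than an error, so the search can proceed.
#'
#' @param genome logical vector over the candidate pool.
#' @param folds inner-fold data from [inner_fold_data()].
#' @param classifier a [new_classifier()] object.
#' @return list with `mean_auc`, `sd_auc`, `eq1`, `n_selected`.
#' @export
eval_objectives <- function(genome, folds, classifier) {
  n_sel <- sum(genome)
  worst <- list(mean_auc = 0, sd_auc = 1, eq1 = 2, n_selected = n_sel)
  if (n_sel == 0L) return(worst)
  aucs <- vapply(folds, function(f) {
    cols <- which(genome & f$usable)
    if (length(cols) == 0L) return(NA_real_)
    model <- classifier$fit(f$xtr[, cols, drop = FALSE], f$ytr)
    roc_auc(classifier$score(model, f$xva[, cols, drop = FALSE]), f$yva)
  }, numeric(1))
  if (anyNA(aucs)) return(worst)
  m <- mean(aucs)
  s <- if (length(aucs) > 1L) stats::sd(aucs) else 0
  list(mean_auc = m, sd_auc = s, eq1 = 1 - m + s, n_selected = n_sel)
}

#' Fast non-dominated sorting (minimization)
#'
#' Deb's dominance-count algorithm: front 1 is the exact Pareto-optimal
#' subset; every member of front i is dominated by at least one member of
#' front i-1; fronts partition the population.
#'
#' @param objectives numeric matrix, one row per individual, one column per
#'   objective, all minimized.
#' @return list of integer index vectors, best front first.
#' @export
fast_nondominated_sort <- function(objectives) {
  if (is.null(dim(objectives))) objectives <- matrix(objectives, ncol = 1)
  n <- nrow(objectives)
  if (n == 0L) return(list())
  S <- vector("list", n)
  ndom <- integer(n)
  for (i in seq_len(n)) {
    oi <- objectives[i, ]
    for (j in seq_len(n)) {
      if (i == j) next
      oj <- objectives[j, ]
      if (all(oi <= oj) && any(oi < oj)) S[[i]] <- c(S[[i]], j)
      else if (all(oj <= oi) && any(oj < oi)) ndom[i] <- ndom[i] + 1L
    }
  }
  fronts <- list()
  current <- which(ndom == 0L)
  while (length(current)) {
    fronts[[length(fronts) + 1L]] <- current
    nxt <- integer(0)
    for (i in current) {
      for (j in S[[i]]) {
        ndom[j] <- ndom[j] - 1L
        if (ndom[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- sort(unique(nxt))
  }
  fronts
}

#' Crowding distance within one front
#'
#' Boundary individuals of each objective get infinite distance; interior
#' individuals accumulate normalized nearest-neighbour gaps per objective.
#' An objective with zero range across the front contributes nothing
#' (avoiding division by zero). Ties within an objective are ordered stably.
#'
#' @param objectives numeric matrix of the front's objective rows.
#' @return numeric distance per individual (Inf allowed).
#' @export
crowding_distance <- function(objectives) {
  if (is.null(dim(objectives))) objectives <- matrix(objectives, ncol = 1)
  n <- nrow(objectives)
  d <- numeric(n)
  if (n <= 2L) return(rep(Inf, n))
  for (m in seq_len(ncol(objectives))) {
    o <- objectives[, m]
    ord <- order(o, seq_len(n))  # stable
    d[ord[1]] <- Inf
    d[ord[n]] <- Inf
    rng <- o[ord[n]] - o[ord[1]]
    if (rng > 0) {
      mid <- ord[2:(n - 1)]
      d[mid] <- d[mid] + (o[ord[3:n]] - o[ord[1:(n - 2)]]) / rng
    }
  }
  d
}

# crowded-comparison binary tournament: lower rank wins, ties broken by
# larger crowding distance, then by the first contender (deterministic given
# the rng draws)
tournament_pick <- function(rank, crowding, n) {
  ij <- sample.int(n, 2L)
  i <- ij[1]; j <- ij[2]
  if (rank[i] < rank[j]) return(i)
  if (rank[j] < rank[i]) return(j)
  if (crowding[i] >= crowding[j]) i else j
}

#' Create an offspring population
#'
#' Binary tournaments on the crowded-comparison order pick parent pairs;
#' with probability `crossover_prob` a pair undergoes uniform crossover
#' (each bit swapped independently with probability 1/2); each child bit then
#' flips with `mutation_prob`. Uses the current RNG stream: call inside a
#' seeded context for reproducibility.
#'
#' @param genomes logical matrix N x L, one row per individual.
#' @param rank,crowding front index and crowding distance per individual.
#' @param config an [nsga2_config()].
#' @return logical matrix N x L of offspring.
#' @export
make_offspring <- function(genomes, rank, crowding, config) {
  n <- nrow(genomes)
  L <- ncol(genomes)
  pm <- config$mutation_prob %||% (1 / L)
  children <- matrix(FALSE, n, L)
  for (pair in seq_len(n %/% 2)) {
    p1 <- genomes[tournament_pick(rank, crowding, n), ]
    p2 <- genomes[tournament_pick(rank, crowding, n), ]
    if (stats::runif(1) < config$crossover_prob) {
      swap <- stats::runif(L) < 0.5
      tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
    }
    if (pm > 0) {
      f1 <- stats::runif(L) < pm
      f2 <- stats::runif(L) < pm
      p1 <- xor(p1, f1); p2 <- xor(p2, f2)
    }
    children[2 * pair - 1L, ] <- p1
    children[2 * pair, ] <- p2
  }
  children
}

# objective matrix for survival/selection under the configured mode
objective_matrix <- function(objs, mode) {
  eq1 <- vapply(objs, `[[`, numeric(1), "eq1")
  if (mode == "bi_objective")
    cbind(eq1 = eq1, n_selected = vapply(objs, `[[`, numeric(1), "n_selected"))
  else cbind(eq1 = eq1)
}

#' Run the binary NSGA-II wrapper search for one outer fold
#'
#' The elitist loop: combine parents and offspring, sort the union into
#' non-dominated fronts, fill the next population front by front and truncate
#' the last admitted front by descending crowding distance. Genome
#' evaluations are cached, so re-encountered bit patterns are not refit.
#'
#' @param em an [expression_matrix()].
#' @param plan a [build_nested_folds()] plan.
#' @param outer_index outer fold whose inner partitions drive the fitness.
#' @param pool_ids candidate feature ids (genome bit order).
#' @param classifier fitness classifier (default [classifier_lda()]).
#' @param config an [nsga2_config()].
#' @return `nsga2_result` list: `pool_ids`, `population` (list with `genomes`
#'   matrix and `objectives` data.frame), `best` (genome, feature ids,
#'   objectives; minimal eq1, ties broken toward fewer then lower-indexed
#'   features), `history` (best eq1 per generation), `config`.
#' @export
nsga2_run <- function(em, plan, outer_index, pool_ids,
                      classifier = classifier_lda(), config = nsga2_config()) {
  check_that(length(pool_ids) >= 1L, "candidate pool must be non-empty")
  folds <- inner_fold_data(em, plan, outer_index, pool_ids)
  L <- length(pool_ids)
  N <- config$pop_size
  cache <- new.env(hash = TRUE, parent = emptyenv())
  evaluate <- function(genomes) {
    lapply(seq_len(nrow(genomes)), function(i) {
      g <- genomes[i, ]
      key <- paste(as.integer(g), collapse = "")
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      o <- eval_objectives(g, folds, classifier)
      cache[[key]] <- o
      o
    })
  }

  with_seed(config$seed, {
    genomes <- matrix(stats::runif(N * L) < config$init_bit_prob, N, L)
    objs <- evaluate(genomes)
    om <- objective_matrix(objs, config$objective_mode)
    fronts <- fast_nondominated_sort(om)
    rank <- integer(N); crowd <- numeric(N)
    for (fi in seq_along(fronts)) {
      rank[fronts[[fi]]] <- fi
      crowd[fronts[[fi]]] <- crowding_distance(om[fronts[[fi]], , drop = FALSE])
    }
    history <- numeric(config$n_generations)

    for (gen in seq_len(config$n_generations)) {
      off <- make_offspring(genomes, rank, crowd, config)
      off_objs <- evaluate(off)
      all_g <- rbind(genomes, off)
      all_o <- c(objs, off_objs)
      all_om <- objective_matrix(all_o, config$objective_mode)
      fronts <- fast_nondominated_sort(all_om)
      sel <- integer(0)
      rank_new <- integer(0); crowd_new <- numeric(0)
      for (fi in seq_along(fronts)) {
        f <- fronts[[fi]]
        cd <- crowding_distance(all_om[f, , drop = FALSE])
        if (length(sel) + length(f) <= N) {
          sel <- c(sel, f)
          rank_new <- c(rank_new, rep(fi, length(f)))
          crowd_new <- c(crowd_new, cd)
        } else {
          need <- N - length(sel)
          ord <- order(-cd, seq_along(f))  # crowding desc, stable
          take <- ord[seq_len(need)]
          sel <- c(sel, f[take])
          rank_new <- c(rank_new, rep(fi, need))
          crowd_new <- c(crowd_new, cd[take])
          break
        }
      }
      genomes <- all_g[sel, , drop = FALSE]
      objs <- all_o[sel]
      rank <- rank_new; crowd <- crowd_new
      history[gen] <- min(vapply(objs, `[[`, numeric(1), "eq1"))
    }

    best_i <- pick_best(genomes, objs)
    structure(list(
      pool_ids = pool_ids,
      population = list(
        genomes = genomes,
        objectives = do.call(rbind, lapply(objs, as.data.frame))),
      best = list(genome = genomes[best_i, ],
                  feature_set = pool_ids[genomes[best_i, ]],
                  objectives = objs[[best_i]]),
      history = history, outer_index = outer_index, config = config),
      class = "nsga2_result")
  })
}

# minimal eq1; ties -> fewer selected features, then lexicographically
# earliest set of selected feature indices
pick_best <- function(genomes, objs) {
  eq1 <- vapply(objs, `[[`, numeric(1), "eq1")
  nsel <- vapply(objs, `[[`, numeric(1), "n_selected")
  cand <- which(eq1 == min(eq1))
  cand <- cand[nsel[cand] == min(nsel[cand])]
  if (length(cand) == 1L) return(cand)
  keys <- vapply(cand, function(i)
    paste(sprintf("%06d", which(genomes[i, ])), collapse = ","), character(1))
  cand[order(keys)][1]
}

#' Run the wrapper search for every outer fold and merge the selections
#'
#' One NSGA-II run per outer fold (fold `i` seeded with `config$seed + i` so
#' runs are independent but reproducible), merged by [finalize_selection()].
#'
#' @inheritParams nsga2_run
#' @param pool a `candidate_pool` from [pool_candidates()] (or a character
#'   vector of feature ids).
#' @return list with `selection` (the merged feature table), `per_outer`
#'   (list of `nsga2_result`), `pool_ids`.
#' @export
nsga2_select <- function(em, plan, pool, classifier = classifier_lda(),
                         config = nsga2_config()) {
  pool_ids <- if (is.data.frame(pool)) pool$feature_id else pool
  results <- lapply(seq_len(plan$k_outer), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    nsga2_run(em, plan, i, pool_ids, classifier, cfg)
  })
  list(selection = finalize_selection(results),
       per_outer = results, pool_ids = pool_ids)
}

#' Merge per-outer-fold best genomes into the final feature selection
#'
#' Union of set-bit features across the outer folds' best individuals,
#' ordered by the number of outer folds selecting the feature (descending)
#' then feature id.
#'
#' @param results non-empty list of `nsga2_result` objects (or a list of
#'   named logical genomes).
#' @return data.frame with `feature_id` and `n_outer`.
#' @export
finalize_selection <- function(results) {
  check_that(length(results) >= 1L, "need at least one per-outer result")
  genomes <- lapply(results, function(r) {
    if (inherits(r, "nsga2_result"))
      stats::setNames(r$best$genome, r$pool_ids)
    else r
  })
  ids <- names(genomes[[1]])
  counts <- Reduce(`+`, lapply(genomes, as.integer))
  keep <- counts > 0
  ord <- order(-counts[keep], ids[keep])
  data.frame(feature_id = ids[keep][ord], n_outer = counts[keep][ord],
             row.names = NULL, stringsAsFactors = FALSE)
}
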