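#' End-to-end pipeline configuration
#'
#' Defaults equal the published workflow settings: 10 outer x 5 inner folds,
#' 15 top features per inner partition, NSGA-II population 40 over 50
#' generations, ARM thresholds 0.3 (min-support) / 4 (max-length) / 1.1
#' (lift). Either `cohort` (a [cohort_config()], to simulate) or `input_tsv`
#' (an expression table path) must be supplied.
#'
#' @param cohort optional [cohort_config()] for a simulated input.
#' @param input_tsv optional path to an expression TSV
#'   (see [read_expression_table()]).
#' @param k_outer,k_inner nested fold counts.
#' @param k_top filter selections per inner partition.
#' @param nsga2 an [nsga2_config()].
#' @param arm an [arm_config()].
#' @param wrapper_classifier fitness classifier for the wrapper search.
#' @param classifiers named roster for the evaluation stage.
#' @param top_rules_n rules reported in the top-rules tables.
#' @param n_top_spearman transcripts per stage entering the Spearman table.
#' @param seed global seed; stage seeds are derived from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, input_tsv = NULL,
                            k_outer = 10L, k_inner = 5L, k_top = 15L,
                            nsga2 = nsga2_config(),
                            arm = arm_config(),
                            wrapper_classifier = classifier_lda(),
                            classifiers = default_classifier_roster(),
                            top_rules_n = 20L, n_top_spearman = 3L,
                            seed = 1L) {
  check_that(xor(is.null(cohort), is.null(input_tsv)),
             "supply exactly one of `cohort` or `input_tsv`")
  if (!is.null(cohort))
    check_that(inherits(cohort, "cohort_config"), "`cohort` must be a cohort_config")
  check_that(inherits(nsga2, "nsga2_config"), "`nsga2` must be an nsga2_config")
  check_that(inherits(arm, "arm_config"), "`arm` must be an arm_config")
  check_that(is_count(k_top, 1L), "k_top must be >= 1")
  structure(list(cohort = cohort, input_tsv = input_tsv,
                 k_outer = as.integer(k_outer), k_inner = as.integer(k_inner),
                 k_top = as.integer(k_top), nsga2 = nsga2, arm = arm,
                 wrapper_classifier = wrapper_classifier,
                 classifiers = classifiers,
                 top_rules_n = as.integer(top_rules_n),
                 n_top_spearman = as.integer(n_top_spearman),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' The file mirrors the [pipeline_config()] fields; nested `cohort`, `nsga2`
#' and `arm` maps mirror the corresponding constructor arguments. Classifier
#' rosters are named by the constructor they map to (SVM, KNN, NB, RF, LDA).
#'
#' @param path path to a YAML configuration file.
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c(SVM = classifier_svm_linear, KNN = classifier_knn,
             NB = classifier_nb, RF = classifier_rf, LDA = classifier_lda)
  args <- list()
  if (!is.null(cfg$cohort)) args$cohort <- do.call(cohort_config, cfg$cohort)
  if (!is.null(cfg$input_tsv)) args$input_tsv <- cfg$input_tsv
  for (f in c("k_outer", "k_inner", "k_top", "top_rules_n", "n_top_spearman", "seed"))
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  if (!is.null(cfg$nsga2)) args$nsga2 <- do.call(nsga2_config, cfg$nsga2)
  if (!is.null(cfg$arm)) args$arm <- do.call(arm_config, cfg$arm)
  if (!is.null(cfg$classifiers)) {
    check_that(all(cfg$classifiers %in% names(known)),
               sprintf("unknown classifier name; known: %s",
                       paste(names(known), collapse = ", ")))
    args$classifiers <- stats::setNames(
      lapply(cfg$classifiers, function(nm) known[[nm]]()), cfg$classifiers)
  }
  if (!is.null(cfg$wrapper_classifier))
    args$wrapper_classifier <- known[[cfg$wrapper_classifier]]()
  do.call(pipeline_config, args)
}

#' Run the full stage-discrimination and rule-mining pipeline
#'
#' Chains all stages — input, nested folds, filter pooling, wrapper
#' selection, classifier evaluation, rule mining, rule analytics — and
#' writes every tabular artifact to `outdir`. Outputs are byte-identical
#' under an identical configuration and seed. Any stage failure aborts with
#' the stage name; artifacts written before the failure are preserved.
#'
#' Artifacts: `candidate_pool.csv`, `selected_features.csv`, `metrics.csv`,
#' `rules.csv`, `top_rules_early.csv`, `top_rules_late.csv`,
#' `repeat_counts.csv`, `rule_graph_early.graphml`/`.csv`,
#' `rule_graph_late.graphml`/`.csv`, `spearman.csv`, `run_report.yaml`.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if missing).
#' @param verbose print stage progress messages.
#' @return invisibly, a list with the main in-memory results (`matrix`,
#'   `plan`, `pool`, `selection`, `metrics`, `rules`, `repeat_counts`,
#'   `artifacts`).
#' @export
run_pipeline <- function(config, outdir, verbose = TRUE) {
  check_that(inherits(config, "pipeline_config"), "`config` must be a pipeline_config")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    st <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- round(as.numeric(difftime(Sys.time(), st, units = "secs")), 3)
    say("stage %-12s %6.1fs", name, timings[[name]])
    out
  }
  art <- function(f) file.path(outdir, f)

  em <- stage("input", {
    if (!is.null(config$cohort)) generate_cohort(config$cohort)$matrix
    else read_expression_table(config$input_tsv)
  })

  plan <- stage("folds", build_nested_folds(
    em$stage, config$k_outer, config$k_inner, seed = config$seed))

  pool <- stage("filter", {
    p <- pool_candidates(em, plan, k_top = config$k_top)
    data.table::fwrite(p, art("candidate_pool.csv"))
    p
  })

  wrap <- stage("wrapper", {
    cfg <- config$nsga2
    cfg$seed <- config$seed
    w <- nsga2_select(em, plan, pool, config$wrapper_classifier, cfg)
    data.table::fwrite(w$selection, art("selected_features.csv"))
    w
  })
  selected <- wrap$selection$feature_id

  metrics <- stage("evaluate", {
    m <- evaluate_feature_set(em, selected, plan,
                              classifiers = config$classifiers,
                              seed = config$seed)
    data.table::fwrite(m, art("metrics.csv"))
    m
  })

  mined <- stage("mine", {
    keep <- remove_constant_features(em$values[, selected, drop = FALSE],
                                     seq_len(plan$n))
    v01 <- minmax_scale(em$values[, selected[keep], drop = FALSE])
    tx <- build_transactions(discretize_tertiles(v01), em$stage)
    rules <- mine_rules(tx, config$arm)
    flat <- rules[, c("lhs", "rhs", "support", "confidence", "lift", "count")]
    data.table::fwrite(flat, art("rules.csv"))
    list(tx = tx, rules = rules)
  })

  analysis <- stage("analyze", {
    early <- stage_rules(mined$rules, "early")
    late <- stage_rules(mined$rules, "late")
    rc <- repeat_count_table(early, late)
    data.table::fwrite(rc, art("repeat_counts.csv"))
    flat_cols <- c("lhs", "rhs", "support", "confidence", "lift")
    data.table::fwrite(top_rules_by_lift(early, config$top_rules_n)[, flat_cols],
                       art("top_rules_early.csv"))
    data.table::fwrite(top_rules_by_lift(late, config$top_rules_n)[, flat_cols],
                       art("top_rules_late.csv"))
    for (st_name in c("early", "late")) {
      rs <- if (st_name == "early") early else late
      if (nrow(rs) > 0)
        write_rule_graph(build_rule_graph(rs),
                         art(sprintf("rule_graph_%s.graphml", st_name)),
                         art(sprintf("rule_graph_%s.csv", st_name)))
    }
    top_feats <- unique(c(
      utils::head(rc$feature_id[order(-rc$early_count)], config$n_top_spearman),
      utils::head(rc$feature_id[order(-rc$late_count)], config$n_top_spearman)))
    if (length(top_feats) >= 2) {
      rho <- spearman_matrix(em, top_feats)
      data.table::fwrite(data.table::as.data.table(rho, keep.rownames = "feature_id"),
                         art("spearman.csv"))
    }
    list(early = early, late = late, repeat_counts = rc)
  })

  report <- list(
    seed = config$seed,
    n_samples = plan$n, n_features = ncol(em$values),
    settings = list(k_outer = config$k_outer, k_inner = config$k_inner,
                    k_top = config$k_top,
                    nsga2 = unclass(config$nsga2)[c("pop_size", "n_generations",
                                                    "crossover_prob", "init_bit_prob",
                                                    "objective_mode")],
                    arm = unclass(config$arm)),
    pool_size = nrow(pool), n_selected = length(selected),
    n_rules = nrow(mined$rules),
    n_early_rules = nrow(analysis$early), n_late_rules = nrow(analysis$late),
    timings_sec = timings,
    total_sec = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("stagemine")))
  yaml::write_yaml(report, art("run_report.yaml"))

  invisible(list(matrix = em, plan = plan, pool = pool, selection = wrap$selection,
                 per_outer = wrap$per_outer, metrics = metrics,
                 rules = mined$rules, transactions = mined$tx,
                 repeat_counts = analysis$repeat_counts,
                 artifacts = list.files(outdir, full.names = TRUE)))
}
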