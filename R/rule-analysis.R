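# Rule analytics: stage-consequent extraction, repeat counts, rule graphs,
# Spearman correlation among top transcripts.

item_feature <- function(items) sub("=.*$", "", items)
is_stage_item <- function(items) startsWith(items, "stage=")

#' Extract rules whose consequent is a single stage item
#'
#' @param rules an `assoc_rules` table.
#' @param stage `"early"` or `"late"`.
#' @return the subset of `rules` with consequent exactly `{stage=<stage>}`.
#' @export
stage_rules <- function(rules, stage = c("early", "late")) {
  stage <- match.arg(stage)
  target <- paste0("stage=", stage)
  keep <- vapply(rules$consequent, function(cq)
    length(cq) == 1L && cq == target, logical(1))
  rules[keep, , drop = FALSE]
}

#' Per-transcript repeat counts in stage-consequent rules
#'
#' For each feature, counts the rules whose antecedent contains any level
#' item of that feature, separately for the early-stage and late-stage rule
#' sets (levels are aggregated per feature, matching how transcripts are
#' reported). Since a transaction holds at most one level per feature, each
#' rule contributes 0 or 1 to a feature's count.
#'
#' @param early_rules,late_rules stage-filtered `assoc_rules` tables from
#'   [stage_rules()].
#' @return data.frame `feature_id`, `early_count`, `late_count`, sorted by
#'   total count descending then feature id.
#' @export
repeat_count_table <- function(early_rules, late_rules) {
  count_stage <- function(rules) {
    feats <- unlist(lapply(rules$antecedent, function(a)
      unique(item_feature(a[!is_stage_item(a)]))))
    if (is.null(feats)) feats <- character(0)
    table(feats)
  }
  e <- count_stage(early_rules)
  l <- count_stage(late_rules)
  ids <- sort(union(names(e), names(l)))
  df <- data.frame(
    feature_id = ids,
    early_count = as.integer(ifelse(ids %in% names(e), e[ids], 0L)),
    late_count = as.integer(ifelse(ids %in% names(l), l[ids], 0L)),
    stringsAsFactors = FALSE)
  df[order(-(df$early_count + df$late_count), df$feature_id), , drop = FALSE]
}

#' Top rules by lift
#'
#' @param rules an `assoc_rules` table.
#' @param n number of rules to return (>= 1).
#' @return the first `min(n, available)` rules sorted by lift descending,
#'   ties by support descending then canonical antecedent order.
#' @export
top_rules_by_lift <- function(rules, n = 20L) {
  check_that(is_count(n, 1L), "`n` must be an integer >= 1")
  ord <- order(-rules$lift, -rules$support, rules$lhs, rules$rhs)
  rules[utils::head(ord, n), , drop = FALSE]
}

#' Rules involving an anchor transcript
#'
#' Returns rules whose antecedent or consequent contains any level item of
#' the anchor feature and whose lift strictly exceeds `min_lift` — the
#' neighbourhood used to inspect a top transcript's dependencies on other
#' transcripts.
#'
#' @param rules an `assoc_rules` table (carries the mining alphabet).
#' @param anchor_feature a feature id present in the mining alphabet.
#' @param min_lift strict lower bound on lift.
#' @return the qualifying subset of `rules`.
#' @export
anchor_feature_rules <- function(rules, anchor_feature, min_lift = 1.1) {
  alphabet <- attr(rules, "alphabet")
  known <- unique(item_feature(alphabet[!is_stage_item(alphabet)]))
  check_that(anchor_feature %in% known,
             sprintf("unknown anchor feature '%s'", anchor_feature))
  hit <- vapply(seq_len(nrow(rules)), function(i) {
    its <- c(rules$antecedent[[i]], rules$consequent[[i]])
    any(item_feature(its[!is_stage_item(its)]) == anchor_feature)
  }, logical(1))
  rules[hit & rules$lift > min_lift, , drop = FALSE]
}

#' Build the phenotype-rule-feature graph
#'
#' Typed directed graph: feature nodes point into the rule nodes whose
#' antecedent they appear in (edge attribute `level`); each rule node points
#' to its consequent — a phenotype node for a stage consequent, feature
#' nodes otherwise. Rule nodes carry `lift`, `support` and `confidence`.
#' No edge ever joins two nodes of the same type. Node order (phenotypes,
#' then rules in input order, then sorted features) is deterministic.
#'
#' @param rules a non-empty `assoc_rules` table.
#' @return an `igraph` graph with vertex attributes `type` and `label`.
#' @export
build_rule_graph <- function(rules) {
  check_that(nrow(rules) >= 1L, "cannot build a graph from zero rules")
  rule_names <- sprintf("rule_%03d", seq_len(nrow(rules)))
  all_items <- unlist(c(rules$antecedent, rules$consequent))
  stage_vals <- sort(unique(sub("^stage=", "", all_items[is_stage_item(all_items)])))
  feat_nodes <- sort(unique(item_feature(all_items[!is_stage_item(all_items)])))
  phen_nodes <- if (length(stage_vals)) paste0("stage:", stage_vals) else character(0)

  edges <- list()
  for (i in seq_len(nrow(rules))) {
    for (it in rules$antecedent[[i]]) {
      from <- if (is_stage_item(it)) paste0("stage:", sub("^stage=", "", it))
              else item_feature(it)
      edges[[length(edges) + 1L]] <- data.frame(
        from = from, to = rule_names[i],
        level = if (is_stage_item(it)) NA_character_ else sub("^.*=", "", it),
        stringsAsFactors = FALSE)
    }
    for (it in rules$consequent[[i]]) {
      to <- if (is_stage_item(it)) paste0("stage:", sub("^stage=", "", it))
            else item_feature(it)
      edges[[length(edges) + 1L]] <- data.frame(
        from = rule_names[i], to = to,
        level = if (is_stage_item(it)) NA_character_ else sub("^.*=", "", it),
        stringsAsFactors = FALSE)
    }
  }
  edf <- do.call(rbind, edges)
  vdf <- data.frame(
    name = c(phen_nodes, rule_names, feat_nodes),
    type = c(rep("phenotype", length(phen_nodes)),
             rep("rule", length(rule_names)),
             rep("feature", length(feat_nodes))),
    stringsAsFactors = FALSE)
  vdf$label <- vdf$name
  vdf$lift <- NA_real_; vdf$support <- NA_real_; vdf$confidence <- NA_real_
  ridx <- match(rule_names, vdf$name)
  vdf$lift[ridx] <- rules$lift
  vdf$support[ridx] <- rules$support
  vdf$confidence[ridx] <- rules$confidence
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}

#' Serialize a rule graph to GraphML and an edge-list CSV
#'
#' @param graph an igraph graph from [build_rule_graph()].
#' @param graphml_path output GraphML path (skipped when `NULL`).
#' @param edges_path output edge-list CSV path (skipped when `NULL`).
#' @return invisibly, the paths written.
#' @export
write_rule_graph <- function(graph, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(graph, graphml_path, format = "graphml")
  if (!is.null(edges_path)) {
    edf <- igraph::as_data_frame(graph, what = "edges")
    data.table::fwrite(edf, edges_path)
  }
  invisible(c(graphml = graphml_path, edges = edges_path))
}

#' Spearman correlation among a set of transcripts
#'
#' Rank correlation with average-rank tie handling; the matrix is symmetric
#' with an exact unit diagonal.
#'
#' @param em an [expression_matrix()] (or a plain numeric matrix).
#' @param feature_set at least two feature ids, none constant.
#' @return symmetric correlation matrix over `feature_set`.
#' @export
spearman_matrix <- function(em, feature_set) {
  values <- if (inherits(em, "expr_matrix")) em$values else em
  check_that(length(feature_set) >= 2L, "need at least two features")
  check_that(all(feature_set %in% colnames(values)),
             "all requested features must exist")
  x <- values[, feature_set, drop = FALSE]
  sds <- col_sds_sub(x, seq_len(nrow(x)))
  if (any(sds == 0))
    stop(sprintf("constant feature(s): %s",
                 paste(feature_set[sds == 0], collapse = ", ")), call. = FALSE)
  rho <- stats::cor(x, method = "spearman")
  diag(rho) <- 1
  rho
}
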