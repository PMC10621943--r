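#' Configuration for a synthetic two-stage expression cohort
#'
#' The generator draws expression on the log scale (Gaussian feature baselines
#' plus Gaussian noise) and exponentiates, giving the right-skewed,
#' non-negative marginal distributions typical of FPKM data. A small planted
#' set of informative features receives a location shift of
#' `effect_size * noise_sd` on the log scale in the late group, with the shift
#' direction alternating per feature so both up- and down-regulated markers
#' exist. Optional equicorrelated feature blocks induce feature-feature
#' structure for rule mining, and constant (zero-variance) features exercise
#' the cleaning step.
#'
#' @param n_early,n_late samples per stage group (each >= 2).
#' @param n_features total number of features.
#' @param n_informative number of stage-informative features.
#' @param effect_size standardized mean shift (Cohen's d) applied to
#'   informative features in the late group, on the log scale; >= 0.
#' @param n_constant number of zero-variance features.
#' @param block_spec list of `c(size, rho)` pairs: correlated feature blocks
#'   with within-block correlation `rho` in `[0, 1)`.
#' @param noise_sd log-scale noise standard deviation (> 0).
#' @param baseline_log_mean,baseline_log_sd distribution of per-feature
#'   baseline log-expression means.
#' @param seed integer seed; the generator is a pure function of the config.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_early, n_late, n_features,
                          n_informative = 0L, effect_size = 1,
                          n_constant = 0L, block_spec = list(),
                          noise_sd = 1, baseline_log_mean = 2,
                          baseline_log_sd = 1.5, seed = 1L) {
  check_that(is_count(n_early, 2L), "n_early must be an integer >= 2")
  check_that(is_count(n_late, 2L), "n_late must be an integer >= 2")
  check_that(is_count(n_features, 1L), "n_features must be a positive integer")
  check_that(is_count(n_informative), "n_informative must be a non-negative integer")
  check_that(is_count(n_constant), "n_constant must be a non-negative integer")
  check_that(is.numeric(effect_size) && effect_size >= 0, "effect_size must be >= 0")
  check_that(is.numeric(noise_sd) && noise_sd > 0, "noise_sd must be > 0")
  check_that(is.list(block_spec), "block_spec must be a list of c(size, rho)")
  for (b in block_spec) {
    check_that(length(b) == 2L && is_count(b[1], 2L) && is_prob(b[2], 0, 1) && b[2] < 1,
               "each block_spec entry must be c(size >= 2, rho in [0, 1))")
  }
  block_sizes <- vapply(block_spec, function(b) as.integer(b[1]), integer(1))
  check_that(n_informative + n_constant + sum(block_sizes) <= n_features,
             "n_informative + n_constant + sum(block sizes) must not exceed n_features")
  structure(list(n_early = as.integer(n_early), n_late = as.integer(n_late),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, n_constant = as.integer(n_constant),
                 block_spec = block_spec, noise_sd = noise_sd,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Named cohort presets
#'
#' `"ptc_tcga_profile"` pins the cohort shape used for full-scale interface
#' tests: 375 early + 179 late samples over 60,483 features, matching the
#' dimensions of a papillary thyroid carcinoma HTSeq-FPKM cohort.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return a `cohort_config`.
#' @export
cohort_preset <- function(name = "ptc_tcga_profile", seed = 1L) {
  switch(name,
    ptc_tcga_profile = cohort_config(
      n_early = 375L, n_late = 179L, n_features = 60483L,
      n_informative = 50L, effect_size = 1.5, n_constant = 100L,
      block_spec = list(c(10, 0.8)), noise_sd = 1, seed = seed),
    stop(sprintf("unknown cohort preset '%s'", name), call. = FALSE)
  )
}

#' Generate a synthetic cohort with known planted structure
#'
#' @param config a [cohort_config()].
#' @return a list with elements `matrix` (an [expression_matrix()]) and
#'   `truth` (a `planted_truth` list: `informative_ids`, per-feature shift
#'   `direction` (+1 up in late, -1 down) and `shift` magnitude on the log
#'   scale, `block_membership` (named integer block index), `constant_ids`).
#' @export
generate_cohort <- function(config) {
  check_that(inherits(config, "cohort_config"), "`config` must be a cohort_config")
  n <- config$n_early + config$n_late
  p <- config$n_features
  block_sizes <- vapply(config$block_spec, function(b) as.integer(b[1]), integer(1))

  with_seed(config$seed, {
    fid <- sprintf("G%06d", seq_len(p))
    # assign feature roles to random, disjoint positions
    n_special <- config$n_informative + config$n_constant + sum(block_sizes)
    special <- if (n_special > 0) sample.int(p, n_special) else integer(0)
    inf_idx <- utils::head(special, config$n_informative)
    rest <- special[seq_along(special) > config$n_informative]
    block_idx <- utils::head(rest, sum(block_sizes))
    const_idx <- rest[seq_along(rest) > sum(block_sizes)]

    mu <- stats::rnorm(p, config$baseline_log_mean, config$baseline_log_sd)
    X <- matrix(stats::rnorm(n * p, 0, config$noise_sd), nrow = n, ncol = p)

    # equicorrelated blocks: shared per-sample factor mixed into the noise
    block_membership <- integer(0)
    off <- 0L
    for (bi in seq_along(config$block_spec)) {
      sz <- block_sizes[bi]
      rho <- config$block_spec[[bi]][2]
      cols <- block_idx[(off + 1L):(off + sz)]
      z <- stats::rnorm(n, 0, config$noise_sd)
      X[, cols] <- sqrt(rho) * z + sqrt(1 - rho) * X[, cols]
      block_membership <- c(block_membership, stats::setNames(rep(bi, sz), fid[cols]))
      off <- off + sz
    }

    # planted stage effect: alternating-direction log-scale shift in late group
    late_rows <- (config$n_early + 1L):n
    direction <- numeric(0)
    if (config$n_informative > 0) {
      dirs <- rep(c(1, -1), length.out = config$n_informative)
      shift <- config$effect_size * config$noise_sd
      X[late_rows, inf_idx] <- X[late_rows, inf_idx] +
        rep(dirs * shift, each = length(late_rows))
      direction <- stats::setNames(dirs, fid[inf_idx])
    }

    X <- X + rep(mu, each = n)
    values <- exp(X)
    # constant features: exactly zero variance
    if (length(const_idx))
      values[, const_idx] <- rep(exp(mu[const_idx]), each = n)

    rownames(values) <- sprintf("S%04d", seq_len(n))
    colnames(values) <- fid
    labels <- rep(STAGE_LEVELS, c(config$n_early, config$n_late))

    truth <- structure(list(
      informative_ids = fid[inf_idx],
      direction = direction,
      shift = config$effect_size * config$noise_sd,
      block_membership = block_membership,
      constant_ids = fid[const_idx]), class = "planted_truth")

    list(matrix = expression_matrix(values, labels), truth = truth)
  })
}
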