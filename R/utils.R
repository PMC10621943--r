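# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded generators are pure functions
#' of their configuration and do not disturb the caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# fail with a clean, caller-attributed message
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) && x >= min
}

is_prob <- function(x, lo = 0, hi = 1) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= lo && x <= hi
}

# column means / sds restricted to a row subset, without apply()
col_means_sub <- function(values, idx) colMeans(values[idx, , drop = FALSE])

col_sds_sub <- function(values, idx) {
  x <- values[idx, , drop = FALSE]
  n <- nrow(x)
  mu <- colMeans(x)
  sq <- colSums(x * x) - n * mu * mu
  sq[sq < 0] <- 0  # numerical guard
  sqrt(sq / (n - 1))
}

# stage labels are a two-level factor everywhere in the package
STAGE_LEVELS <- c("early", "late")

as_stage_factor <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  check_that(all(labels %in% STAGE_LEVELS),
             sprintf("stage labels must be one of: %s",
                     paste(STAGE_LEVELS, collapse = ", ")))
  factor(labels, levels = STAGE_LEVELS)
}
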