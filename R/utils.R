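# Internal helpers: classed conditions, seeded RNG scopes, positive normals.

stop_anthropix <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "anthropix_error"),
                      call = call))
}

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded package functions do not disturb the global
#' random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_anthropix("'seed' must be a single integer", "anthropix_config_error")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministic splitting scheme used by [run_pipeline()]: stage `i` runs
#' under `(seed * 48271 + i) mod (2^31 - 1)`, so stages are individually
#' reproducible without sharing a random stream.
#'
#' @param seed Master integer seed.
#' @param stage Stage index (small positive integer).
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  m <- 2147483647
  as.integer((abs(as.numeric(seed)) %% m * 48271 + as.numeric(stage)) %% m)
}

# Normal draws conditioned positive by rejection; negligible rejection rate
# at anthropometric parameters, keeps the stated means.
rnorm_pos <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_anthropix(sprintf("'%s' must be a single positive number", name),
                   "anthropix_config_error")
  invisible(x)
}

check_gender <- function(gender) {
  if (!is.character(gender) || length(gender) != 1L ||
      !gender %in% c("female", "male"))
    stop_anthropix("'gender' must be \"female\" or \"male\"",
                   "anthropix_config_error")
  gender
}
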