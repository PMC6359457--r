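#' @keywords internal
"_PACKAGE"

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a global seed and a tag
#'
#' Hierarchical seeding: a single global seed spawns distinct, deterministic
#' per-module seeds so partial pipeline re-runs stay reproducible.
#'
#' @param seed integer global seed.
#' @param tag character tag naming the consumer (e.g. "gmofs").
#' @return an integer seed in [0, 2^31 - 1).
#' @export
spawn_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647)
}

# run expr with a local RNG state (restores the caller's .Random.seed)
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
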