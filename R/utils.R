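#' Derive a reproducible sub-seed from a master seed
#'
#' Each analysis stage consumes its own stream of pseudo-random numbers; a
#' single configured master seed is mapped deterministically onto per-stage
#' seeds so that stages can be re-run in isolation yet remain reproducible.
#' The derived seed always fits in a signed 32-bit integer.
#'
#' @param seed integer master seed.
#' @param stage character or integer tag identifying the consumer.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  tag <- if (is.character(stage)) sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) else as.numeric(stage)
  # 64-bit-safe modular mix kept below 2^31
  m <- 2147483647
  x <- (abs(seed) %% m)
  x <- (x * 48271 + tag * 16807 + 12345) %% m
  as.integer(x)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_invalid <- function(...) {
  stop(structure(class = c("modmap_invalid_parameter", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
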