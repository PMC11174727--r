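# Seed management helpers (exported) and internal error utilities.

#' Run code with a private, reproducible RNG state
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so library internals never perturb user-level
#' random streams.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed and a stream tag
#'
#' Deterministic integer hash so one master seed fans out to independent
#' per-module / per-replicate streams. Result is always in `[0, 2^31 - 1)`.
#'
#' @param seed Master integer seed.
#' @param tag Character stream tag.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  chars <- utf8ToInt(paste0("s", tag))
  h <- seed %% 2147483647
  for (ch in chars) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

stop_bagseg <- function(msg, class) {
  abort(msg, class = c(class, "bagseg_error"))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x == as.integer(x)
}
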