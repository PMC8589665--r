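# Internal helpers shared across modules.

# Validation failures are signalled as classed conditions so callers and
# tests can distinguish contract violations from programming errors.
abort_validation <- function(..., class = "bistate_validation_error") {
  stop(errorCondition(paste0(...), class = c(class, "error", "condition")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so package functions never clobber the global stream.
with_seed <- function(seed, code) {
  if (!is_scalar_number(seed)) abort_validation("seed must be a single finite number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible child seed
#'
#' Deterministically maps a master seed plus one or more integer offsets
#' (iteration number, patient index, ...) to a new seed in `[0, 2^31 - 2]`.
#' Used so that every stochastic stage of the pipeline can be replayed from a
#' single master seed.
#'
#' @param seed Master seed (single integer-like number).
#' @param ... Integer offsets identifying the sub-stream.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, 3, 7)
derive_seed <- function(seed, ...) {
  if (!is_scalar_number(seed)) abort_validation("seed must be a single finite number")
  idx <- c(...)
  v <- abs(as.double(seed)) %% 2147483647
  # linear-congruential style mixing, kept in double precision (< 2^53)
  for (i in c(1, idx)) {
    v <- (v * 69069 + abs(as.double(i)) + 1) %% 2147483647
  }
  as.integer(v)
}

clip01 <- function(x) pmin(1, pmax(0, x))

# Column presence check for CSV readers; names the offender.
require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_validation(what, " is missing required column(s): ",
                     paste(missing, collapse = ", "))
  }
  invisible(df)
}
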