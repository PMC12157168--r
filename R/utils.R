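# Internal helpers shared across modules.

# Derive a child seed from a master seed and a stream index.
# Kept below 2^31 - 1 so the result is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729 + 17) %% 2147483629)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so package functions never disturb user RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_formbo <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "formbo_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is_number(x) || x < lower || x > upper) {
    stop_formbo(sprintf("`%s` must be a finite number in [%g, %g]", name, lower, upper),
                "formbo_config_error")
  }
  invisible(x)
}
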