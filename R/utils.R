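# Internal helpers shared across modules.

# Collapse runs of whitespace and strip ends; the only text mutation applied
# at ingest.
normalize_ws <- function(x) {
  stringr::str_squish(x)
}

# Stop with a classed condition so callers and tests can match on class.
stop_qorient <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "qorient_error"), ...)
}

# Deterministic RNG scope: run `expr` under `seed` without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == as.integer(x)
}
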