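
# Internal helpers shared across modules.

assert_binary <- function(x, name) {
  if (any(is.na(x)) || !all(x %in% c(0, 1))) {
    abort(sprintf("`%s` must be binary (0/1); got non-binary values.", name))
  }
  invisible(x)
}

# Deterministic child seeds below 2^31, derived from a user seed.
# Double arithmetic: the products stay below 2^53, so the modulus is exact
# and no integer overflow can occur.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(k) * 12289) %% 2147483629)
}

# One-hot encode a binary decision as two 0/1 slots; slot index equals the
# decision value.
decision_onehot <- function(d, name) {
  assert_binary(d, name)
  m <- cbind(1 - d, d)
  colnames(m) <- paste0(name, "_", 0:1)
  m
}

row_max <- function(...) do.call(pmax, list(...))

pct <- function(x) 100 * mean(x)

percentile_ci <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  q <- quantile(x, c(a, 1 - a), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

# Evaluate code with a local, restorable RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% 2147483629L)
  force(code)
}
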