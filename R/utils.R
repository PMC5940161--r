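# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Round-half-up at `digits` decimals (base round() is round-half-even).
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 0.5 + 1e-9) / s
}

# Truncate toward zero at `digits` decimals (x assumed >= 0).
trunc_decimal <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 1e-9) / s
}

# Random DNA strings with a given GC content.
random_dna <- function(n, length, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw one element of x; immune to base sample()'s scalar expansion.
sample1 <- function(x) x[sample.int(length(x), 1L)]
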