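# Shared fixtures: the toy complex is deterministic per seed, but caching
# one instance keeps the suite fast.
.fixture_env <- new.env(parent = emptyenv())

toy_fixture <- function(seed = 1) {
  key <- paste0("toy", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- make_toy_complex(seed = seed)
  }
  .fixture_env[[key]]
}

# A small random blob of C/N/O atoms, used where tests need an arbitrary
# model with realistic elements.
random_model <- function(n = 50, seed = 1, spread = 12) {
  set.seed(seed)
  elems <- sample(c("C", "N", "O"), n, replace = TRUE)
  atomic_model(data.frame(
    serial = seq_len(n), name = paste0("X", seq_len(n)), elem = elems,
    resno = seq_len(n), resname = "ALA", chain = "A",
    x = runif(n, -spread, spread), y = runif(n, -spread, spread),
    z = runif(n, -spread, spread)
  ), roles = c(A = "protein"))
}

# Independent naive Debye oracle: explicit double loop over atom pairs
# (vectorized only over q), sharing no code with the package paths.
naive_debye <- function(model, q) {
  xyz <- coords(model)
  ff <- form_factors(model$atoms$elem, q)
  n <- nrow(xyz)
  I <- numeric(length(q))
  for (i in seq_len(n)) {
    I <- I + ff[, i]^2
    for (j in seq_len(n)) {
      if (j == i) next
      r <- sqrt(sum((xyz[i, ] - xyz[j, ]) ^ 2))
      x <- q * r
      s <- ifelse(x == 0, 1, sin(x) / ifelse(x == 0, 1, x))
      I <- I + ff[, i] * ff[, j] * s
    }
  }
  I
}
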