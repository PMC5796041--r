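# Shared fixtures: one reference scorer and one completed block library,
# built once per test run (library construction is fast and deterministic).

fixture_model <- disorder_model()
fixture_params <- design_params()
fixture_library <- build_block_library(fixture_model, fixture_params,
                                       seed = 101L)

# Independent naive scorer: recomputes every neighbourhood and smoothing
# window from scratch with explicit loops; used as the oracle for the
# vectorized implementation.
naive_score_profile <- function(sequence, model) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(aa)
  M <- model$energy_matrix
  raw <- numeric(n)
  for (i in seq_len(n)) {
    vals <- numeric(0)
    for (j in seq_len(n)) {
      s <- abs(i - j)
      if (s >= model$neighborhood_min && s <= model$neighborhood_max)
        vals <- c(vals, M[aa[i], aa[j]])
    }
    e <- if (length(vals) > 0L) mean(vals) else M[aa[i], aa[i]]
    raw[i] <- 1 / (1 + exp(-(e - model$transform_midpoint) /
                             model$transform_slope))
  }
  out <- numeric(n)
  half <- (model$smoothing_window - 1L) %/% 2L
  for (i in seq_len(n)) {
    w <- max(1L, i - half):min(n, i + half)
    out[i] <- mean(raw[w])
  }
  out
}

# constant-profile scorer stub (function-contract scorer)
constant_scorer <- function(value) {
  function(sequence) rep(value, nchar(sequence))
}

random_sequence <- function(n, alphabet = AA_BLOCK) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
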