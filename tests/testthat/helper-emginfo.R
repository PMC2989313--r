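# Shared fixtures and independent oracles, all built in code.

# Independent mutual-information oracle: symmetric double sum
# sum_{s,r} P(s,r) log2( P(s,r) / (P(s) P(r)) ), written without reusing any
# package code path.
mi_oracle <- function(P) {
  ps <- rowSums(P)
  pr <- colSums(P)
  total <- 0
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(ncol(P))) {
      if (P[i, j] > 0) {
        total <- total + P[i, j] * log2(P[i, j] / (ps[i] * pr[j]))
      }
    }
  }
  total
}

# Random joint probability matrix with a sprinkling of structural zeros.
random_joint <- function(nr, nc, zero_frac = 0.3) {
  P <- matrix(stats::rexp(nr * nc), nr, nc)
  P[stats::runif(nr * nc) < zero_frac] <- 0
  if (sum(P) == 0) P[1, 1] <- 1
  # guarantee every row/column can still be empty; only total mass matters
  P / sum(P)
}

quick_static <- function(seed = 1, hold = 3, noise_floor = 0.05, ...) {
  generate_static_session(
    synth_params(seed = seed, noise_floor = noise_floor, ...),
    static_protocol(hold_duration = hold))
}

quick_dynamic <- function(seed = 1, n_cycles = 1, ...) {
  generate_dynamic_session(
    synth_params(seed = seed, ...),
    dynamic_protocol(n_cycles = n_cycles))
}

# Feature-series stub (the joint builders consume stimulus + value only).
fake_series <- function(stimulus, value,
                        direction = rep("abduction", length(value))) {
  data.frame(stimulus = stimulus, value = value, direction = direction,
             time_s = seq_along(value))
}
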