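# Independent brute-force oracles for the HMM recursions: sum / argmax over
# every state path of a short series, written without any shared code with
# the package's forward-backward or Viterbi implementations.

enum_paths <- function(T) {
  as.matrix(expand.grid(rep(list(1:2), T)))
}

# Exact likelihood by exhaustive enumeration over all 2^T paths.
brute_likelihood <- function(e, mu, sigma, A, pi0) {
  paths <- enum_paths(length(e))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- pi0[s[1]] * dnorm(e[1], mu[s[1]], sigma[s[1]])
    if (length(e) > 1)
      for (t in 2:length(e))
        p <- p * A[s[t - 1], s[t]] * dnorm(e[t], mu[s[t]], sigma[s[t]])
    total <- total + p
  }
  total
}

# Most probable path by exhaustive enumeration.
brute_viterbi <- function(e, mu, sigma, A, pi0) {
  paths <- enum_paths(length(e))
  best <- -Inf
  best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    lp <- log(pi0[s[1]]) + dnorm(e[1], mu[s[1]], sigma[s[1]], log = TRUE)
    if (length(e) > 1)
      for (t in 2:length(e))
        lp <- lp + log(A[s[t - 1], s[t]]) +
          dnorm(e[t], mu[s[t]], sigma[s[t]], log = TRUE)
    if (lp > best) { best <- lp; best_path <- s }
  }
  list(path = best_path, logprob = best)
}
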