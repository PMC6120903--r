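# Independent oracles used to freeze expected values; these never call the
# code paths they validate.

## exact inclusion probability of `target` in a sequential length-weighted
## draw of m distinct items, by full enumeration of ordered draws
oracle_inclusion_prob <- function(target, weights, m) {
  rec <- function(avail, m_left) {
    if (m_left == 0) return(0)
    tot <- sum(weights[avail])
    p <- 0
    for (i in avail) {
      pi <- weights[i] / tot
      p <- p + pi * (if (i == target) 1 else rec(setdiff(avail, i), m_left - 1))
    }
    p
  }
  rec(seq_along(weights), m)
}

## exact Poisson-binomial upper tail P(X >= k) for independent runs
oracle_poisbinom_tail <- function(pis, k) {
  if (k <= 0) return(1)
  dp <- c(1, rep(0, length(pis)))
  for (p in pis) {
    n <- length(dp)
    dp <- dp * (1 - p) + c(0, dp[-n]) * p
  }
  sum(dp[(k + 1):length(dp)])
}

## exact hotspot p-value for a target site given per-run distinct-site counts
oracle_hotspot_p <- function(target, weights, m_runs, k_obs) {
  if (k_obs == 0) return(1)
  pis <- vapply(m_runs, function(m) oracle_inclusion_prob(target, weights, m),
                numeric(1))
  oracle_poisbinom_tail(pis, k_obs)
}

## brute-force simulation of the planted shared-core + singleton-background
## model, returning the mean averaged frequency F (for expected_overlap_f)
oracle_expected_f_sim <- function(N, fix_probs, background_mean, n_sim = 20000) {
  f <- numeric(n_sim)
  keep <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    core_counts <- rbinom(length(fix_probs), N, fix_probs)
    B <- rpois(1, N * background_mean)
    t <- sum(core_counts) + B
    d <- sum(core_counts > 0) + B
    if (d > 0) { f[i] <- t / (N * d); keep[i] <- TRUE }
  }
  mean(f[keep])
}
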