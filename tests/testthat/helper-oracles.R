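# Shared fixtures and independent oracles used across the suite.

canonical_sets <- function() builtin_sets()

# Small session design (shared UML grid built once per test run).
small_design <- local({
  cache <- NULL
  function(trials_per_set = 10L, sets = builtin_sets()) {
    if (is.null(cache)) cache <<- uml_grid()
    session_design(trials_per_set = trials_per_set, sets = sets,
                   grid = cache)
  }
})

# Binary responses from a known logistic psychometric observer.
logistic_responder <- function(alpha, beta, lambda = 0) {
  function(x) {
    stats::rbinom(1, 1, psychometric_probability(x, alpha, beta, lambda))
  }
}

# Independent oracle for the harmonic model's predicted PSE on a
# 2-interval toy set: direct numerical integration. The perceived
# intervals are truncated normals T_i ~ N(mu_i, mu_i * w_f) on (0, Inf);
# the median of H = 2 / (1/T1 + 1/T2) is computed as a weighted quantile
# over a fine product quadrature grid (no Monte Carlo involved).
harmonic_median_oracle <- function(mu, w_f, n_grid = 1200L) {
  stopifnot(length(mu) == 2L)
  sd <- mu * w_f
  nodes <- function(m, s) {
    lo <- max(m - 6 * s, 1e-9)
    hi <- m + 6 * s
    seq(lo, hi, length.out = n_grid)
  }
  t1 <- nodes(mu[1], sd[1])
  t2 <- nodes(mu[2], sd[2])
  # truncated-normal weights, renormalized on the grid
  w1 <- stats::dnorm(t1, mu[1], sd[1])
  w2 <- stats::dnorm(t2, mu[2], sd[2])
  w1 <- w1 / sum(w1)
  w2 <- w2 / sum(w2)
  h <- 2 / outer(1 / t1, 1 / t2, `+`)
  w <- outer(w1, w2)
  ord <- order(h)
  cum <- cumsum(w[ord])
  h[ord][which(cum >= 0.5)[1]]
}

# Weighted-quantile helper for Monte-Carlo standard errors of a median:
# batch-means estimate from b batches.
median_mc_se <- function(draws, b = 100L) {
  n <- length(draws)
  per <- n %/% b
  meds <- vapply(seq_len(b), function(i) {
    stats::median(draws[((i - 1) * per + 1):(i * per)])
  }, 0)
  stats::sd(meds) / sqrt(b)
}
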