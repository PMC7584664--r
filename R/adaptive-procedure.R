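# Updated-maximum-likelihood (UML) adaptive procedure.
#
# A discretized joint posterior over the threshold (alpha, ms), slope
# (beta, 1/ms) and lapse rate (lambda) of a logistic psychometric function
# is updated after every binary response, and the next comparison stimulus
# is placed to minimize the expected posterior variance of the threshold.
# This is a functional reimplementation of the UML idea (psi-method style
# one-step-ahead stimulus selection), not a bit-exact port of any toolbox.
#
# Performance notes: all posterior math is in log space; the Bernoulli
# likelihood of every candidate stimulus at every grid node is precomputed
# once per grid object, and the lapse dimension is marginalized analytically
# in the stimulus-selection step (p = lambda/2 + (1-lambda)*L factorizes),
# so one trial costs three small matrix-vector products.

#' Lapse-augmented logistic psychometric function
#'
#' Probability of a "comparison longer" response at stimulus `x`:
#' `lambda/2 + (1 - lambda) / (1 + exp(-(x - alpha) * beta))`. The lapse
#' rate `lambda` flattens both asymptotes symmetrically, bounding the
#' probability in `[lambda/2, 1 - lambda/2]`.
#'
#' @param x Stimulus (comparison duration, ms); vectorized.
#' @param alpha Threshold in ms (the PSE).
#' @param beta Slope in 1/ms; must be positive.
#' @param lambda Lapse rate in `[0, 0.5)`.
#' @return Response probability, same length as the broadcast arguments.
#' @examples
#' psychometric_probability(700, 700, 0.01, 0)         # 0.5
#' psychometric_probability(700 + log(3) / 0.01, 700, 0.01, 0)  # 0.75
#' @export
psychometric_probability <- function(x, alpha, beta, lambda = 0) {
  if (any(beta <= 0)) stop_invalid("beta must be positive")
  if (any(lambda < 0 | lambda >= 0.5)) {
    stop_invalid("lambda must lie in [0, 0.5)")
  }
  lambda / 2 + (1 - lambda) * stats::plogis((x - alpha) * beta)
}

#' UML posterior grid
#'
#' Builds the discretized parameter grid and precomputes candidate-stimulus
#' likelihoods. Defaults: threshold alpha linear on [200, 1400] ms (61
#' nodes, spanning all set means); slope beta log-spaced on [0.002, 0.2]
#' per ms (41 nodes, covering plausible Weber fractions); lapse lambda 0 to
#' 0.2 in steps of 0.02 (11 nodes). Priors are flat on the grid (log-flat
#' for beta, since the nodes are log-spaced). Candidate stimuli are the
#' alpha grid clamped to `stimulus_range`.
#'
#' @param alpha_grid,beta_grid,lambda_grid Strictly increasing parameter
#'   grids.
#' @param candidates Candidate comparison stimuli in ms.
#' @param stimulus_range Allowed stimulus range in ms; candidates are
#'   clamped to it.
#' @param initial_stimulus First comparison duration of a fresh track (ms).
#' @return An object of class `uml_grid`.
#' @export
uml_grid <- function(alpha_grid = seq(200, 1400, length.out = 61),
                     beta_grid = exp(seq(log(0.002), log(0.2),
                                         length.out = 41)),
                     lambda_grid = seq(0, 0.2, by = 0.02),
                     candidates = NULL,
                     stimulus_range = c(100, 2000),
                     initial_stimulus = 500) {
  if (is.unsorted(alpha_grid, strictly = TRUE) ||
      is.unsorted(beta_grid, strictly = TRUE) ||
      is.unsorted(lambda_grid, strictly = TRUE)) {
    stop_invalid("parameter grids must be strictly increasing")
  }
  if (any(beta_grid <= 0) || any(lambda_grid < 0 | lambda_grid >= 0.5)) {
    stop_invalid("beta grid must be positive, lambda grid within [0, 0.5)")
  }
  if (is.null(candidates)) candidates <- alpha_grid
  candidates <- sort(unique(pmin(pmax(candidates, stimulus_range[1]),
                                 stimulus_range[2])))
  na <- length(alpha_grid)
  nb <- length(beta_grid)
  nl <- length(lambda_grid)
  nab <- na * nb
  alpha_ab <- rep(alpha_grid, times = nb)
  beta_ab <- rep(beta_grid, each = na)
  # logistic part at every (alpha, beta) node for every candidate stimulus
  lmat <- stats::plogis(
    (rep(candidates, each = nab) - alpha_ab) * beta_ab
  )
  dim(lmat) <- c(nab, length(candidates))
  lambda_full <- rep(lambda_grid, each = nab)
  p_full <- lambda_full / 2 + (1 - lambda_full) *
    lmat[rep(seq_len(nab), times = nl), , drop = FALSE]
  g <- list(
    alpha_grid = alpha_grid, beta_grid = beta_grid,
    lambda_grid = lambda_grid,
    candidates = candidates, stimulus_range = stimulus_range,
    initial_stimulus = initial_stimulus,
    n_alpha = na, n_beta = nb, n_lambda = nl, n_ab = nab,
    n_nodes = nab * nl,
    alpha_ab = alpha_ab, beta_ab = beta_ab,
    alpha_full = rep(alpha_ab, times = nl),
    log_beta_full = rep(log(beta_ab), times = nl),
    lambda_full = lambda_full,
    L = lmat,
    logP1 = log(p_full),
    logP0 = log1p(-p_full)
  )
  class(g) <- "uml_grid"
  g
}

#' Fresh UML track
#'
#' A track holds the (log) posterior over the grid, the stimulus/response
#' history, and per-trial parameter-estimate traces.
#'
#' @param grid A [uml_grid()]; built with defaults when omitted.
#' @return An object of class `uml_track`.
#' @examples
#' tr <- uml_track()
#' select_next_stimulus(tr)  # 500, the initial comparison
#' @export
uml_track <- function(grid = uml_grid()) {
  stopifnot(inherits(grid, "uml_grid"))
  structure(
    list(
      grid = grid,
      log_posterior = rep(-log(grid$n_nodes), grid$n_nodes),
      stimulus = numeric(0),
      response = integer(0),
      alpha_trace = numeric(0),
      beta_trace = numeric(0),
      lambda_trace = numeric(0)
    ),
    class = "uml_track"
  )
}

#' @export
print.uml_track <- function(x, ...) {
  est <- estimate_parameters(x)
  cat(sprintf(
    "<uml_track> %d trials; alpha_hat=%.1f ms, beta_hat=%.4g /ms, lambda_hat=%.3f\n",
    length(x$stimulus), est[["alpha"]], est[["beta"]], est[["lambda"]]
  ))
  invisible(x)
}

posterior_mass <- function(track) {
  if (!is.null(track$mass)) return(track$mass)
  lp <- track$log_posterior
  m <- exp(lp - max(lp))
  m / sum(m)
}

#' Normalized posterior grid of a track
#'
#' @param track A [uml_track()].
#' @return List with the three parameter grids and the posterior probability
#'   array of dimension (alpha, beta, lambda); the array sums to 1.
#' @export
posterior_grid <- function(track) {
  g <- track$grid
  m <- posterior_mass(track)
  dim(m) <- c(g$n_alpha, g$n_beta, g$n_lambda)
  list(
    alpha_grid = g$alpha_grid, beta_grid = g$beta_grid,
    lambda_grid = g$lambda_grid, posterior = m
  )
}

#' Bayesian posterior update after one response
#'
#' Multiplies the posterior by the Bernoulli likelihood of the observed
#' response at every grid node and renormalizes (in log space). The
#' stimulus/response pair and the updated posterior-mean estimates are
#' appended to the track's history.
#'
#' @param track A [uml_track()].
#' @param stimulus_ms Comparison duration presented (ms).
#' @param response 1 if "comparison longer", 0 otherwise.
#' @return The updated `uml_track`.
#' @export
update_posterior <- function(track, stimulus_ms, response) {
  stopifnot(inherits(track, "uml_track"))
  response <- as.integer(response)
  if (!response %in% c(0L, 1L)) stop_invalid("response must be 0 or 1")
  g <- track$grid
  ci <- match(stimulus_ms, g$candidates)
  if (!is.na(ci)) {
    ll <- if (response == 1L) g$logP1[, ci] else g$logP0[, ci]
  } else {
    p <- g$lambda_full / 2 + (1 - g$lambda_full) *
      stats::plogis((stimulus_ms - g$alpha_full) * exp(g$log_beta_full))
    ll <- if (response == 1L) log(p) else log1p(-p)
  }
  lp <- track$log_posterior + ll
  mx <- max(lp)
  if (!is.finite(mx)) {
    stop_numerical("posterior lost all mass (degenerate update)")
  }
  w <- exp(lp - mx)
  total <- sum(w)
  track$log_posterior <- lp - mx - log(total)
  m <- w / total
  track$mass <- m  # cached normalized posterior, reused by selection
  track$stimulus <- c(track$stimulus, stimulus_ms)
  track$response <- c(track$response, response)
  track$alpha_trace <- c(track$alpha_trace, sum(m * g$alpha_full))
  track$beta_trace <- c(track$beta_trace, exp(sum(m * g$log_beta_full)))
  track$lambda_trace <- c(track$lambda_trace, sum(m * g$lambda_full))
  track
}

#' Adaptive stimulus selection
#'
#' In `"variance-min"` mode (the default), returns the candidate stimulus
#' minimizing the one-step-ahead expected posterior variance of the
#' threshold alpha, averaging over the two possible responses; ties go to
#' the smallest candidate so reruns are deterministic. In `"sweep"` mode,
#' cycles through stimuli at posterior quantiles of alpha
#' (50%, 10%, 90%, 30%, 70%). A fresh track always receives the configured
#' initial comparison (500 ms by default). Results are clamped to the
#' grid's stimulus range.
#'
#' @param track A [uml_track()].
#' @param mode `"variance-min"` or `"sweep"`.
#' @return Next comparison duration in ms.
#' @export
select_next_stimulus <- function(track, mode = c("variance-min", "sweep")) {
  stopifnot(inherits(track, "uml_track"))
  mode <- match.arg(mode)
  g <- track$grid
  if (length(track$stimulus) == 0L) {
    return(min(max(g$initial_stimulus, g$stimulus_range[1]),
               g$stimulus_range[2]))
  }
  m <- posterior_mass(track)
  if (mode == "sweep") {
    probs <- c(0.5, 0.1, 0.9, 0.3, 0.7)
    prob <- probs[(length(track$stimulus) %% length(probs)) + 1L]
    dim(m) <- c(g$n_ab, g$n_lambda)
    alpha_marg <- rowsum(rowSums(m), group = g$alpha_ab)
    cum <- cumsum(alpha_marg[, 1])
    x <- g$alpha_grid[which(cum >= prob)[1]]
    return(min(max(x, g$stimulus_range[1]), g$stimulus_range[2]))
  }
  # Marginalize lambda: p = lambda/2 + (1 - lambda) * L(alpha, beta).
  dim(m) <- c(g$n_ab, g$n_lambda)
  wl <- 1 - g$lambda_grid
  a0 <- as.vector(m %*% wl)              # sum_l (1-l) m(ab, l)
  a1 <- a0 * g$alpha_ab
  a2 <- a1 * g$alpha_ab
  rs <- rowSums(m)
  # t_j = sum over nodes of m * (lambda/2) * alpha^j; since
  # sum_l lambda * m(ab, l) = rs - a0, these reduce to sums over ab nodes.
  t0 <- sum(rs - a0) / 2
  t1 <- sum((rs - a0) * g$alpha_ab) / 2
  t2 <- sum((rs - a0) * g$alpha_ab^2) / 2
  qs <- crossprod(g$L, cbind(a0, a1, a2))
  q1 <- t0 + qs[, 1]
  s1 <- t1 + qs[, 2]
  s2 <- t2 + qs[, 3]
  tot1 <- sum(rs * g$alpha_ab)
  tot2 <- sum(rs * g$alpha_ab^2)
  q0 <- 1 - q1
  s1_0 <- tot1 - s1
  s2_0 <- tot2 - s2
  eps <- 1e-12
  exp_var <- (s2 - s1^2 / pmax(q1, eps)) + (s2_0 - s1_0^2 / pmax(q0, eps))
  x <- g$candidates[which.min(exp_var)]  # which.min -> first = smallest
  min(max(x, g$stimulus_range[1]), g$stimulus_range[2])
}

#' Posterior-mean parameter estimates
#'
#' Posterior means of threshold, slope and lapse; the slope is averaged in
#' log space (its grid is log-spaced). On a fresh track this returns the
#' prior means.
#'
#' @param track A [uml_track()].
#' @return Named numeric vector `c(alpha, beta, lambda)`.
#' @export
estimate_parameters <- function(track) {
  stopifnot(inherits(track, "uml_track"))
  g <- track$grid
  m <- posterior_mass(track)
  c(
    alpha = sum(m * g$alpha_full),
    beta = exp(sum(m * g$log_beta_full)),
    lambda = sum(m * g$lambda_full)
  )
}

#' Run one adaptive track against a response-generating function
#'
#' Convenience driver: repeatedly selects the next stimulus, queries
#' `respond(stimulus_ms)` for a binary response, and updates the posterior.
#'
#' @param n_trials Number of trials.
#' @param respond Function of one argument (stimulus in ms) returning 0/1.
#' @param grid A [uml_grid()].
#' @param mode Stimulus-selection mode, see [select_next_stimulus()].
#' @return The final `uml_track` (history and estimate traces included).
#' @export
run_uml_track <- function(n_trials, respond, grid = uml_grid(),
                          mode = "variance-min") {
  track <- uml_track(grid)
  for (i in seq_len(n_trials)) {
    x <- select_next_stimulus(track, mode = mode)
    track <- update_posterior(track, x, respond(x))
  }
  track
}

#' Per-trial estimate trace of a track
#'
#' @param track A [uml_track()].
#' @return Data frame with one row per trial: `trial`, `stimulus_ms`,
#'   `response`, `alpha_hat`, `beta_hat`, `lambda_hat`. Writable as CSV to
#'   mirror a threshold-convergence plot.
#' @export
uml_trace <- function(track) {
  stopifnot(inherits(track, "uml_track"))
  data.frame(
    trial = seq_along(track$stimulus),
    stimulus_ms = track$stimulus,
    response = track$response,
    alpha_hat = track$alpha_trace,
    beta_hat = track$beta_trace,
    lambda_hat = track$lambda_trace
  )
}

#' Checkpoint a UML track to JSON (and restore it)
#'
#' Serializes the grid specification, the log posterior, and the history;
#' the precomputed likelihood tables are rebuilt on load.
#'
#' @param track A [uml_track()].
#' @param path File path.
#' @return `uml_save_track` returns `path` invisibly; `uml_load_track`
#'   returns the restored `uml_track`.
#' @export
uml_save_track <- function(track, path) {
  stopifnot(inherits(track, "uml_track"))
  g <- track$grid
  payload <- list(
    grid = list(
      alpha_grid = g$alpha_grid, beta_grid = g$beta_grid,
      lambda_grid = g$lambda_grid, candidates = g$candidates,
      stimulus_range = g$stimulus_range,
      initial_stimulus = g$initial_stimulus
    ),
    log_posterior = track$log_posterior,
    stimulus = track$stimulus,
    response = track$response,
    alpha_trace = track$alpha_trace,
    beta_trace = track$beta_trace,
    lambda_trace = track$lambda_trace
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname uml_save_track
#' @export
uml_load_track <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- payload$grid
  grid <- uml_grid(
    alpha_grid = g$alpha_grid, beta_grid = g$beta_grid,
    lambda_grid = g$lambda_grid, candidates = g$candidates,
    stimulus_range = g$stimulus_range,
    initial_stimulus = g$initial_stimulus
  )
  track <- uml_track(grid)
  track$log_posterior <- payload$log_posterior
  track$stimulus <- as.numeric(payload$stimulus)
  track$response <- as.integer(payload$response)
  track$alpha_trace <- as.numeric(payload$alpha_trace)
  track$beta_trace <- as.numeric(payload$beta_trace)
  track$lambda_trace <- as.numeric(payload$lambda_trace)
  track
}
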