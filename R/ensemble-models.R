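# Ensemble-averaging schemes for sets of time intervals, their noisy
# generative versions, and model-predicted points of subjective equality
# (PSEs).
#
# Four candidate schemes are modeled. On a linear internal timeline each
# perceived interval T_i is corrupted by scalar noise,
#   T_i ~ N(mu_i, mu_i * w_f),
# and averaged arithmetically, harmonically, or with duration-proportional
# weights. On a logarithmic timeline the intervals are log-encoded with
# constant log-noise,
#   log(T_i) ~ N(log(mu_i), sigma_t),
# averaged in log space, biased, and exponentiated back; the noise-free
# readout is then the geometric mean. A general bias B ~ N(mu_b, sigma) is
# added to every ensemble average (in log units for the geometric scheme,
# in ms otherwise).

AVERAGING_SCHEMES <- c("arithmetic", "geometric", "weighted", "harmonic")

#' Interval set
#'
#' An identified ensemble of base interval durations (the stimulus set whose
#' average the observer judges).
#'
#' @param set_id Short label, e.g. `"set1"`.
#' @param intervals Numeric vector of base durations in ms; all strictly
#'   positive, length at least 2.
#'
#' @return An object of class `interval_set` with fields `set_id` and
#'   `intervals`.
#' @examples
#' interval_set("set1", c(300, 550, 800, 1050, 1300))
#' @export
interval_set <- function(set_id, intervals) {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 2L) {
    stop_invalid("an interval set needs at least 2 intervals")
  }
  if (any(!is.finite(intervals)) || any(intervals <= 0)) {
    stop_invalid("all intervals must be finite and strictly positive")
  }
  structure(
    list(set_id = as.character(set_id), intervals = intervals),
    class = "interval_set"
  )
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf(
    "<interval_set '%s'> %s ms (AM %.1f, GM %.1f)\n",
    x$set_id, paste(x$intervals, collapse = ", "),
    arithmetic_mean(x$intervals), geometric_mean(x$intervals)
  ))
  invisible(x)
}

#' The three canonical interval sets
#'
#' The three five-interval sets used throughout: sets 1 and 2 share the same
#' arithmetic mean (800 ms), sets 1 and 3 share (nearly) the same geometric
#' mean (710 ms), so the linear and logarithmic accounts make distinct
#' predictions across the triplet.
#'
#' @return A named list of three [interval_set()] objects
#'   (`set1`, `set2`, `set3`).
#' @examples
#' sapply(builtin_sets(), function(s) arithmetic_mean(s$intervals))
#' @export
builtin_sets <- function() {
  list(
    set1 = interval_set("set1", c(300, 550, 800, 1050, 1300)),
    set2 = interval_set("set2", c(600, 700, 800, 900, 1000)),
    set3 = interval_set("set3", c(500, 610, 730, 840, 950))
  )
}

#' Virtual observer parameters
#'
#' Generative parameters of a simulated observer performing ensemble
#' averaging of intervals.
#'
#' @param scheme Averaging scheme, one of `"arithmetic"`, `"geometric"`,
#'   `"weighted"`, `"harmonic"`.
#' @param weber_fraction Weber fraction `w_f >= 0` of the scalar noise
#'   (linear-scale schemes): each interval is perceived as
#'   `T_i ~ N(mu_i, mu_i * w_f)`, truncated to positive durations.
#' @param log_noise_sd Log-space noise SD `sigma_t >= 0` (geometric scheme):
#'   `log(T_i) ~ N(log(mu_i), sigma_t)`.
#' @param bias_mean Mean `mu_b` of the general bias added to the ensemble
#'   average: in log units for the geometric scheme (so -0.04 is about a 4%
#'   shortening), in ms otherwise.
#' @param bias_sd SD `sigma >= 0` of the bias, same units as `bias_mean`.
#' @param lapse_rate Probability in `[0, 0.5)` that a response is a
#'   stimulus-independent coin flip.
#' @param rng_seed Optional integer seed attached to the observer; used by
#'   [simulate_session()] when no explicit seed is given.
#'
#' @return An object of class `observer_params`.
#' @examples
#' observer_params("geometric", log_noise_sd = 0.15, bias_mean = -0.04)
#' @export
observer_params <- function(scheme,
                            weber_fraction = 0,
                            log_noise_sd = 0,
                            bias_mean = 0,
                            bias_sd = 0,
                            lapse_rate = 0,
                            rng_seed = NULL) {
  scheme <- match.arg(scheme, AVERAGING_SCHEMES)
  if (weber_fraction < 0 || log_noise_sd < 0 || bias_sd < 0) {
    stop_invalid("noise and sd parameters must be non-negative")
  }
  if (lapse_rate < 0 || lapse_rate >= 0.5) {
    stop_invalid("lapse_rate must lie in [0, 0.5)")
  }
  structure(
    list(
      scheme = scheme,
      weber_fraction = weber_fraction,
      log_noise_sd = log_noise_sd,
      bias_mean = bias_mean,
      bias_sd = bias_sd,
      lapse_rate = lapse_rate,
      rng_seed = rng_seed
    ),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "<observer_params> scheme=%s w_f=%g sigma_t=%g mu_b=%g sigma=%g lapse=%g\n",
    x$scheme, x$weber_fraction, x$log_noise_sd, x$bias_mean, x$bias_sd,
    x$lapse_rate
  ))
  invisible(x)
}

check_positive_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop_invalid("empty value list")
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop_invalid("all values must be finite and strictly positive")
  }
  values
}

#' Ensemble-averaging schemes
#'
#' The four candidate summary statistics of an interval ensemble:
#' `arithmetic_mean` is `sum(x)/n`; `geometric_mean` is
#' `exp(mean(log(x)))`, the noise-free readout of averaging on a
#' logarithmic timeline; `harmonic_mean` is `n / sum(1/x)`, the average
#' under reciprocal (short-interval-favoring) weighting; `weighted_mean`
#' weights every value by its relative magnitude within the set,
#' `sum(x^2) / sum(x)`. For any non-constant positive input,
#' harmonic < geometric < arithmetic <= weighted.
#'
#' @param values Numeric vector of strictly positive values (durations
#'   in ms).
#'
#' @return The scheme's mean, in the units of `values`.
#' @examples
#' s1 <- c(300, 550, 800, 1050, 1300)
#' arithmetic_mean(s1)  # 800
#' geometric_mean(s1)   # 709.8
#' harmonic_mean(s1)    # 615.5
#' weighted_mean(s1)    # 956.25
#' @export
arithmetic_mean <- function(values) {
  mean(check_positive_values(values))
}

#' @rdname arithmetic_mean
#' @export
geometric_mean <- function(values) {
  exp(mean(log(check_positive_values(values))))
}

#' @rdname arithmetic_mean
#' @export
harmonic_mean <- function(values) {
  values <- check_positive_values(values)
  length(values) / sum(1 / values)
}

#' @rdname arithmetic_mean
#' @export
weighted_mean <- function(values) {
  values <- check_positive_values(values)
  sum(values^2) / sum(values)
}

scheme_mean <- function(scheme, values) {
  switch(scheme,
    arithmetic = arithmetic_mean(values),
    geometric = geometric_mean(values),
    weighted = weighted_mean(values),
    harmonic = harmonic_mean(values),
    stop_invalid(sprintf("unknown scheme '%s'", scheme))
  )
}

#' Noise-free model prediction for an interval set
#'
#' The scheme mean of the base durations with the deterministic part of the
#' bias applied: `mean + mu_b` in ms for linear-scale schemes,
#' `GM * exp(mu_b)` for the geometric scheme.
#'
#' @param set An [interval_set()].
#' @param scheme Averaging scheme.
#' @param bias_mean Bias `mu_b` (log units for geometric, ms otherwise).
#' @return Predicted PSE in ms.
#' @export
noise_free_prediction <- function(set, scheme, bias_mean = 0) {
  scheme <- match.arg(scheme, AVERAGING_SCHEMES)
  m <- scheme_mean(scheme, set$intervals)
  if (scheme == "geometric") m * exp(bias_mean) else m + bias_mean
}

# Scalar-noise draws truncated to positive durations by resampling.
# Returns an n x length(mu) matrix of perceived intervals.
draw_scalar_intervals <- function(mu, weber_fraction, n) {
  k <- length(mu)
  t_mat <- matrix(
    stats::rnorm(n * k, mean = rep(mu, each = n),
                 sd = rep(mu * weber_fraction, each = n)),
    nrow = n, ncol = k
  )
  bad <- which(t_mat <= 0)
  while (length(bad) > 0L) {
    col <- (bad - 1L) %/% n + 1L
    t_mat[bad] <- stats::rnorm(length(bad), mu[col], mu[col] * weber_fraction)
    bad <- bad[t_mat[bad] <= 0]
  }
  t_mat
}

#' Sample noisy ensemble averages
#'
#' Draws `n` realizations of an observer's internal ensemble average for one
#' interval set. Linear-scale schemes perceive each interval with scalar
#' noise `T_i ~ N(mu_i, mu_i * w_f)` (truncated positive), average per the
#' scheme, and add a bias draw `B ~ N(mu_b, sigma)` in ms. The geometric
#' scheme averages log-scale draws `log(T_i) ~ N(log(mu_i), sigma_t)`, adds
#' the bias in log space, and exponentiates. Uses R's global RNG; seed with
#' `set.seed()` for reproducibility.
#'
#' @param set An [interval_set()].
#' @param obs An [observer_params()].
#' @param n Number of draws.
#' @return Numeric vector of `n` ensemble averages in ms.
#' @examples
#' set.seed(1)
#' s1 <- builtin_sets()$set1
#' obs <- observer_params("geometric", log_noise_sd = 0.15)
#' median(sample_ensemble_average(s1, obs, 1e4))  # close to GM = 709.8
#' @export
sample_ensemble_average <- function(set, obs, n = 1L) {
  stopifnot(inherits(set, "interval_set"), inherits(obs, "observer_params"))
  n <- as.integer(n)
  if (n < 1L) stop_invalid("n must be >= 1")
  mu <- set$intervals
  k <- length(mu)
  bias <- if (obs$bias_sd > 0) {
    stats::rnorm(n, obs$bias_mean, obs$bias_sd)
  } else {
    rep(obs$bias_mean, n)
  }
  if (obs$scheme == "geometric") {
    logs <- matrix(
      stats::rnorm(n * k, mean = rep(log(mu), each = n), sd = obs$log_noise_sd),
      nrow = n, ncol = k
    )
    return(exp(rowMeans(logs) + bias))
  }
  t_mat <- draw_scalar_intervals(mu, obs$weber_fraction, n)
  avg <- switch(obs$scheme,
    arithmetic = rowMeans(t_mat),
    weighted = as.vector(t_mat %*% (mu / sum(mu))),
    harmonic = k / rowSums(1 / t_mat)
  )
  avg + bias
}

#' Model-predicted PSE for an interval set
#'
#' The model's predicted point of subjective equality: the median of the
#' distribution of internal ensemble averages (the stimulus at which the
#' comparison is judged longer on half the trials). With all noise
#' parameters zero, the closed form is returned (scheme mean plus bias, or
#' `GM * exp(mu_b)` for the geometric scheme); otherwise the median of
#' `n_sim` Monte-Carlo draws. Under the median convention the noise
#' parameters leave the arithmetic, geometric, and weighted predictions
#' unchanged; only the harmonic prediction depends on them.
#'
#' @param set An [interval_set()].
#' @param obs An [observer_params()].
#' @param n_sim Number of simulation rounds (default 100,000).
#' @return Predicted PSE in ms.
#' @examples
#' s <- builtin_sets()
#' obs <- observer_params("geometric", bias_mean = -0.04)
#' predict_pse(s$set1, obs)  # 709.8 * exp(-0.04)
#' @export
predict_pse <- function(set, obs, n_sim = 100000L) {
  stopifnot(inherits(set, "interval_set"), inherits(obs, "observer_params"))
  if (n_sim < 1) stop_invalid("n_sim must be >= 1")
  noise_free <- obs$bias_sd == 0 &&
    ((obs$scheme == "geometric" && obs$log_noise_sd == 0) ||
       (obs$scheme != "geometric" && obs$weber_fraction == 0))
  if (noise_free) {
    return(noise_free_prediction(set, obs$scheme, obs$bias_mean))
  }
  stats::median(sample_ensemble_average(set, obs, n_sim))
}
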