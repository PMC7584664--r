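# Synthetic-data generator: complete two-phase comparison sessions for
# virtual observers. Each trial presents a random permutation of one set's
# five intervals, the observer forms a noisy internal ensemble average
# under its averaging scheme, and judges whether an adaptively chosen
# comparison interval is longer. Three per-set adaptive tracks run
# concurrently with randomly interleaved set order.

#' Session design
#'
#' @param trials_per_set Trials per interval set (80 in the canonical
#'   design).
#' @param sets List of [interval_set()] objects (default: the three
#'   canonical sets).
#' @param initial_comparison_ms First comparison duration of every adaptive
#'   track (500 ms).
#' @param grid Optional [uml_grid()] shared by all tracks; built once with
#'   `initial_stimulus = initial_comparison_ms` when omitted.
#' @return Object of class `session_design`.
#' @export
session_design <- function(trials_per_set = 80L,
                           sets = builtin_sets(),
                           initial_comparison_ms = 500,
                           grid = NULL) {
  trials_per_set <- as.integer(trials_per_set)
  if (trials_per_set < 1L) stop_invalid("trials_per_set must be >= 1")
  if (length(sets) < 1L || !all(vapply(sets, inherits, TRUE, "interval_set"))) {
    stop_invalid("sets must be a non-empty list of interval_set objects")
  }
  names(sets) <- vapply(sets, `[[`, "", "set_id")
  if (anyDuplicated(names(sets))) stop_invalid("set ids must be unique")
  if (is.null(grid)) {
    grid <- uml_grid(initial_stimulus = initial_comparison_ms)
  }
  structure(
    list(
      trials_per_set = trials_per_set, sets = sets,
      initial_comparison_ms = initial_comparison_ms, grid = grid
    ),
    class = "session_design"
  )
}

#' Simulate one binary comparison response
#'
#' With probability `lapse_rate` the response is a fair coin flip;
#' otherwise the observer draws one internal ensemble average and responds
#' 1 ("comparison longer") iff `comparison_ms` exceeds it.
#'
#' @param set An [interval_set()].
#' @param comparison_ms Comparison duration in ms (> 0).
#' @param obs An [observer_params()].
#' @return List with `response` (0/1) and `internal_average_ms` (the latent
#'   draw; `NA` on lapse trials).
#' @export
simulate_response <- function(set, comparison_ms, obs) {
  if (comparison_ms <= 0) stop_invalid("comparison_ms must be positive")
  if (obs$lapse_rate > 0 && stats::runif(1) < obs$lapse_rate) {
    return(list(response = as.integer(stats::runif(1) < 0.5),
                internal_average_ms = NA_real_))
  }
  avg <- sample_ensemble_average(set, obs, 1L)
  list(response = as.integer(comparison_ms > avg), internal_average_ms = avg)
}

#' Simulate a full adaptive session for one observer
#'
#' Runs one UML track per interval set; on every trial the set is drawn
#' uniformly without replacement from the remaining trial budgets (so all
#' tracks finish together), a fresh random permutation of the set's
#' intervals is presented, and the track's adaptively selected comparison
#' is judged. Fully reproducible given `seed`.
#'
#' @param obs An [observer_params()].
#' @param design A [session_design()].
#' @param seed Integer seed; defaults to `obs$rng_seed`. `NULL` leaves the
#'   global RNG untouched.
#' @param observer_id Label copied into the trial records.
#' @return List with `trials` (data frame: one row per trial with columns
#'   `observer_id`, `trial_index`, `set_id`, `i1..ik` presented order,
#'   `comparison_ms`, `response`, `internal_average_ms`) and `tracks`
#'   (final `uml_track` per set).
#' @export
simulate_session <- function(obs, design = session_design(),
                             seed = obs$rng_seed, observer_id = "obs1") {
  stopifnot(inherits(obs, "observer_params"),
            inherits(design, "session_design"))
  if (!is.null(seed)) set.seed(seed)
  sets <- design$sets
  n_sets <- length(sets)
  k <- length(sets[[1]]$intervals)
  if (any(vapply(sets, function(s) length(s$intervals), 0L) != k)) {
    stop_invalid("all sets in a session must have the same size")
  }
  n_total <- design$trials_per_set * n_sets
  tracks <- lapply(sets, function(s) uml_track(design$grid))
  set_order <- sample(rep(seq_len(n_sets), each = design$trials_per_set))
  perm <- matrix(NA_real_, n_total, k)
  set_id <- character(n_total)
  comparison <- numeric(n_total)
  response <- integer(n_total)
  internal <- numeric(n_total)
  for (t in seq_len(n_total)) {
    si <- set_order[t]
    s <- sets[[si]]
    x <- select_next_stimulus(tracks[[si]])
    presented <- sample(s$intervals)
    r <- simulate_response(s, x, obs)
    tracks[[si]] <- update_posterior(tracks[[si]], x, r$response)
    set_id[t] <- s$set_id
    perm[t, ] <- presented
    comparison[t] <- x
    response[t] <- r$response
    internal[t] <- r$internal_average_ms
  }
  trials <- data.frame(
    observer_id = observer_id,
    trial_index = seq_len(n_total),
    set_id = set_id,
    stringsAsFactors = FALSE
  )
  perm_df <- as.data.frame(perm)
  names(perm_df) <- paste0("i", seq_len(k))
  trials <- cbind(trials, perm_df)
  trials$comparison_ms <- comparison
  trials$response <- response
  trials$internal_average_ms <- internal
  list(trials = trials, tracks = tracks)
}

# Largest-remainder apportionment of n among proportions p (named).
largest_remainder_counts <- function(n, p) {
  quota <- n * p
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    frac <- quota - counts
    # ties broken by position order (deterministic)
    top <- order(frac, decreasing = TRUE)[seq_len(short)]
    counts[top] <- counts[top] + 1
  }
  as.integer(counts)
}

#' Default observer-parameter ranges per scheme
#'
#' Uniform sampling ranges used by [generate_cohort()]: Weber fractions
#' 0.10-0.20 (typical interval-timing sensitivity), log-noise SD 0.10-0.20,
#' zero-mean bias with zero spread, lapse 0-0.05. Override any entry via
#' the `param_ranges` argument of [generate_cohort()].
#'
#' @return Named list of `c(min, max)` ranges.
#' @export
default_param_ranges <- function() {
  list(
    weber_fraction = c(0.10, 0.20),
    log_noise_sd = c(0.10, 0.20),
    bias_mean_ms = c(0, 0),      # linear-scale schemes
    bias_mean_log = c(0, 0),     # geometric scheme
    bias_sd = c(0, 0),
    lapse_rate = c(0, 0.05)
  )
}

runif_range <- function(r) stats::runif(1, r[1], r[2])

#' Generate a cohort of simulated observers
#'
#' Samples ground-truth observer parameters per scheme from `param_ranges`,
#' simulates a full adaptive session per observer, and returns both the
#' pooled trial table and the hidden ground truth for recovery tests.
#' Scheme counts follow largest-remainder rounding of `scheme_mix`.
#'
#' @param n_observers Number of observers (0 gives empty tables).
#' @param scheme_mix Named proportions over schemes, summing to 1.
#' @param param_ranges Named list of `c(min, max)` ranges, see
#'   [default_param_ranges()]; partial overrides are merged.
#' @param design A [session_design()].
#' @param seed Integer seed for the whole cohort.
#' @return List with `trials` (pooled trial data frame) and `ground_truth`
#'   (one row per observer: scheme and generative parameters).
#' @export
generate_cohort <- function(n_observers,
                            scheme_mix = c(geometric = 1),
                            param_ranges = list(),
                            design = session_design(),
                            seed = NULL) {
  n_observers <- as.integer(n_observers)
  if (n_observers < 0L) stop_invalid("n_observers must be >= 0")
  if (is.list(scheme_mix)) scheme_mix <- unlist(scheme_mix)
  if (is.null(names(scheme_mix)) ||
      !all(names(scheme_mix) %in% AVERAGING_SCHEMES)) {
    stop_invalid("scheme_mix must be named with valid schemes")
  }
  if (any(scheme_mix < 0) || abs(sum(scheme_mix) - 1) > 1e-8) {
    stop_invalid("scheme_mix proportions must be non-negative and sum to 1")
  }
  ranges <- utils::modifyList(default_param_ranges(), param_ranges)
  if (!is.null(seed)) set.seed(seed)
  counts <- largest_remainder_counts(n_observers, scheme_mix)
  schemes <- rep(names(scheme_mix), counts)
  gt <- vector("list", n_observers)
  all_trials <- vector("list", n_observers)
  for (i in seq_len(n_observers)) {
    scheme <- schemes[i]
    bias_range <- if (scheme == "geometric") {
      ranges$bias_mean_log
    } else {
      ranges$bias_mean_ms
    }
    obs <- observer_params(
      scheme = scheme,
      weber_fraction = runif_range(ranges$weber_fraction),
      log_noise_sd = runif_range(ranges$log_noise_sd),
      bias_mean = runif_range(bias_range),
      bias_sd = runif_range(ranges$bias_sd),
      lapse_rate = runif_range(ranges$lapse_rate)
    )
    oid <- sprintf("obs%02d", i)
    sess <- simulate_session(obs, design, seed = NULL, observer_id = oid)
    all_trials[[i]] <- sess$trials
    gt[[i]] <- data.frame(
      observer_id = oid, scheme = obs$scheme,
      weber_fraction = obs$weber_fraction,
      log_noise_sd = obs$log_noise_sd,
      bias_mean = obs$bias_mean, bias_sd = obs$bias_sd,
      lapse_rate = obs$lapse_rate,
      stringsAsFactors = FALSE
    )
  }
  if (n_observers == 0L) {
    return(list(trials = empty_trial_table(design),
                ground_truth = data.frame(
                  observer_id = character(0), scheme = character(0),
                  weber_fraction = numeric(0), log_noise_sd = numeric(0),
                  bias_mean = numeric(0), bias_sd = numeric(0),
                  lapse_rate = numeric(0)
                )))
  }
  list(
    trials = do.call(rbind, all_trials),
    ground_truth = do.call(rbind, gt)
  )
}

empty_trial_table <- function(design) {
  k <- length(design$sets[[1]]$intervals)
  cols <- c("observer_id", "trial_index", "set_id",
            paste0("i", seq_len(k)), "comparison_ms", "response",
            "internal_average_ms")
  df <- as.data.frame(
    stats::setNames(rep(list(numeric(0)), length(cols)), cols)
  )
  df$observer_id <- character(0)
  df$set_id <- character(0)
  df$response <- integer(0)
  df
}

#' Read and write trial tables
#'
#' The on-disk exchange format is a plain CSV with one row per trial and
#' columns `observer_id, trial_index, set_id, i1..ik, comparison_ms,
#' response` (plus `internal_average_ms` when the latent draw is kept).
#' Ground truth goes to a sidecar CSV keyed by `observer_id`.
#'
#' @param trials Trial data frame as produced by [simulate_session()] or
#'   [generate_cohort()].
#' @param path CSV file path.
#' @param keep_latent Keep the `internal_average_ms` column when writing?
#' @return `read_trials` returns the trial data frame; `write_trials`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path, keep_latent = FALSE) {
  if (!keep_latent) trials$internal_average_ms <- NULL
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("observer_id", "trial_index", "set_id", "comparison_ms",
            "response")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_invalid(paste("trial CSV lacks columns:",
                       paste(missing, collapse = ", ")))
  }
  df
}
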