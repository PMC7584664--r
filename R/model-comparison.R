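# Fitting the four ensemble-averaging models to observed per-set PSEs,
# difference-plane classification of observers, and the end-to-end
# analysis that ties simulation, psychometric fitting, and model
# comparison together.

#' Summarize a per-observer PSE table
#'
#' @param fits Data frame with columns `observer_id`, `set_id`, `pse`,
#'   `jnd` (e.g. from [fit_trial_table()]).
#' @return List of class `pse_table`: `rows` (the input, one row per
#'   observer x set) and `summary` (per set: grand-mean PSE/JND and
#'   standard errors).
#' @export
pse_table <- function(fits) {
  need <- c("observer_id", "set_id", "pse", "jnd")
  if (!all(need %in% names(fits))) {
    stop_invalid("fits must have observer_id, set_id, pse, jnd columns")
  }
  if (nrow(fits) == 0L) stop_invalid("empty PSE table")
  if (any(fits$pse <= 0) || any(fits$jnd <= 0)) {
    stop_invalid("pse and jnd must be positive")
  }
  if (anyDuplicated(fits[, c("observer_id", "set_id")])) {
    stop_invalid("one row per observer x set expected")
  }
  se <- function(v) stats::sd(v) / sqrt(length(v))
  summ <- do.call(rbind, lapply(split(fits, fits$set_id), function(g) {
    data.frame(
      set_id = g$set_id[1], n = nrow(g),
      mean_pse = mean(g$pse), se_pse = se(g$pse),
      mean_jnd = mean(g$jnd), se_jnd = se(g$jnd),
      stringsAsFactors = FALSE
    )
  }))
  rownames(summ) <- NULL
  structure(list(rows = fits, summary = summ), class = "pse_table")
}

#' @export
print.pse_table <- function(x, ...) {
  cat("<pse_table>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

grand_mean_pses <- function(observed, sets) {
  # accept a pse_table, a per-observer data frame, or a named vector
  if (inherits(observed, "pse_table")) {
    v <- stats::setNames(observed$summary$mean_pse, observed$summary$set_id)
  } else if (is.data.frame(observed)) {
    v <- tapply(observed$pse, observed$set_id, mean)
    v <- stats::setNames(as.numeric(v), names(v))
  } else {
    v <- observed
  }
  ids <- vapply(sets, `[[`, "", "set_id")
  if (!all(ids %in% names(v))) {
    stop_invalid(paste(
      "observed PSEs missing for set(s):",
      paste(setdiff(ids, names(v)), collapse = ", ")
    ))
  }
  v[ids]
}

#' Ideal arithmetic and geometric points in the PSE-difference plane
#'
#' With three sets, the coordinates are the differences of set means:
#' arithmetic point `(AM1 - AM2, AM1 - AM3)`, geometric point
#' `(GM1 - GM2, GM1 - GM3)`. An observer whose per-set PSEs follow a
#' scheme (up to a common additive shift) lands on that scheme's point.
#'
#' @param sets List of exactly three [interval_set()] objects, in the
#'   order (set 1, set 2, set 3).
#' @return List with numeric length-2 vectors `arithmetic` and
#'   `geometric` (`delta_12`, `delta_13`, ms).
#' @examples
#' ideal_points(builtin_sets())
#' @export
ideal_points <- function(sets = builtin_sets()) {
  if (length(sets) != 3L) stop_invalid("exactly three sets required")
  am <- vapply(sets, function(s) arithmetic_mean(s$intervals), 0)
  gm <- vapply(sets, function(s) geometric_mean(s$intervals), 0)
  list(
    arithmetic = c(delta_12 = am[[1]] - am[[2]], delta_13 = am[[1]] - am[[3]]),
    geometric = c(delta_12 = gm[[1]] - gm[[2]], delta_13 = gm[[1]] - gm[[3]])
  )
}

#' Classify an observer in the PSE-difference plane
#'
#' Labels the observer `"geometric-oriented"` iff its point
#' `(delta_12, delta_13)` is strictly nearer (Euclidean) to the geometric
#' ideal point than to the arithmetic one — i.e. by the side of the
#' perpendicular bisector (the reflection line) of the segment joining the
#' two ideal points. Exact ties go to `"arithmetic-oriented"`.
#'
#' @param delta_12 `PSE(set1) - PSE(set2)` in ms.
#' @param delta_13 `PSE(set1) - PSE(set3)` in ms.
#' @param ideal Output of [ideal_points()].
#' @return `"geometric-oriented"` or `"arithmetic-oriented"` (vectorized
#'   over `delta_12`/`delta_13`).
#' @export
classify_observer <- function(delta_12, delta_13,
                              ideal = ideal_points(builtin_sets())) {
  d_geo <- (delta_12 - ideal$geometric[1])^2 +
    (delta_13 - ideal$geometric[2])^2
  d_ari <- (delta_12 - ideal$arithmetic[1])^2 +
    (delta_13 - ideal$arithmetic[2])^2
  unname(ifelse(d_geo < d_ari, "geometric-oriented", "arithmetic-oriented"))
}

#' Classification table for a per-observer PSE table
#'
#' @param fits Data frame with `observer_id`, `set_id`, `pse` (one row per
#'   observer x set, all three sets present per observer).
#' @param sets The three [interval_set()]s, in order.
#' @return Data frame: `observer_id`, `delta_12`, `delta_13`, `label`.
#' @export
classify_cohort <- function(fits, sets = builtin_sets()) {
  ideal <- ideal_points(sets)
  ids <- vapply(sets, `[[`, "", "set_id")
  rows <- lapply(split(fits, fits$observer_id), function(g) {
    p <- stats::setNames(g$pse, g$set_id)
    if (!all(ids %in% names(p))) {
      stop_invalid(sprintf("observer %s lacks a PSE for some set",
                           g$observer_id[1]))
    }
    d12 <- p[[ids[1]]] - p[[ids[2]]]
    d13 <- p[[ids[1]]] - p[[ids[3]]]
    data.frame(
      observer_id = g$observer_id[1], delta_12 = d12, delta_13 = d13,
      label = classify_observer(d12, d13, ideal),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Closed-form bias fit of a noise-free averaging model
#'
#' Fits the single bias parameter `mu_b` of the arithmetic, weighted,
#' harmonic, or geometric model to observed grand-mean PSEs by least
#' squares. Linear-scale schemes admit the closed form
#' `mu_b = mean(observed - noise-free prediction)` in ms; the geometric
#' scheme is fit in log space, `mu_b = mean(log observed - log GM)`.
#'
#' @param scheme Averaging scheme.
#' @param observed A `pse_table`, a per-observer fits data frame, or a
#'   named vector of grand-mean PSEs keyed by `set_id`.
#' @param sets List of [interval_set()]s.
#' @return List of class `model_prediction`: `scheme`, `fitted_bias`
#'   (`mu_b`), `per_set_pse` (named predictions, ms), `sse` (ms^2),
#'   `extra_params` (empty here; populated by the harmonic grid search).
#' @export
fit_bias <- function(scheme, observed, sets = builtin_sets()) {
  scheme <- match.arg(scheme, AVERAGING_SCHEMES)
  obs_pse <- grand_mean_pses(observed, sets)
  base <- vapply(sets, function(s) scheme_mean(scheme, s$intervals), 0)
  names(base) <- names(obs_pse)
  if (scheme == "geometric") {
    mu_b <- mean(log(obs_pse) - log(base))
    pred <- base * exp(mu_b)
  } else {
    mu_b <- mean(obs_pse - base)
    pred <- base + mu_b
  }
  structure(
    list(
      scheme = scheme, fitted_bias = mu_b, per_set_pse = pred,
      sse = sum((pred - obs_pse)^2), extra_params = list()
    ),
    class = "model_prediction"
  )
}

#' @export
print.model_prediction <- function(x, ...) {
  extras <- if (length(x$extra_params)) {
    paste0(" (", paste(names(x$extra_params), signif(unlist(x$extra_params), 3),
                       sep = "=", collapse = ", "), ")")
  } else ""
  cat(sprintf(
    "<model_prediction %s> mu_b=%.4g%s, SSE=%.1f ms^2\n  predictions: %s\n",
    x$scheme, x$fitted_bias, extras, x$sse,
    paste(sprintf("%s=%.1f", names(x$per_set_pse), x$per_set_pse),
          collapse = ", ")
  ))
  invisible(x)
}

# Exact inverse-CDF truncated-normal scalar-noise draws from shared
# uniforms: common random numbers across grid nodes keep the grid-search
# argmin deterministic under enumeration reordering.
harmonic_mc_medians <- function(set, w_f, sigma, u_mat, z_bias) {
  mu <- set$intervals
  n <- nrow(u_mat)
  k <- length(mu)
  if (w_f == 0) {
    hm <- rep(harmonic_mean(mu), n)
  } else {
    sd_i <- mu * w_f
    p0 <- stats::pnorm(0, mean = mu, sd = sd_i)
    t_mat <- stats::qnorm(
      rep(p0, each = n) + u_mat * rep(1 - p0, each = n),
      mean = rep(mu, each = n), sd = rep(sd_i, each = n)
    )
    hm <- k / rowSums(1 / t_mat)
  }
  stats::median(hm + sigma * z_bias)
}

#' Grid search for the harmonic model's parameters
#'
#' The harmonic average is a non-linear function of the noisy intervals,
#' so its predicted PSE depends on the noise parameters; the bias cannot
#' be fit in closed form. This evaluates the Monte-Carlo predicted PSE
#' (median of simulated harmonic averages) on a grid over the Weber
#' fraction `w_f`, bias mean `mu_b`, and bias SD `sigma`, and returns the
#' node minimizing the sum of squared errors against the observed
#' grand-mean PSEs. Common random numbers (one shared uniform matrix per
#' set) make the argmin deterministic given the seed, independent of grid
#' enumeration order; ties break to the lexicographically smallest
#' `(w_f, mu_b, sigma)`.
#'
#' Because the bias enters additively, predictions factorize as
#' `median(HM + sigma * Z) + mu_b`, so the simulation cost is paid per
#' `(w_f, sigma)` pair only.
#'
#' @param observed As in [fit_bias()].
#' @param sets List of [interval_set()]s.
#' @param w_f_grid,mu_b_grid,sigma_grid Parameter grids (defaults: `w_f`
#'   0-0.3 step 0.025; `mu_b` -200-50 ms step 5; `sigma` 0-60 ms step 10).
#' @param n_sim Monte-Carlo rounds per node (default 20,000).
#' @param seed Seed for the shared random draws.
#' @return A `model_prediction` with `extra_params = list(w_f, sigma)`.
#' @export
grid_search_harmonic <- function(observed, sets = builtin_sets(),
                                 w_f_grid = seq(0, 0.3, by = 0.025),
                                 mu_b_grid = seq(-200, 50, by = 5),
                                 sigma_grid = seq(0, 60, by = 10),
                                 n_sim = 20000L, seed = 1L) {
  if (length(w_f_grid) == 0L || length(mu_b_grid) == 0L ||
      length(sigma_grid) == 0L) {
    stop_invalid("empty parameter grid")
  }
  obs_pse <- grand_mean_pses(observed, sets)
  w_f_grid <- sort(w_f_grid)
  mu_b_grid <- sort(mu_b_grid)
  sigma_grid <- sort(sigma_grid)
  k <- length(sets[[1]]$intervals)
  set.seed(seed)
  u_mat <- matrix(stats::runif(n_sim * k), n_sim, k)
  z_bias <- stats::rnorm(n_sim)
  n_sets <- length(sets)
  # base medians per (w_f, sigma, set); mu_b shifts them additively
  base <- array(NA_real_,
                c(length(w_f_grid), length(sigma_grid), n_sets))
  for (i in seq_along(w_f_grid)) {
    for (j in seq_along(sigma_grid)) {
      for (s in seq_len(n_sets)) {
        base[i, j, s] <- harmonic_mc_medians(
          sets[[s]], w_f_grid[i], sigma_grid[j], u_mat, z_bias
        )
      }
    }
  }
  best <- NULL
  for (i in seq_along(w_f_grid)) {
    for (b in seq_along(mu_b_grid)) {
      for (j in seq_along(sigma_grid)) {
        pred <- base[i, j, ] + mu_b_grid[b]
        sse <- sum((pred - obs_pse)^2)
        if (is.null(best) || sse < best$sse - 1e-12) {
          best <- list(i = i, b = b, j = j, sse = sse, pred = pred)
        }
      }
    }
  }
  pred <- stats::setNames(best$pred, names(obs_pse))
  structure(
    list(
      scheme = "harmonic", fitted_bias = mu_b_grid[best$b],
      per_set_pse = pred, sse = best$sse,
      extra_params = list(w_f = w_f_grid[best$i],
                          sigma = sigma_grid[best$j])
    ),
    class = "model_prediction"
  )
}

#' Noise-free prediction patterns of the four models
#'
#' The analytic per-set means under each scheme (zero noise, zero bias):
#' the qualitative PSE patterns that distinguish linear from logarithmic
#' encoding across the canonical sets.
#'
#' @param sets List of [interval_set()]s.
#' @return Matrix, schemes x sets, of predicted PSEs in ms.
#' @export
prediction_patterns <- function(sets = builtin_sets()) {
  ids <- vapply(sets, `[[`, "", "set_id")
  out <- sapply(sets, function(s) {
    vapply(AVERAGING_SCHEMES, function(sc) scheme_mean(sc, s$intervals), 0)
  })
  colnames(out) <- ids
  out
}

#' Run the complete analysis pipeline on a trial table
#'
#' Per observer and set, fits the psychometric function and extracts
#' PSE/JND; summarizes the PSE table; fits the bias parameter of the
#' arithmetic, geometric and weighted models in closed form and the
#' harmonic model by grid search; and classifies every observer in the
#' PSE-difference plane. Inferential statistics are reported as
#' descriptive summaries only.
#'
#' @param trials Trial data frame or CSV path (format of
#'   [write_trials()]).
#' @param sets The three [interval_set()]s, in order.
#' @param variant Psychometric variant for the per-observer fits.
#' @param harmonic_grid Optional named list overriding
#'   [grid_search_harmonic()] arguments (`w_f_grid`, `mu_b_grid`,
#'   `sigma_grid`, `n_sim`, `seed`).
#' @return List of class `ensemble_report`: `set_statistics` (analytic
#'   means per scheme and set), `pse_table`, `model_fits` (one
#'   `model_prediction` per scheme), `winner` (lowest-SSE scheme),
#'   `classification` (per-observer labels and the geometric:arithmetic
#'   counts), `ideal_points`. Serializable with [write_report()].
#' @export
run_full_analysis <- function(trials, sets = builtin_sets(),
                              variant = "logistic_lapse",
                              harmonic_grid = list()) {
  if (is.character(trials)) trials <- read_trials(trials)
  if (!is.data.frame(trials) || nrow(trials) == 0L) {
    stop_invalid("empty trial table: nothing to analyze")
  }
  fits <- fit_trial_table(trials, variant = variant)
  ptab <- pse_table(fits)
  args <- utils::modifyList(list(observed = ptab, sets = sets),
                            harmonic_grid)
  model_fits <- list(
    arithmetic = fit_bias("arithmetic", ptab, sets),
    geometric = fit_bias("geometric", ptab, sets),
    weighted = fit_bias("weighted", ptab, sets),
    harmonic = do.call(grid_search_harmonic, args)
  )
  sse <- vapply(model_fits, `[[`, 0, "sse")
  cls <- classify_cohort(fits, sets)
  counts <- c(
    geometric = sum(cls$label == "geometric-oriented"),
    arithmetic = sum(cls$label == "arithmetic-oriented")
  )
  structure(
    list(
      set_statistics = prediction_patterns(sets),
      pse_table = ptab,
      model_fits = model_fits,
      sse = sse,
      winner = names(sse)[which.min(sse)],
      classification = list(table = cls, counts = counts),
      ideal_points = ideal_points(sets)
    ),
    class = "ensemble_report"
  )
}

#' @export
print.ensemble_report <- function(x, ...) {
  cat("== Ensemble interval-averaging report ==\n\n")
  cat("Analytic set means (ms):\n")
  print(round(x$set_statistics, 1))
  cat("\nGrand-mean PSEs:\n")
  print(x$pse_table$summary, row.names = FALSE)
  cat("\nModel fits (SSE in ms^2):\n")
  for (m in x$model_fits) print(m)
  cat(sprintf("\nWinning model (lowest SSE): %s\n", x$winner))
  cat(sprintf(
    "Classification: %d geometric-oriented vs %d arithmetic-oriented\n",
    x$classification$counts[["geometric"]],
    x$classification$counts[["arithmetic"]]
  ))
  invisible(x)
}

#' Write a machine-readable JSON report
#'
#' @param report An `ensemble_report` from [run_full_analysis()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "ensemble_report"))
  payload <- list(
    set_statistics = as.data.frame(report$set_statistics),
    pse_summary = report$pse_table$summary,
    pse_rows = report$pse_table$rows,
    model_fits = lapply(report$model_fits, function(m) {
      list(scheme = m$scheme, fitted_bias = m$fitted_bias,
           per_set_pse = as.list(m$per_set_pse), sse = m$sse,
           extra_params = m$extra_params)
    }),
    sse = as.list(report$sse),
    winner = report$winner,
    classification = report$classification$table,
    classification_counts = as.list(report$classification$counts),
    ideal_points = lapply(report$ideal_points, as.list)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
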