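# Offline maximum-likelihood psychometric fitting, PSE/JND extraction,
# and AIC comparison of model variants.
#
# Variants:
#   logistic        p = logistic((x - alpha) * beta)                 (k = 2)
#   logistic_lapse  p = lambda/2 + (1 - lambda) * logistic(...)      (k = 3)
#   logistic_nt     p = p_nt * q_nt + (1 - p_nt) * logistic(...)     (k = 4)
#   gamma_nt        p = p_nt * q_nt + (1 - p_nt) * pgamma(x)         (k = 4)
# The non-temporal component models stimulus-unrelated responding: with
# probability p_nt the response ignores the stimulus and is "longer" with
# a free bias q_nt in [0, 1] (0.5 = unbiased coin flip). A stimulus-sloped
# non-temporal component (e.g. an exponential guess-time CDF over the
# stimulus range) was rejected: its slope trades off against the temporal
# slope and the fitted weight no longer tracks the generative lapse.

PSYCHOMETRIC_VARIANTS <- c("logistic", "logistic_lapse", "gamma_nt",
                           "logistic_nt")

variant_k <- function(variant) {
  switch(variant, logistic = 2L, logistic_lapse = 3L,
         gamma_nt = 4L, logistic_nt = 4L)
}

clamp_prob <- function(p) pmin(pmax(p, 1e-9), 1 - 1e-9)

as_trial_xy <- function(trials) {
  if (is.data.frame(trials)) {
    xcol <- intersect(c("stimulus_ms", "comparison_ms"), names(trials))[1]
    if (is.na(xcol) || !"response" %in% names(trials)) {
      stop_invalid(
        "trials must have a stimulus_ms/comparison_ms and a response column"
      )
    }
    list(x = as.numeric(trials[[xcol]]), y = as.integer(trials$response))
  } else {
    trials <- as.matrix(trials)
    list(x = as.numeric(trials[, 1]), y = as.integer(trials[, 2]))
  }
}

# Response probability for a variant at untransformed parameters.
variant_prob <- function(variant, x, par, lo, hi) {
  switch(variant,
    logistic = stats::plogis((x - par$alpha) * par$beta),
    logistic_lapse = par$lambda / 2 +
      (1 - par$lambda) * stats::plogis((x - par$alpha) * par$beta),
    logistic_nt = par$p_nt * par$nt_bias +
      (1 - par$p_nt) * stats::plogis((x - par$alpha) * par$beta),
    gamma_nt = par$p_nt * par$nt_bias +
      (1 - par$p_nt) * stats::pgamma(x, shape = par$shape, rate = par$rate)
  )
}

# theta is the unconstrained optimization vector; back-transform it.
theta_to_par <- function(variant, theta) {
  switch(variant,
    logistic = list(alpha = theta[1], beta = exp(theta[2])),
    logistic_lapse = list(alpha = theta[1], beta = exp(theta[2]),
                          lambda = 0.3 * stats::plogis(theta[3])),
    logistic_nt = list(alpha = theta[1], beta = exp(theta[2]),
                       p_nt = 0.5 * stats::plogis(theta[3]),
                       nt_bias = stats::plogis(theta[4])),
    gamma_nt = list(shape = exp(theta[1]), rate = exp(theta[2]),
                    p_nt = 0.5 * stats::plogis(theta[3]),
                    nt_bias = stats::plogis(theta[4]))
  )
}

variant_starts <- function(variant, x, y) {
  # data-driven deterministic multi-starts
  xr <- range(x)
  spread <- max(stats::sd(x), diff(xr) / 6, 1)
  a0 <- stats::quantile(x, c(0.35, 0.5, 0.65), names = FALSE)
  b0 <- log(c(0.5, 2, 8) / spread)
  q0 <- stats::qlogis(0.5)  # unbiased non-temporal responding
  switch(variant,
    logistic = {
      g <- expand.grid(a = a0, b = b0)
      lapply(seq_len(nrow(g)), function(i) c(g$a[i], g$b[i]))
    },
    logistic_lapse = {
      g <- expand.grid(a = a0, b = b0, l = stats::qlogis(c(0.02, 0.2) / 0.3))
      lapply(seq_len(nrow(g)), function(i) c(g$a[i], g$b[i], g$l[i]))
    },
    logistic_nt = {
      g <- expand.grid(a = a0[c(1, 3)], b = b0[c(1, 3)],
                       p = stats::qlogis(c(0.02, 0.2) / 0.5))
      lapply(seq_len(nrow(g)), function(i) c(g$a[i], g$b[i], g$p[i], q0))
    },
    gamma_nt = {
      m <- stats::median(x)
      shapes <- c(5, 20, 60)
      lapply(seq_along(shapes), function(i) {
        k <- shapes[i]
        c(log(k), log(k / m), stats::qlogis(0.1 / 0.5), q0)
      })
    }
  )
}

#' Maximum-likelihood psychometric fit
#'
#' Fits one psychometric model variant to binary comparison responses by
#' maximizing the Bernoulli log-likelihood with multi-start quasi-Newton
#' optimization on transformed parameters (log slope, logit-bounded lapse
#' and mixture parameters; lapse bounded in \[0, 0.3\], non-temporal weight
#' `p_nt` in \[0, 0.5\], non-temporal "longer" bias `nt_bias` in \[0, 1\]).
#' Deterministic: the starts are data-driven, so refitting the same trials
#' gives the same result.
#'
#' @param trials Data frame with columns `stimulus_ms` (or `comparison_ms`)
#'   and `response` (0/1), or a two-column matrix.
#' @param variant One of `"logistic"`, `"logistic_lapse"`, `"gamma_nt"`,
#'   `"logistic_nt"`.
#' @return Object of class `psychometric_fit`: fields `model_variant`,
#'   `params` (named list), `loglik`, `aic` (`2k - 2 loglik`), `pse`, `jnd`
#'   (both ms), `n_trials`, `stimulus_range`, and `flags` (character
#'   vector, e.g. `"slope_at_bound"` under separation, `"pse_outside_hull"`
#'   when the PSE leaves the stimulus hull extended by 50%).
#' @examples
#' set.seed(1)
#' x <- runif(240, 400, 1100)
#' y <- rbinom(240, 1, psychometric_probability(x, 700, 0.01, 0))
#' fit <- fit_psychometric(data.frame(stimulus_ms = x, response = y))
#' c(fit$pse, fit$jnd)
#' @export
fit_psychometric <- function(trials, variant = "logistic_lapse") {
  variant <- match.arg(variant, PSYCHOMETRIC_VARIANTS)
  xy <- as_trial_xy(trials)
  x <- xy$x
  y <- xy$y
  if (length(x) < 10L) {
    stop_invalid("need at least 10 trials to fit a psychometric function")
  }
  if (length(unique(y)) < 2L) {
    stop_degenerate("responses contain a single category; cannot fit")
  }
  lo <- min(x)
  hi <- max(x)
  nll <- function(theta) {
    par <- theta_to_par(variant, theta)
    p <- clamp_prob(variant_prob(variant, x, par, lo, hi))
    -sum(y * log(p) + (1 - y) * log1p(-p))
  }
  # Analytic gradient for the logistic variants (the bulk fitting path);
  # the mixture variants fall back on optim's numerical gradient.
  gr <- NULL
  if (variant %in% c("logistic", "logistic_lapse")) {
    gr <- function(theta) {
      alpha <- theta[1]
      beta <- exp(theta[2])
      lambda <- if (variant == "logistic_lapse") {
        0.3 * stats::plogis(theta[3])
      } else 0
      z <- (x - alpha) * beta
      s <- stats::plogis(z)
      p <- clamp_prob(lambda / 2 + (1 - lambda) * s)
      dldp <- (p - y) / (p * (1 - p))
      ds <- (1 - lambda) * s * (1 - s)
      g <- c(sum(dldp * ds * (-beta)), sum(dldp * ds * z))
      if (variant == "logistic_lapse") {
        dlam <- lambda * (1 - lambda / 0.3)  # d lambda / d theta3
        g <- c(g, sum(dldp * (0.5 - s) * dlam))
      }
      g
    }
  }
  # Screen all starts by likelihood, polish the best few with BFGS.
  starts <- variant_starts(variant, x, y)
  start_vals <- vapply(starts, function(s) {
    v <- tryCatch(nll(s), error = function(e) Inf)
    if (is.finite(v)) v else Inf
  }, 0)
  n_polish <- min(3L, length(starts))
  best <- NULL
  for (si in order(start_vals)[seq_len(n_polish)]) {
    res <- tryCatch(
      stats::optim(starts[[si]], nll, gr = gr, method = "BFGS",
                   control = list(maxit = 300, reltol = 1e-9)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop_fit_failure(sprintf(
      "all %d starts failed for variant '%s'",
      length(variant_starts(variant, x, y)), variant
    ))
  }
  par <- theta_to_par(variant, best$par)
  loglik <- -best$value
  k <- variant_k(variant)
  fit <- structure(
    list(
      model_variant = variant, params = par,
      loglik = loglik, aic = 2 * k - 2 * loglik,
      n_trials = length(x), stimulus_range = c(lo, hi),
      flags = character(0)
    ),
    class = "psychometric_fit"
  )
  fit$pse <- pse_of(fit)
  fit$jnd <- jnd_of(fit)
  if (!is.null(par$beta) && par$beta > 1) {
    fit$flags <- c(fit$flags, "slope_at_bound")
  }
  half <- diff(c(lo, hi)) / 2
  if (fit$pse < lo - half || fit$pse > hi + half) {
    fit$flags <- c(fit$flags, "pse_outside_hull")
  }
  fit
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit %s> PSE=%.1f ms, JND=%.1f ms, loglik=%.2f, AIC=%.2f%s\n",
    x$model_variant, x$pse, x$jnd, x$loglik, x$aic,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""
  ))
  invisible(x)
}

#' PSE of a fitted psychometric model
#'
#' The stimulus at which the temporal component of the model crosses 0.5:
#' the threshold `alpha` for logistic variants (the symmetric lapse and the
#' non-temporal mixture do not move the temporal midpoint), the gamma
#' median for the gamma variant.
#'
#' @param fit A [fit_psychometric()] result.
#' @return PSE in ms.
#' @export
pse_of <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  p <- fit$params
  if (fit$model_variant == "gamma_nt") {
    stats::qgamma(0.5, shape = p$shape, rate = p$rate)
  } else {
    p$alpha
  }
}

#' JND of a fitted psychometric model
#'
#' The interval difference between the 75%- and 50%-points of the temporal
#' component: `log(3) / beta` for logistic variants (analytic), the
#' 0.75-0.50 quantile gap for the gamma variant.
#'
#' @param fit A [fit_psychometric()] result.
#' @return JND in ms.
#' @export
jnd_of <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  p <- fit$params
  if (fit$model_variant == "gamma_nt") {
    stats::qgamma(0.75, shape = p$shape, rate = p$rate) -
      stats::qgamma(0.5, shape = p$shape, rate = p$rate)
  } else {
    log(3) / p$beta
  }
}

#' Fit several psychometric variants and rank them by AIC
#'
#' Fits every requested variant to the same trials; per-variant failures
#' are collected without aborting the others.
#'
#' @param trials As in [fit_psychometric()].
#' @param variants Character vector of variant names.
#' @return Data frame ranked by AIC with columns `model_variant`, `k`,
#'   `loglik`, `aic`, `delta_aic` (against the best), `pse`, `jnd`;
#'   attributes `fits` (named list of `psychometric_fit`) and `failures`
#'   (named character vector of error messages).
#' @export
compare_variants <- function(trials, variants = PSYCHOMETRIC_VARIANTS) {
  variants <- match.arg(variants, PSYCHOMETRIC_VARIANTS, several.ok = TRUE)
  fits <- list()
  failures <- character(0)
  for (v in variants) {
    f <- tryCatch(fit_psychometric(trials, v), error = function(e) e)
    if (inherits(f, "psychometric_fit")) {
      fits[[v]] <- f
    } else {
      failures[v] <- conditionMessage(f)
    }
  }
  if (length(fits) == 0L) {
    stop_fit_failure("every requested variant failed to fit")
  }
  tab <- data.frame(
    model_variant = names(fits),
    k = vapply(names(fits), variant_k, 0L),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    aic = vapply(fits, `[[`, 0, "aic"),
    pse = vapply(fits, `[[`, 0, "pse"),
    jnd = vapply(fits, `[[`, 0, "jnd"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$aic), ]
  tab$delta_aic <- tab$aic - tab$aic[1]
  tab <- tab[, c("model_variant", "k", "loglik", "aic", "delta_aic",
                 "pse", "jnd")]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  attr(tab, "failures") <- failures
  tab
}

#' Per-observer, per-set psychometric fits of a trial table
#'
#' Groups a trial table by observer and set, fits the requested variant to
#' each group, and returns the PSE/JND table that drives the model
#' comparison.
#'
#' @param trials Trial data frame (or CSV path) as written by
#'   [write_trials()].
#' @param variant Psychometric variant passed to [fit_psychometric()].
#' @return Data frame with one row per observer x set: `observer_id`,
#'   `set_id`, `alpha`, `beta`, `lambda`, `loglik`, `aic`, `pse`, `jnd`.
#' @export
fit_trial_table <- function(trials, variant = "logistic_lapse") {
  if (is.character(trials)) trials <- read_trials(trials)
  if (nrow(trials) == 0L) stop_invalid("empty trial table")
  groups <- split(trials, list(trials$observer_id, trials$set_id),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    fit <- fit_psychometric(
      data.frame(stimulus_ms = g$comparison_ms, response = g$response),
      variant
    )
    data.frame(
      observer_id = g$observer_id[1], set_id = g$set_id[1],
      alpha = if (is.null(fit$params$alpha)) NA_real_ else fit$params$alpha,
      beta = if (is.null(fit$params$beta)) NA_real_ else fit$params$beta,
      lambda = if (is.null(fit$params$lambda)) NA_real_
               else fit$params$lambda,
      loglik = fit$loglik, aic = fit$aic, pse = fit$pse, jnd = fit$jnd,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$observer_id, out$set_id), ]
  rownames(out) <- NULL
  out
}
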