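test_that("psychometric_probability has the analytic landmarks", {
  expect_equal(psychometric_probability(700, 700, 0.01, 0), 0.5)
  expect_equal(psychometric_probability(700 + log(3) / 0.01, 700, 0.01, 0),
               0.75)
  expect_equal(psychometric_probability(1e9, 700, 0.01, 0.1), 0.95)
  expect_equal(psychometric_probability(-1e9, 700, 0.01, 0.1), 0.05)
  # strictly increasing in x
  x <- seq(100, 1500, by = 50)
  expect_true(all(diff(psychometric_probability(x, 700, 0.005, 0.04)) > 0))
  expect_error(psychometric_probability(700, 700, -1, 0),
               class = "enstime_invalid_input")
  expect_error(psychometric_probability(700, 700, 0.01, 0.6),
               class = "enstime_invalid_input")
})

test_that("posterior stays normalized through updates", {
  track <- uml_track(small_design()$grid)
  set.seed(61)
  for (i in 1:25) {
    x <- select_next_stimulus(track)
    track <- update_posterior(track, x, stats::rbinom(1, 1, 0.5))
    expect_lt(abs(sum(posterior_grid(track)$posterior) - 1), 1e-9)
  }
})

test_that("a 'longer' response shifts threshold mass downward", {
  track <- uml_track(small_design()$grid)
  prior_mean <- estimate_parameters(track)[["alpha"]]
  up <- update_posterior(track, 700, 1L)
  expect_lt(estimate_parameters(up)[["alpha"]], prior_mean)
  down <- update_posterior(track, 700, 0L)
  expect_gt(estimate_parameters(down)[["alpha"]], prior_mean)
})

test_that("contradictory responses reweight the prior by p(1-p)", {
  g <- small_design()$grid
  track <- uml_track(g)
  track <- update_posterior(track, 700, 1L)
  track <- update_posterior(track, 700, 0L)
  # direct computation of the expected posterior on the full grid
  p <- g$lambda_full / 2 + (1 - g$lambda_full) *
    stats::plogis((700 - g$alpha_full) * exp(g$log_beta_full))
  expected <- p * (1 - p)
  expected <- expected / sum(expected)
  got <- as.vector(posterior_grid(track)$posterior)
  expect_equal(got, expected, tolerance = 1e-10)
  expect_lt(abs(sum(got) - 1), 1e-9)
})

test_that("a fresh track returns prior means and the initial stimulus", {
  g <- small_design()$grid
  track <- uml_track(g)
  est <- estimate_parameters(track)
  expect_equal(est[["alpha"]], mean(g$alpha_grid))
  expect_equal(est[["beta"]], exp(mean(log(g$beta_grid))), tolerance = 1e-10)
  expect_equal(est[["lambda"]], mean(g$lambda_grid))
  expect_equal(select_next_stimulus(track), 500)
})

test_that("a candidate set of size 1 forces that stimulus", {
  g <- uml_grid(alpha_grid = seq(400, 1000, length.out = 13),
                beta_grid = exp(seq(log(0.005), log(0.1), length.out = 9)),
                lambda_grid = c(0, 0.05),
                candidates = 700)
  track <- update_posterior(uml_track(g), 700, 1L)
  expect_equal(select_next_stimulus(track), 700)
})

test_that("variance-min selection stays near a concentrated posterior", {
  g <- uml_grid()
  track <- uml_track(g)
  # hand-built posterior: alpha ~ N(700, 40), beta tight near 0.02,
  # lapse concentrated at 0
  lp <- stats::dnorm(g$alpha_full, 700, 40, log = TRUE) +
    stats::dnorm(g$log_beta_full, log(0.02), 0.1, log = TRUE) +
    ifelse(g$lambda_full == 0, 0, -50)
  track$log_posterior <- lp - max(lp)
  track$mass <- NULL
  track$stimulus <- 500  # non-empty history so selection is adaptive
  track$response <- 1L
  x <- select_next_stimulus(track)
  pg <- posterior_grid(track)
  alpha_marg <- apply(pg$posterior, 1, sum)
  cum <- cumsum(alpha_marg)
  q10 <- g$alpha_grid[which(cum >= 0.1)[1]]
  q90 <- g$alpha_grid[which(cum >= 0.9)[1]]
  expect_gte(x, q10)
  expect_lte(x, q90)
})

test_that("sweep mode returns posterior-quantile stimuli in range", {
  track <- uml_track(small_design()$grid)
  set.seed(62)
  for (i in 1:8) {
    x <- select_next_stimulus(track, mode = "sweep")
    if (i == 1) expect_equal(x, 500)
    expect_gte(x, 100)
    expect_lte(x, 2000)
    track <- update_posterior(track, x, stats::rbinom(1, 1, 0.5))
  }
})

test_that("240 responses from a known observer give a consistent posterior", {
  set.seed(63)
  track <- run_uml_track(240, logistic_responder(700, 0.02, 0.05),
                         grid = small_design()$grid)
  pg <- posterior_grid(track)
  alpha_marg <- apply(pg$posterior, 1, sum)
  a_mean <- sum(alpha_marg * pg$alpha_grid)
  a_sd <- sqrt(sum(alpha_marg * pg$alpha_grid^2) - a_mean^2)
  expect_lt(abs(a_mean - 700), 2 * a_sd)
})

test_that("a deterministic geometric observer is recovered within 5%", {
  sets <- canonical_sets()
  obs <- observer_params("geometric")  # zero noise: step function at GM
  set.seed(64)
  track <- run_uml_track(
    80,
    function(x) simulate_response(sets$set1, x, obs)$response,
    grid = small_design()$grid
  )
  alpha_hat <- estimate_parameters(track)[["alpha"]]
  expect_lt(abs(alpha_hat - 709.8) / 709.8, 0.05)
})

test_that("tracks survive a JSON checkpoint round-trip", {
  set.seed(65)
  track <- run_uml_track(12, logistic_responder(750, 0.015),
                         grid = small_design()$grid)
  path <- withr::local_tempfile(fileext = ".json")
  uml_save_track(track, path)
  back <- uml_load_track(path)
  expect_equal(estimate_parameters(back), estimate_parameters(track))
  expect_equal(select_next_stimulus(back), select_next_stimulus(track))
  expect_equal(uml_trace(back), uml_trace(track))
})

test_that("estimate trace has one row per trial", {
  set.seed(66)
  track <- run_uml_track(15, logistic_responder(800, 0.01),
                         grid = small_design()$grid)
  tr <- uml_trace(track)
  expect_equal(nrow(tr), 15L)
  expect_true(all(is.finite(tr$alpha_hat)))
})
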