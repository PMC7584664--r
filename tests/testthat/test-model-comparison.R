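test_that("ideal points match direct computation from the printed sets", {
  ip <- ideal_points(canonical_sets())
  expect_equal(unname(ip$arithmetic), c(0, 74))
  expect_equal(unname(ip$geometric), c(-77.448, 1.985), tolerance = 1e-4)
})

test_that("ideal points degenerate and permute as expected", {
  same <- list(interval_set("a", c(500, 700)), interval_set("b", c(500, 700)),
               interval_set("c", c(500, 700)))
  ip <- ideal_points(same)
  expect_equal(unname(ip$arithmetic), c(0, 0))
  expect_equal(unname(ip$geometric), c(0, 0))
  sets <- canonical_sets()
  swapped <- ideal_points(list(sets$set1, sets$set3, sets$set2))
  orig <- ideal_points(sets)
  expect_equal(unname(swapped$arithmetic),
               unname(orig$arithmetic[c(2, 1)]))
  expect_equal(unname(swapped$geometric), unname(orig$geometric[c(2, 1)]))
})

test_that("classification follows the perpendicular bisector with ties
           to arithmetic", {
  ip <- ideal_points(canonical_sets())
  expect_equal(classify_observer(ip$geometric[1], ip$geometric[2], ip),
               "geometric-oriented")
  expect_equal(classify_observer(ip$arithmetic[1], ip$arithmetic[2], ip),
               "arithmetic-oriented")
  mid <- (ip$geometric + ip$arithmetic) / 2  # on the reflection line
  expect_equal(classify_observer(mid[1], mid[2], ip),
               "arithmetic-oriented")
})

test_that("classification is invariant to a common translation", {
  ip <- ideal_points(canonical_sets())
  set.seed(81)
  pts <- cbind(stats::runif(40, -150, 150), stats::runif(40, -150, 150))
  labels <- classify_observer(pts[, 1], pts[, 2], ip)
  shift <- c(37.5, -81.25)
  ip_shift <- list(arithmetic = ip$arithmetic + shift,
                   geometric = ip$geometric + shift)
  shifted <- classify_observer(pts[, 1] + shift[1], pts[, 2] + shift[2],
                               ip_shift)
  expect_identical(labels, shifted)
})

test_that("fit_bias solves constructed inverse problems exactly", {
  sets <- canonical_sets()
  gms <- vapply(sets, function(s) geometric_mean(s$intervals), 0)
  names(gms) <- names(sets)
  fit <- fit_bias("geometric", gms, sets)
  expect_equal(fit$fitted_bias, 0)
  expect_equal(fit$sse, 0)
  fit <- fit_bias("geometric", gms * exp(-0.04), sets)
  expect_equal(fit$fitted_bias, -0.04)
  expect_equal(fit$sse, 0, tolerance = 1e-18)
  ams <- vapply(sets, function(s) arithmetic_mean(s$intervals), 0)
  names(ams) <- names(sets)
  fit <- fit_bias("arithmetic", ams - 50, sets)
  expect_equal(fit$fitted_bias, -50)
  expect_equal(fit$sse, 0)
  wms <- vapply(sets, function(s) weighted_mean(s$intervals), 0)
  names(wms) <- names(sets)
  fit <- fit_bias("weighted", wms + 12, sets)
  expect_equal(fit$fitted_bias, 12)
  expect_equal(fit$sse, 0, tolerance = 1e-18)
  expect_error(fit_bias("geometric", gms[1:2], sets),
               class = "enstime_invalid_input")
})

test_that("harmonic grid search recovers self-generated parameters", {
  sets <- canonical_sets()
  true_wf <- 0.1
  true_mub <- -50
  set.seed(82)
  obs <- observer_params("harmonic", weber_fraction = true_wf,
                         bias_mean = true_mub)
  observed <- vapply(sets, predict_pse, 0, obs = obs, n_sim = 50000)
  names(observed) <- names(sets)
  fit <- grid_search_harmonic(observed, sets,
                              w_f_grid = seq(0, 0.3, by = 0.05),
                              mu_b_grid = seq(-100, 0, by = 10),
                              sigma_grid = 0,
                              n_sim = 20000, seed = 9)
  expect_lte(abs(fit$extra_params$w_f - true_wf), 0.05)
  expect_lte(abs(fit$fitted_bias - true_mub), 10)
})

test_that("harmonic grid search is deterministic and handles edge grids", {
  sets <- canonical_sets()
  observed <- c(set1 = 650, set2 = 770, set3 = 700)
  one <- grid_search_harmonic(observed, sets, w_f_grid = 0.1,
                              mu_b_grid = -20, sigma_grid = 10,
                              n_sim = 2000, seed = 3)
  expect_equal(one$extra_params$w_f, 0.1)
  expect_equal(one$fitted_bias, -20)
  expect_gte(one$sse, 0)
  # enumeration order must not change the argmin (ties lexicographic)
  a <- grid_search_harmonic(observed, sets,
                            w_f_grid = c(0, 0.05, 0.1),
                            mu_b_grid = seq(-60, 0, by = 20),
                            sigma_grid = c(0, 20),
                            n_sim = 4000, seed = 3)
  b <- grid_search_harmonic(observed, sets,
                            w_f_grid = c(0.1, 0, 0.05),
                            mu_b_grid = c(0, -40, -20, -60),
                            sigma_grid = c(20, 0),
                            n_sim = 4000, seed = 3)
  expect_identical(a$extra_params, b$extra_params)
  expect_identical(a$fitted_bias, b$fitted_bias)
  expect_error(grid_search_harmonic(observed, sets, w_f_grid = numeric(0)),
               class = "enstime_invalid_input")
})

test_that("pse_table validates its input", {
  bad <- data.frame(observer_id = "a", set_id = "set1", pse = -5, jnd = 10)
  expect_error(pse_table(bad), class = "enstime_invalid_input")
  dup <- data.frame(observer_id = c("a", "a"), set_id = c("set1", "set1"),
                    pse = c(700, 710), jnd = c(50, 60))
  expect_error(pse_table(dup), class = "enstime_invalid_input")
  ok <- data.frame(observer_id = rep(c("a", "b"), each = 2),
                   set_id = rep(c("set1", "set2"), 2),
                   pse = c(700, 780, 690, 770), jnd = c(50, 60, 55, 65))
  tab <- pse_table(ok)
  expect_equal(nrow(tab$summary), 2L)
  expect_equal(tab$summary$mean_pse[tab$summary$set_id == "set1"], 695)
})

test_that("run_full_analysis recovers a geometric cohort end to end", {
  des <- small_design(trials_per_set = 40L)
  coh <- generate_cohort(
    4, c(geometric = 1),
    param_ranges = list(log_noise_sd = c(0.1, 0.1),
                        lapse_rate = c(0.02, 0.02)),
    design = des, seed = 83
  )
  report <- run_full_analysis(coh$trials,
                              harmonic_grid = list(n_sim = 3000, seed = 5))
  expect_s3_class(report, "ensemble_report")
  expect_equal(report$winner, "geometric")
  expect_equal(sum(report$classification$counts), 4)
  # grand-mean pattern: set2 above both others
  summ <- report$pse_table$summary
  pse <- stats::setNames(summ$mean_pse, summ$set_id)
  expect_gt(pse[["set2"]], pse[["set1"]])
  expect_gt(pse[["set2"]], pse[["set3"]])
  # report serializes to JSON
  path <- withr::local_tempfile(fileext = ".json")
  write_report(report, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$winner, "geometric")
  expect_named(parsed$model_fits,
               c("arithmetic", "geometric", "weighted", "harmonic"))
})

test_that("run_full_analysis rejects empty input", {
  expect_error(run_full_analysis(data.frame()),
               class = "enstime_invalid_input")
})

test_that("prediction_patterns reports all four schemes for all sets", {
  pat <- prediction_patterns(canonical_sets())
  expect_equal(dim(pat), c(4L, 3L))
  expect_equal(pat["arithmetic", "set1"], 800)
  expect_equal(pat["harmonic", "set2"], 774.4315, tolerance = 1e-6)
})
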