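fake_records <- function(best_rp, neuronal = TRUE, valid = TRUE) {
  n <- length(best_rp)
  data.frame(
    image_id = "img", tile_row = seq_len(n), tile_col = 1L,
    neuronal = rep_len(neuronal, n), direction_valid = rep_len(valid, n),
    theta_n_deg = 0, best_rp = best_rp, best_theta_deg = 0,
    best_phi_rad = 0, detected = NA)
}

test_that("abundance and regularity arithmetic", {
  s <- summarize_records(fake_records(c(0.1, 0.3, 0.5)), threshold = 0.2)
  expect_equal(s$abundance, 2 / 3)
  expect_equal(s$mean_rp_above, 0.4)
  expect_equal(s$n_analyzed, 3L)

  s0 <- summarize_records(fake_records(c(0.05, 0.1)), threshold = 0.2)
  expect_equal(s0$abundance, 0)
  expect_true(is.na(s0$mean_rp_above))

  # zero analyzed tiles: missing abundance, not an error
  sN <- summarize_records(fake_records(c(0.4, 0.5), valid = FALSE),
                          threshold = 0.2)
  expect_equal(sN$n_analyzed, 0L)
  expect_true(is.na(sN$abundance))
})

test_that("direction-discarded tiles are excluded from the denominator by default", {
  rec <- rbind(fake_records(c(0.5, 0.1)),
               fake_records(NA_real_, valid = FALSE))
  s <- summarize_records(rec, threshold = 0.2)
  expect_equal(s$n_analyzed, 2L)
  expect_equal(s$abundance, 1 / 2)
  s_alt <- summarize_records(rec, threshold = 0.2, count_discarded = TRUE)
  expect_equal(s_alt$n_analyzed, 3L)
  expect_equal(s_alt$abundance, 1 / 3)
})

test_that("raising the threshold never raises the abundance", {
  set.seed(41)
  rec <- fake_records(runif(200, 0, 0.6))
  ab <- sapply(seq(0, 0.6, by = 0.05),
               function(t) summarize_records(rec, threshold = t)$abundance)
  expect_true(all(diff(ab) <= 0))
})

test_that("an image crossed by a periodic neurite is detected tile by tile", {
  cfg <- sim_config(pattern = mps_pattern(phi_rad = 1.2), theta_true = 25,
                    fov_nm = 3000, neurite_width_nm = 900,
                    neurite_length_nm = 6000, seed = 7)
  cfg$bg_mean <- solve_bg_mean(cfg, 8)
  sim <- simulate_mps(cfg)
  an <- analyze_image(sim$image, sim$pixel_size, threshold = 0.2,
                      config = mps_config(seed = 7))
  expect_equal(nrow(an), 9L)
  s <- summary(an)
  expect_gte(s$n_analyzed, 2L)
  expect_gte(s$abundance, 0.8)
  expect_gt(s$mean_rp_above, 0.2)
  # detection map bookkeeping
  expect_equal(sum(s$detection_map), s$n_detected)
  # pipeline determinism: identical inputs and seed give identical tables
  an2 <- analyze_image(sim$image, sim$pixel_size, threshold = 0.2,
                       config = mps_config(seed = 7))
  expect_identical(as.data.frame(an), as.data.frame(an2))
})

test_that("an image with no neuronal tiles yields an empty summary, not an error", {
  an <- analyze_image(matrix(5, 150, 150), 20, threshold = 0.2,
                      config = mps_config())
  s <- summary(an)
  expect_equal(s$n_analyzed, 0L)
  expect_true(is.na(s$abundance))
})

test_that("noiseless logistic data is recovered exactly", {
  x <- seq(2, 20, by = 1)
  y <- 0.05 + (0.65 - 0.05) / (1 + exp(-(x - 9) / 1.5))
  fit <- fit_trend(x, y, model = "sigmoid")
  expect_true(fit$converged)
  expect_equal(coef(fit)[["x50"]], 9.0, tolerance = 0.01 / 9)
  expect_equal(unname(predict(fit, 9)), 0.35, tolerance = 1e-4)
})

test_that("noisy abundance curves recover the midpoint within one covariate unit", {
  set.seed(42)
  x <- seq(2, 20, by = 2)  # 10 covariate points
  errs <- replicate(50, {
    y <- 0.05 + 0.6 / (1 + exp(-(x - 9) / 1.5)) + rnorm(length(x), 0, 0.02)
    fit <- fit_trend(x, y)
    if (fit$converged) abs(coef(fit)[["x50"]] - 9) else NA_real_
  })
  expect_gte(mean(!is.na(errs)), 0.9)
  expect_lte(median(errs, na.rm = TRUE), 1.0)
})

test_that("degenerate trend inputs are flagged, not thrown", {
  fit <- fit_trend(1:10, rep(0.3, 10))
  expect_false(fit$converged)
  expect_true(all(is.na(coef(fit))))
  expect_error(predict(fit), "converge")
  # exponential model fits an increasing saturating trend
  x <- 1:12
  y <- 0.7 - 0.6 * exp(-x / 4)
  fe <- fit_trend(x, y, model = "exponential")
  expect_true(fe$converged)
  expect_equal(coef(fe)[["tau"]], 4, tolerance = 0.01)
})
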