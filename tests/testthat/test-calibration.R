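test_that("threshold is the null mean plus n_sigma standard deviations", {
  # mean 0.10, sample sd 0.04 exactly
  vals <- c(0.06, 0.10, 0.14)
  expect_equal(sd(vals), 0.04)
  cal <- fit_threshold(vals, n_sigma = 2.5)
  expect_equal(cal$threshold, 0.20)
  expect_equal(cal$null_mean, 0.10)

  expect_warning(cal0 <- fit_threshold(c(0.3, 0.3, 0.3)), "zero variance")
  expect_equal(cal0$threshold, 0.3)
  expect_error(fit_threshold(0.5), "at least 2")
})

test_that("threshold calibrated on a large Gaussian null sits at 2.5 sigma", {
  set.seed(21)
  cal <- fit_threshold(rnorm(1e5), n_sigma = 2.5)
  expect_lt(abs(cal$threshold - 2.5), 0.03)
})

test_that("false rates follow the strict-above detection rule", {
  null <- c(0.1, 0.15, 0.25, 0.05)
  pos <- c(0.3, 0.5, 0.18)
  r <- false_rates(null, pos, threshold = 0.2)
  expect_equal(r[["fpr"]], 1 / 4)
  expect_equal(r[["fnr"]], 1 / 3)
  # all positives strictly above the threshold
  expect_equal(false_rates(null, c(0.21, 0.9), 0.2)[["fnr"]], 0)
  # no positives supplied: missing, not zero
  expect_true(is.na(false_rates(null, NULL, 0.2)[["fnr"]]))
})

test_that("Gaussian null at mean + 2.5 sigma keeps false positives near the tail mass", {
  set.seed(22)
  null <- rnorm(2e5, 0.1, 0.04)
  cal <- fit_threshold(null, n_sigma = 2.5)
  expect_lte(cal$fpr, 0.01)
  expect_equal(cal$fpr, pnorm(-2.5), tolerance = 0.25)
  # positives drawn from the null itself miss with rate ~ 1 - fpr
  r <- false_rates(null, rnorm(2e5, 0.1, 0.04), cal$threshold)
  expect_equal(r[["fnr"]], 1 - r[["fpr"]], tolerance = 0.01)
})

test_that("false rates trade off monotonically in the threshold", {
  set.seed(23)
  null <- rnorm(5000, 0.1, 0.04)
  pos <- rnorm(5000, 0.4, 0.08)
  ths <- seq(0, 0.6, by = 0.05)
  fpr <- sapply(ths, function(t) false_rates(null, pos, t)[["fpr"]])
  fnr <- sapply(ths, function(t) false_rates(null, pos, t)[["fnr"]])
  expect_true(all(diff(fpr) <= 0))
  expect_true(all(diff(fnr) >= 0))
})

test_that("threshold is equivariant under affine transformation of the values", {
  set.seed(24)
  null <- rnorm(500, 0.2, 0.05)
  cal <- fit_threshold(null)
  cal2 <- fit_threshold(3 * null + 1)
  expect_equal(cal2$threshold, 3 * cal$threshold + 1, tolerance = 1e-12)
})

test_that("calibration records round-trip through JSON", {
  cal <- fit_threshold(c(0.06, 0.10, 0.14), modality = "STED",
                       positive_values = c(0.4, 0.5))
  f <- tempfile(fileext = ".json")
  write_calibration(cal, f)
  back <- read_calibration(f)
  expect_equal(back$threshold, cal$threshold)
  expect_equal(back$modality, "STED")
  expect_equal(back$fnr, cal$fnr)
})
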