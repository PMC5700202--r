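test_that("profile evaluates the sine-power model and respects its bounds", {
  p <- mps_pattern(A = 0, B = 1, P = 6, T_nm = 190, phi_rad = 0)
  expect_equal(evaluate_profile(95, p), 1.0)

  # amplitude-free limit is the constant baseline
  p0 <- mps_pattern(A = 3.2, B = 0)
  expect_equal(evaluate_profile(c(-50, 0, 17, 1000), p0), rep(3.2, 4))

  # bounded in [A, A + B] and T-periodic
  pa <- mps_pattern(A = 1.5, B = 2.5, phi_rad = 0.7)
  x <- seq(-500, 500, by = 0.5)
  f <- evaluate_profile(x, pa)
  expect_true(all(f >= pa$A - 1e-12 & f <= pa$A + pa$B + 1e-12))
  expect_equal(evaluate_profile(x + pa$T_nm, pa), f, tolerance = 1e-12)
})

test_that("consecutive maxima are spaced one period apart (sin^P halves the sine period)", {
  p <- mps_pattern()
  x <- seq(0, 2000, by = 0.01)
  f <- evaluate_profile(x, p)
  peaks <- x[which(diff(sign(diff(f))) == -2) + 1]
  expect_true(length(peaks) >= 9)
  expect_equal(diff(peaks), rep(190, length(peaks) - 1), tolerance = 1e-3)
})

test_that("invalid pattern parameters are rejected", {
  expect_error(mps_pattern(T_nm = 0), "T_nm")
  expect_error(mps_pattern(T_nm = -190), "T_nm")
  expect_error(mps_pattern(B = -1), "B")
  expect_error(mps_pattern(P = 5), "even")
  expect_error(mps_pattern(P = 0), "even")
  expect_error(mps_pattern(P = -2), "even")
})

test_that("phase in physical units: f(x; phi) = f(x + T*phi/pi; 0)", {
  p0 <- mps_pattern(phi_rad = 0)
  x <- seq(0, 600, by = 1.3)
  for (phi in c(0.4, 1.0, 2.9, 5.5)) {
    pp <- mps_pattern(phi_rad = phi)
    expect_equal(evaluate_profile(x, pp),
                 evaluate_profile(x + pp$T_nm * phi / pi, p0),
                 tolerance = 1e-10)
  }
})

test_that("rendering geometry follows the stated conventions", {
  # theta = 0: variation along columns, every column constant
  img0 <- render_pattern(c(40, 60), 20, mps_pattern(theta_deg = 0))
  expect_equal(max(apply(img0, 2, function(col) diff(range(col)))), 0)

  # theta = 0 and theta = 180 give identical images (even profile at phi = 0)
  img180 <- render_pattern(c(40, 60), 20, mps_pattern(theta_deg = 180))
  expect_equal(img0, img180, tolerance = 1e-12)

  # any row of the theta = 0 image matches the 1D profile at pixel centres
  p <- mps_pattern()
  x <- (seq_len(60) - 0.5) * 20
  expect_equal(img0[7, ], evaluate_profile(x, p), tolerance = 1e-12)

  # theta = 90 is the transpose relation of theta = 0 on a square grid
  sq0 <- render_pattern(c(50, 50), 20, mps_pattern(theta_deg = 0))
  sq90 <- render_pattern(c(50, 50), 20, mps_pattern(theta_deg = 90))
  expect_equal(sq90, t(sq0), tolerance = 1e-12)
})

test_that("rendered mean over whole periods approaches A + B * mean(sin^P)", {
  # <sin^6> over a period is 5/16
  p <- mps_pattern(A = 2, B = 4, theta_deg = 0)
  img <- render_pattern(c(10, 950), 2, p)  # 1900 nm = 10 periods along x
  expect_equal(mean(img), 2 + 4 * 5 / 16, tolerance = 1e-3)
  # independent of phase
  p2 <- mps_pattern(A = 2, B = 4, theta_deg = 0, phi_rad = 1.1)
  img2 <- render_pattern(c(10, 950), 2, p2)
  expect_equal(mean(img2), mean(img), tolerance = 1e-3)
})

test_that("rendered image is constant along the stripe direction", {
  # pixels displaced perpendicularly to theta carry identical intensity:
  # for theta = atan2(3, 4), the displacement (dcol, drow) = (3, -4) px has
  # zero projection on the variation axis
  th_deg <- atan2(3, 4) * 180 / pi
  img <- render_pattern(c(40, 40), 25, mps_pattern(theta_deg = th_deg,
                                                   phi_rad = 0.8))
  expect_equal(img[5:40, 1:37], img[1:36, 4:40], tolerance = 1e-12)

  # 45 degrees: constant along anti-diagonals
  img45 <- render_pattern(c(40, 40), 25, mps_pattern(theta_deg = 45))
  expect_equal(img45[2:40, 1:39], img45[1:39, 2:40], tolerance = 1e-12)
})

test_that("numerically tabulated profiles reproduce the analytic pattern", {
  p <- mps_pattern(A = 1, B = 2, phi_rad = 0.3)
  xs <- seq(0, 190, length.out = 400)[-400]
  f <- tabulated_profile(xs, evaluate_profile(xs, p), period_nm = 190)
  xq <- seq(-300, 700, by = 3.7)
  expect_equal(f(xq), evaluate_profile(xq, p), tolerance = 1e-3)
})
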