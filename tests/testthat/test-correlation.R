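test_that("masked Pearson matches the double-loop oracle on random inputs", {
  set.seed(11)
  for (i in 1:25) {
    img <- matrix(rnorm(64), 8, 8)
    pat <- matrix(rnorm(64), 8, 8)
    mask <- matrix(runif(64) < 0.6, 8, 8)
    if (sum(mask) < 3) mask[1:3] <- TRUE
    expect_equal(as.numeric(masked_pearson(img, pat, mask)),
                 naive_masked_pearson(img, pat, mask), tolerance = 1e-12)
  }
})

test_that("affine intensity scaling gives 1; inversion gives -1", {
  set.seed(12)
  img <- matrix(runif(400), 20, 20)
  expect_equal(as.numeric(masked_pearson(img, img)), 1, tolerance = 1e-12)
  expect_equal(as.numeric(masked_pearson(img, 2 * img + 5)), 1,
               tolerance = 1e-12)
  expect_equal(as.numeric(masked_pearson(img, -img)), -1, tolerance = 1e-12)
})

test_that("independent noise images are uncorrelated on average", {
  set.seed(13)
  vals <- replicate(100, as.numeric(
    masked_pearson(matrix(runif(2500), 50, 50),
                   matrix(runif(2500), 50, 50))))
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("degenerate inputs give a flagged zero coefficient", {
  img <- matrix(rnorm(100), 10, 10)
  flat <- matrix(5, 10, 10)
  r <- masked_pearson(img, flat)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "degenerate"))
  # too few masked pixels
  m <- matrix(FALSE, 10, 10); m[1] <- TRUE
  r2 <- masked_pearson(img, img, m)
  expect_true(attr(r2, "degenerate"))
  expect_error(masked_pearson(img, matrix(0, 5, 5)), "shape")
})

test_that("the scan recovers orientation and phase of a rendered pattern", {
  p <- mps_pattern(theta_deg = 10, phi_rad = 1.0)
  tile <- render_pattern(c(50, 50), 20, p)
  res <- scan_correlation(tile, NULL, theta_n = 10, pattern = mps_pattern(),
                          pixel_size = 20)
  expect_gte(res$best_rp, 0.99)
  expect_lte(ang_dist(res$best_theta, 10, 180), 1)
  # phase identifiable modulo pi for even powers
  expect_lte(ang_dist(res$best_phi, 1.0, pi), 2 * pi / 20)
  # the diagnostic curve peaks at the best theta; the phase polish can only
  # lift the maximum above the grid value
  expect_equal(res$curve$theta[which.max(res$curve$rp)], 10)
  expect_gte(res$best_rp, max(res$curve$rp))
})

test_that("best coefficient is invariant to affine rescaling of the tile", {
  p <- mps_pattern(theta_deg = 40, phi_rad = 2.2)
  set.seed(14)
  tile <- render_pattern(c(50, 50), 20, p) + matrix(rnorm(2500, 0, 0.3), 50)
  r1 <- scan_correlation(tile, NULL, 40, mps_pattern(), 20)
  r2 <- scan_correlation(5 * tile + 3, NULL, 40, mps_pattern(), 20)
  expect_equal(r1$best_rp, r2$best_rp, tolerance = 1e-12)
  expect_equal(r1$best_theta, r2$best_theta)
})

test_that("refining the orientation grid never lowers the maximum", {
  p <- mps_pattern(theta_deg = 12.4, phi_rad = 0.7)
  set.seed(15)
  tile <- render_pattern(c(50, 50), 20, p) + matrix(rnorm(2500, 0, 0.2), 50)
  coarse <- scan_correlation(tile, NULL, 12, mps_pattern(), 20,
                             theta_step = 2)
  fine <- scan_correlation(tile, NULL, 12, mps_pattern(), 20,
                           theta_step = 0.5)
  expect_gte(fine$best_rp, coarse$best_rp)
})

test_that("tiles with too small a mask are flagged degenerate", {
  tile <- matrix(rnorm(2500), 50, 50)
  m <- matrix(FALSE, 50, 50)
  m[1:10, 1:10] <- TRUE  # 4% of the tile, below the 10% default
  res <- scan_correlation(tile, m, 0, mps_pattern(), 20)
  expect_true(res$degenerate)
  expect_true(is.na(res$best_rp))
})
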