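test_that("background-only simulations have no structure", {
  cfg <- sim_config(label_density = 0, nonspecific_density = 0,
                    bg_mean = 20, seed = 31)
  sim <- simulate_mps(cfg)
  expect_equal(nrow(sim$fluorophores), 0L)
  expect_equal(mean(sim$image), 20, tolerance = 0.05)  # Poisson error at n=2500
  expect_true(all(sim$image >= 0))
  expect_true(is.integer(sim$image))
})

test_that("a fixed seed reproduces the image bit for bit", {
  cfg <- sim_config(seed = 32)
  s1 <- simulate_mps(cfg)
  s2 <- simulate_mps(cfg)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$fluorophores, s2$fluorophores)
  s3 <- simulate_mps(sim_config(seed = 33))
  expect_false(identical(s1$image, s3$image))
})

test_that("solving the background hits the target SBR within 15%", {
  for (tgt in c(3, 8)) {
    cfg <- sim_config(pattern = mps_pattern(phi_rad = 1), theta_true = 30)
    cfg$bg_mean <- solve_bg_mean(cfg, tgt)
    reldev <- sapply(1:4, function(i) {
      cfg$seed <- 100 * tgt + i
      abs(simulate_mps(cfg)$sbr_realized - tgt) / tgt
    })
    expect_lt(mean(reldev), 0.15)
  }
})

test_that("compute_sbr matches its top-decile definition", {
  img <- matrix(10, 40, 40)
  mask <- matrix(FALSE, 40, 40)
  mask[11:30, 11:30] <- TRUE
  # peaks at 50 on 25% of the in-mask pixels -> top decile mean is 50
  img[11:20, 11:20] <- 50
  expect_equal(compute_sbr(img, mask), 5.0)
  # noiseless pure background: signal equals background, SBR exactly 1
  bg <- matrix(20, 40, 40)
  expect_equal(compute_sbr(bg, mask), 1.0)
  expect_error(compute_sbr(img, matrix(TRUE, 40, 40)), "non-empty")
  expect_error(compute_sbr(img, matrix(FALSE, 40, 40)), "non-empty")
})

test_that("fluorophore counts scale linearly with labeling density", {
  n_at <- function(dens, seed) {
    cfg <- sim_config(label_density = dens, nonspecific_density = 0,
                      seed = seed)
    nrow(simulate_mps(cfg)$fluorophores)
  }
  n1 <- mean(sapply(1:5, function(s) n_at(5e-4, s)))
  n2 <- mean(sapply(1:5, function(s) n_at(1e-3, s)))
  n4 <- mean(sapply(1:5, function(s) n_at(2e-3, s)))
  expect_equal(n2 / n1, 2, tolerance = 0.15)
  expect_equal(n4 / n2, 2, tolerance = 0.15)
})

test_that("total counts decompose into fluorophore signal plus background", {
  cfg <- sim_config(bg_mean = 8, seed = 36)
  sim <- simulate_mps(cfg)
  n_px <- length(sim$image)
  expected <- nrow(sim$fluorophores) * cfg$photons_per_fluor + n_px * 8
  expect_equal(sum(sim$image), expected, tolerance = 0.02)
})

test_that("realized SBR grows with labeling density at fixed background", {
  sbr_at <- function(dens) {
    cfg <- sim_config(label_density = dens, bg_mean = 10, seed = 37)
    simulate_mps(cfg)$sbr_realized
  }
  s <- sapply(c(2e-4, 5e-4, 1e-3, 2e-3), sbr_at)
  expect_true(all(diff(s) > 0))
})

test_that("a minimal SBR experiment runs and reports finite spreads", {
  cfg <- sim_config(pattern = mps_pattern(phi_rad = 0.5), theta_true = 20)
  tab <- sbr_experiment(c(4, 8), n_reps = 2, config = cfg, seed = 38)
  expect_equal(nrow(tab), 2L)
  expect_true(all(is.finite(tab$mean_rp)))
  expect_true(all(is.finite(tab$sd_rp)))
  expect_true(is.finite(attr(tab, "rel_range_pct")))
})

test_that("the scan recovers the simulated ground truth at high SBR", {
  cfg <- mps_tile_config(seed = 0, sbr = 10)
  ok <- 0L
  for (s in 1:10) {
    cfg$seed <- 300 + s
    sim <- simulate_mps(cfg)
    res <- scan_correlation(sim$image, sim$truth_mask,
                            theta_n = sim$theta_true,
                            pattern = cfg$pattern, pixel_size = 20)
    expect_gt(res$best_rp, 0.2)
    if (ang_dist(res$best_theta, sim$theta_true, 180) <= 1 &&
        ang_dist(res$best_phi, sim$phi_true, pi) <= 2 * pi / 20)
      ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})
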