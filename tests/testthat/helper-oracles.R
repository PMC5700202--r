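# independent oracle: literal double-loop masked Pearson coefficient
naive_masked_pearson <- function(img, pat, mask) {
  si <- sp <- 0
  n <- 0
  for (m in seq_len(nrow(img))) for (k in seq_len(ncol(img)))
    if (mask[m, k]) { si <- si + img[m, k]; sp <- sp + pat[m, k]; n <- n + 1 }
  mi <- si / n; mp <- sp / n
  num <- d2i <- d2p <- 0
  for (m in seq_len(nrow(img))) for (k in seq_len(ncol(img)))
    if (mask[m, k]) {
      num <- num + (img[m, k] - mi) * (pat[m, k] - mp)
      d2i <- d2i + (img[m, k] - mi)^2
      d2p <- d2p + (pat[m, k] - mp)^2
    }
  num / sqrt(d2i * d2p)
}

# straight band of half-width hw (pixels) through the centre of a side x side
# tile, elongated along `angle_deg`
make_band <- function(side, angle_deg, hw) {
  r <- row(matrix(0, side, side))
  c <- col(matrix(0, side, side))
  th <- angle_deg * pi / 180
  d <- abs(-(c - side / 2) * sin(th) + (r - side / 2) * cos(th))
  d <= hw
}

# simulator configuration for a structure-free ("null") neurite tile:
# uniform nonspecific labeling only, comparable total label count
null_tile_config <- function(seed, sbr = 8, fov_nm = 1000, theta = 30) {
  cfg <- sim_config(label_density = 0, nonspecific_density = 4e-4,
                    theta_true = theta, fov_nm = fov_nm,
                    neurite_length_nm = 2 * fov_nm, seed = seed)
  cfg$bg_mean <- solve_bg_mean(cfg, sbr)
  cfg
}

# structure-bearing tile at a given SBR
mps_tile_config <- function(seed, sbr = 8, phi = 1.0, theta = 30,
                            fov_nm = 1000) {
  cfg <- sim_config(pattern = mps_pattern(phi_rad = phi), theta_true = theta,
                    fov_nm = fov_nm, neurite_length_nm = 2 * fov_nm,
                    seed = seed)
  cfg$bg_mean <- solve_bg_mean(cfg, sbr)
  cfg
}

# angular distance on a circle of the given period
ang_dist <- function(a, b, period) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}
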