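#' Analysis configuration defaults
#'
#' Returns the full set of pipeline parameters with their defaults; any can
#' be overridden through `...`. A fully defaulted configuration runs the
#' pipeline end-to-end on simulator output.
#'
#' @param ... named overrides of the defaults.
#' @return Named list of class `"mps_config"`.
#' @export
mps_config <- function(...) {
  defaults <- list(
    pixel_size_nm = 20,
    modality = "",
    sigma_gf_nm = 125,
    k_thresh = 0.65,
    min_object_px = 0,
    l_sr_nm = 1000,
    min_neuronal_fraction = 0.2,
    hough_min_len_frac = 0.25,
    hough_max_gap_frac = 0.10,
    hough_threshold = 10,
    cluster_tol_deg = 15,
    pattern_A = 0,
    pattern_B = 1,
    pattern_P = 6,
    pattern_T_nm = 190,
    theta_halfrange_deg = 20,
    theta_step_deg = 1,
    n_phi = 20,
    min_mask_fraction = 0.1,
    n_sigma = 2.5,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults[names(over)] <- over
  structure(defaults, class = "mps_config")
}

config_pattern <- function(config) {
  mps_pattern(A = config$pattern_A, B = config$pattern_B,
              P = config$pattern_P, T_nm = config$pattern_T_nm)
}

#' Analyze one image for the periodic structure
#'
#' Runs the full detection pipeline on a single image: neuron
#' discrimination, segmentation into square subregions, per-tile neuronal
#' flagging, neurite direction estimation, and the orientation/phase
#' correlation scan, followed by thresholding of the best coefficient.
#' Every tile yields exactly one record. Tiles without neuronal material
#' carry no direction estimate; tiles with an ambiguous direction (no
#' dominant angular cluster) carry no correlation result and are discarded
#' from abundance statistics downstream.
#'
#' @param image numeric matrix of intensities.
#' @param pixel_size nm per pixel (overrides the config value).
#' @param threshold detection threshold for the best coefficient (strictly
#'   greater-than rule), e.g. from [fit_threshold()]; `NA` leaves the
#'   `detected` column `NA`.
#' @param config an [mps_config()] list.
#' @param image_id identifier recorded with every tile.
#' @return Object of class `"mps_analysis"`: a data.frame with columns
#'   `image_id`, `tile_row`, `tile_col`, `neuronal`, `direction_valid`,
#'   `theta_n_deg`, `best_rp`, `best_theta_deg`, `best_phi_rad`,
#'   `detected`; attributes `grid` (the [segment_grid()] result), `mask`
#'   (the discrimination mask), `threshold`, and `config`.
#' @examples
#' \donttest{
#' sim <- simulate_mps(sim_config(fov_nm = 2000, seed = 3))
#' an <- analyze_image(sim$image, sim$pixel_size, threshold = 0.2,
#'                     config = mps_config())
#' summary(an)
#' }
#' @export
analyze_image <- function(image, pixel_size = NULL, threshold = NA_real_,
                          config = mps_config(), image_id = "image") {
  if (!inherits(config, "mps_config")) config <- do.call(mps_config, config)
  if (is.null(pixel_size)) pixel_size <- config$pixel_size_nm
  nm <- discriminate(image, pixel_size, sigma_gf_nm = config$sigma_gf_nm,
                     k_thresh = config$k_thresh,
                     min_object_px = config$min_object_px)
  grid <- segment_grid(dim(image), pixel_size, config$l_sr_nm)
  pattern <- config_pattern(config)
  tiles <- grid$tiles
  n <- nrow(tiles)
  rec <- data.frame(
    image_id = rep(image_id, n),
    tile_row = tiles$tile_row, tile_col = tiles$tile_col,
    neuronal = FALSE, direction_valid = FALSE,
    theta_n_deg = NA_real_, best_rp = NA_real_,
    best_theta_deg = NA_real_, best_phi_rad = NA_real_,
    detected = NA
  )
  for (t_i in seq_len(n)) {
    tl <- tiles[t_i, ]
    if (!flag_neuronal(tl, nm$mask, config$min_neuronal_fraction)) next
    rec$neuronal[t_i] <- TRUE
    tile_mask <- nm$mask[tl$row0:tl$row1, tl$col0:tl$col1]
    ori <- estimate_direction(
      tile_mask,
      min_len_frac = config$hough_min_len_frac,
      max_gap_frac = config$hough_max_gap_frac,
      threshold = config$hough_threshold,
      cluster_tol_deg = config$cluster_tol_deg,
      seed = derive_seed(config$seed, t_i))
    if (!ori$valid) next
    rec$direction_valid[t_i] <- TRUE
    rec$theta_n_deg[t_i] <- ori$theta_n
    tile_img <- image[tl$row0:tl$row1, tl$col0:tl$col1]
    cor <- scan_correlation(
      tile_img, tile_mask, theta_n = ori$theta_n, pattern = pattern,
      pixel_size = pixel_size,
      theta_halfrange = config$theta_halfrange_deg,
      theta_step = config$theta_step_deg, n_phi = config$n_phi,
      min_mask_fraction = config$min_mask_fraction)
    if (cor$degenerate) {
      rec$direction_valid[t_i] <- FALSE  # excluded like ambiguous tiles
      next
    }
    rec$best_rp[t_i] <- cor$best_rp
    rec$best_theta_deg[t_i] <- cor$best_theta
    rec$best_phi_rad[t_i] <- cor$best_phi
    rec$detected[t_i] <- if (is.na(threshold)) NA else cor$best_rp > threshold
  }
  structure(rec, grid = grid, mask = nm, threshold = threshold,
            config = config, class = c("mps_analysis", "data.frame"))
}

#' @export
print.mps_analysis <- function(x, ...) {
  cat(sprintf("Periodic-structure analysis of '%s': %d tiles\n",
              x$image_id[1], nrow(x)))
  cat(sprintf("  neuronal: %d   direction valid: %d   detected: %s\n",
              sum(x$neuronal), sum(x$direction_valid),
              if (all(is.na(x$detected))) "-" else
                sum(x$detected, na.rm = TRUE)))
  invisible(x)
}

#' Summarize per-tile records into abundance and regularity
#'
#' Aggregates the per-tile records of one experimental condition. The
#' denominator of the abundance is the number of analyzed tiles: those that
#' are neuronal and have a valid direction estimate (tiles discarded for
#' ambiguous direction do not count against the abundance). Abundance is
#' the fraction of analyzed tiles whose best coefficient exceeds the
#' threshold; regularity is the mean best coefficient over the detected
#' tiles. Setting `count_discarded = TRUE` switches the alternative
#' accounting in which direction-discarded neuronal tiles enter the
#' denominator as not-detected; this materially lowers abundance fractions
#' and is off by default.
#'
#' @param records an `"mps_analysis"` object or a data.frame of per-tile
#'   records (possibly concatenated across images of one condition).
#' @param threshold detection threshold; defaults to the one stored in
#'   `records`.
#' @param count_discarded see above.
#' @return Object of class `"mps_summary"`: list with `n_tiles`,
#'   `n_neuronal`, `n_analyzed`, `n_detected`, `abundance`,
#'   `mean_rp_above`, `threshold`, and `detection_map` (0/1 matrix at tile
#'   resolution, only when the records stem from a single image grid).
#' @export
summarize_records <- function(records, threshold = NULL,
                              count_discarded = FALSE) {
  if (is.null(threshold)) {
    threshold <- attr(records, "threshold")
    if (is.null(threshold)) stop("no threshold supplied", call. = FALSE)
  }
  grid <- attr(records, "grid")
  rec <- as.data.frame(records)
  analyzed <- rec$neuronal & rec$direction_valid & !is.na(rec$best_rp)
  if (count_discarded) analyzed <- rec$neuronal
  det <- analyzed & !is.na(rec$best_rp) & rec$best_rp > threshold
  n_analyzed <- sum(analyzed)
  abundance <- if (n_analyzed > 0) sum(det) / n_analyzed else NA_real_
  mean_above <- if (any(det)) mean(rec$best_rp[det]) else NA_real_
  dmap <- NULL
  if (!is.null(grid) && length(unique(rec$image_id)) == 1L) {
    dmap <- matrix(0L, grid$n_rows, grid$n_cols)
    dmap[cbind(rec$tile_row[det], rec$tile_col[det])] <- 1L
  }
  structure(
    list(n_tiles = nrow(rec), n_neuronal = sum(rec$neuronal),
         n_analyzed = n_analyzed, n_detected = sum(det),
         abundance = abundance, mean_rp_above = mean_above,
         threshold = threshold, detection_map = dmap),
    class = "mps_summary"
  )
}

#' @export
summary.mps_analysis <- function(object, threshold = NULL, ...) {
  summarize_records(object, threshold = threshold, ...)
}

#' @export
print.mps_summary <- function(x, ...) {
  cat("Batch summary\n")
  cat(sprintf("  tiles: %d   neuronal: %d   analyzed: %d   detected: %d\n",
              x$n_tiles, x$n_neuronal, x$n_analyzed, x$n_detected))
  cat(sprintf("  abundance: %s   mean R_P above threshold (%.3g): %s\n",
              ifelse(is.na(x$abundance), "-", sprintf("%.3f", x$abundance)),
              x$threshold,
              ifelse(is.na(x$mean_rp_above), "-",
                     sprintf("%.3f", x$mean_rp_above))))
  invisible(x)
}

#' @export
plot.mps_analysis <- function(x, ...) {
  s <- summarize_records(x)
  if (is.null(s$detection_map))
    stop("no detection map available", call. = FALSE)
  graphics::image(t(s$detection_map)[, rev(seq_len(nrow(s$detection_map))),
                                     drop = FALSE],
                  col = grDevices::grey.colors(2, 0.15, 0.95, rev = TRUE),
                  axes = FALSE, asp = nrow(s$detection_map) /
                    ncol(s$detection_map), ...)
  graphics::title("Detection map (1 = structure present)")
  invisible(x)
}

#' Fit a developmental trend to abundance or regularity values
#'
#' Fits either a 4-parameter logistic (sigmoid)
#' `y = y0 + (y1 - y0) / (1 + exp(-(x - x50) / tau))`, whose midpoint `x50`
#' is the half-height time of the rise, or a saturating exponential
#' `y = y1 - (y1 - y0) * exp(-x / tau)`, which only conveys the increasing
#' trend. Fitting uses Levenberg-Marquardt least squares; a fit that fails
#' to converge (or a degenerate input such as constant `y`) is returned
#' with `converged = FALSE` rather than raising an error.
#'
#' @param x covariate values, e.g. days in vitro (DIV).
#' @param y response values (abundance fractions or mean coefficients).
#' @param model `"sigmoid"` (default) or `"exponential"`.
#' @return Object of class `"mps_trend"`: list with `model`, `converged`,
#'   `coefficients` (named vector; includes `x50`, the half-height
#'   covariate value, for the sigmoid), `fitted`, `residuals`, `fit` (the
#'   underlying `nls` object or `NULL`).
#' @examples
#' x <- 2:12
#' y <- 0.05 + 0.6 / (1 + exp(-(x - 9) / 1.5))
#' coef(fit_trend(x, y))["x50"]
#' @export
fit_trend <- function(x, y, model = c("sigmoid", "exponential")) {
  model <- match.arg(model)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  need <- if (model == "sigmoid") 4L else 3L
  fail <- function() structure(
    list(model = model, converged = FALSE,
         coefficients = stats::setNames(rep(NA_real_, need),
           if (model == "sigmoid") c("y0", "y1", "x50", "tau")
           else c("y0", "y1", "tau")),
         fitted = rep(NA_real_, length(y)), residuals = rep(NA_real_,
           length(y)), fit = NULL, x = x, y = y),
    class = "mps_trend")
  if (length(x) < need || stats::sd(y) == 0) return(fail())

  dat <- data.frame(x = x, y = y)
  fit <- tryCatch({
    if (model == "sigmoid") {
      start <- list(y0 = min(y), y1 = max(y),
                    x50 = stats::weighted.mean(x, w = abs(diff(c(y[1], y)))),
                    tau = diff(range(x)) / 5)
      if (!is.finite(start$x50)) start$x50 <- stats::median(x)
      minpack.lm::nlsLM(
        y ~ y0 + (y1 - y0) / (1 + exp(-(x - x50) / tau)),
        data = dat, start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      start <- list(y0 = y[which.min(x)], y1 = max(y),
                    tau = max(diff(range(x)) / 3, 1e-6))
      minpack.lm::nlsLM(
        y ~ y1 - (y1 - y0) * exp(-x / tau),
        data = dat, start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(fail())
  co <- stats::coef(fit)
  # an unidentifiable midpoint (flat data escaping the sd() guard, or a
  # midpoint far outside the covariate range) is reported as non-converged
  if (model == "sigmoid" &&
      (!is.finite(co[["x50"]]) ||
       co[["x50"]] < min(x) - diff(range(x)) ||
       co[["x50"]] > max(x) + diff(range(x)))) return(fail())
  structure(
    list(model = model, converged = TRUE, coefficients = co,
         fitted = stats::fitted(fit), residuals = stats::residuals(fit),
         fit = fit, x = x, y = y),
    class = "mps_trend")
}

#' @export
coef.mps_trend <- function(object, ...) object$coefficients

#' @export
print.mps_trend <- function(x, ...) {
  cat(sprintf("Trend fit (%s): %s\n", x$model,
              if (x$converged) "converged" else "NOT converged"))
  if (x$converged) {
    print(round(x$coefficients, 4))
    if (x$model == "sigmoid")
      cat(sprintf("  half-height at x = %.3f\n", x$coefficients[["x50"]]))
  }
  invisible(x)
}

#' @export
predict.mps_trend <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("trend fit did not converge", call. = FALSE)
  if (is.null(newdata)) return(object$fitted)
  xd <- if (is.data.frame(newdata)) newdata$x else newdata
  stats::predict(object$fit, newdata = data.frame(x = xd))
}

#' @export
plot.mps_trend <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "covariate", ylab = "response", ...)
  if (x$converged) {
    xx <- seq(min(x$x), max(x$x), length.out = 200)
    graphics::lines(xx, predict(x, xx), col = "steelblue")
    if (x$model == "sigmoid")
      graphics::abline(v = x$coefficients[["x50"]], lty = 2, col = "grey50")
  }
  invisible(x)
}
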