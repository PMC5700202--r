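#' Parametric periodic reference pattern
#'
#' Constructs the parameter set of the periodic reference model
#' \deqn{f(x) = A + B \sin^P(\pi x / T + \phi)}
#' used as the template for the correlation analysis. With an even power
#' \eqn{P} the profile is non-negative and has period \eqn{T} (the even power
#' halves the natural \eqn{2T} period of the sine), so consecutive intensity
#' maxima are spaced exactly \eqn{T} nanometres apart. The defaults
#' \eqn{P = 6}, \eqn{T = 190} nm describe the spectrin membrane-associated
#' periodic skeleton (MPS) as measured by STED/STORM nanoscopy; \eqn{A = 0},
#' \eqn{B = 1} are used because the Pearson correlation is invariant to
#' affine intensity scaling of the template.
#'
#' Conventions: pattern intensity varies along the in-plane axis at angle
#' `theta` (degrees, stored modulo 180 since stripe patterns are symmetric
#' under a half turn); stripes run perpendicular to `theta`. The phase `phi`
#' is wrapped to `[0, 2*pi)`; note that for even `P` the rendered pattern is
#' identical under `phi -> phi + pi`, so the phase is identifiable modulo
#' `pi` only.
#'
#' @param A baseline intensity (arbitrary units).
#' @param B amplitude (arbitrary units, must be >= 0).
#' @param P sharpness power; a positive even integer.
#' @param T_nm period in nanometres (> 0).
#' @param phi_rad phase in radians; wrapped to `[0, 2*pi)`.
#' @param theta_deg in-plane orientation of the pattern's variation axis in
#'   degrees, measured from the image column (x) axis toward the row (y)
#'   axis; wrapped modulo 180.
#' @return An object of class `"mps_pattern"`: a list with fields `A`, `B`,
#'   `P`, `T_nm`, `phi_rad`, `theta_deg`.
#' @examples
#' p <- mps_pattern()
#' evaluate_profile(95, p)  # crest of the default MPS pattern
#' @export
mps_pattern <- function(A = 0, B = 1, P = 6, T_nm = 190, phi_rad = 0,
                        theta_deg = 0) {
  stopifnot_scalar_num(A, "A")
  stopifnot_scalar_num(B, "B", nonneg = TRUE)
  stopifnot_scalar_num(T_nm, "T_nm", positive = TRUE)
  stopifnot_scalar_num(phi_rad, "phi_rad")
  stopifnot_scalar_num(theta_deg, "theta_deg")
  if (!is.numeric(P) || length(P) != 1L || !is.finite(P) || P <= 0 ||
      P != round(P) || (round(P) %% 2L) != 0L)
    stop("'P' must be a positive even integer", call. = FALSE)
  structure(
    list(A = A, B = B, P = as.integer(round(P)), T_nm = T_nm,
         phi_rad = wrap_phi(phi_rad), theta_deg = wrap_theta(theta_deg)),
    class = "mps_pattern"
  )
}

#' @export
print.mps_pattern <- function(x, ...) {
  cat(sprintf(
    "Periodic reference pattern: f(x) = %g + %g * sin^%d(pi x / %g + %.4g)\n",
    x$A, x$B, x$P, x$T_nm, x$phi_rad))
  cat(sprintf("  period T = %g nm, orientation theta = %.4g deg\n",
              x$T_nm, x$theta_deg))
  invisible(x)
}

#' Evaluate the 1D periodic reference profile
#'
#' Computes \eqn{f(x) = A + B \sin^P(\pi x / T + \phi)} elementwise. The
#' result is bounded in `[A, A + B]` and has period `T_nm` in `x`.
#'
#' @param x numeric vector of positions in nanometres.
#' @param params an [mps_pattern()] object.
#' @return Numeric vector of intensities, same length as `x`.
#' @export
evaluate_profile <- function(x, params) {
  if (!inherits(params, "mps_pattern"))
    params <- do.call(mps_pattern, as.list(params))
  params$A + params$B *
    sin(pi * x / params$T_nm + params$phi_rad)^params$P
}

#' Render the periodic reference pattern as a 2D image
#'
#' Evaluates the 1D profile at each pixel centre projected onto the
#' pattern's variation axis. Pixel centres sit at `(index - 0.5) *
#' pixel_size` in nanometres; with `theta_deg = 0` the intensity varies along
#' the column (x) axis and every column of the image is constant. The
#' pattern is evaluated analytically at each pixel centre -- no resampling
#' or supersampling -- so rotated templates carry no interpolation bias.
#'
#' @param shape integer vector `c(rows, cols)` in pixels.
#' @param pixel_size pixel size in nm/pixel (> 0).
#' @param params an [mps_pattern()] object; its `theta_deg` sets the
#'   orientation.
#' @return Numeric matrix of dimension `shape`.
#' @examples
#' pat <- render_pattern(c(50, 50), 20, mps_pattern(theta_deg = 30))
#' @export
render_pattern <- function(shape, pixel_size, params) {
  if (!inherits(params, "mps_pattern"))
    params <- do.call(mps_pattern, as.list(params))
  stopifnot_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop("'shape' must be two positive integers (rows, cols)", call. = FALSE)
  th <- params$theta_deg * pi / 180
  x <- (seq_len(shape[2]) - 0.5) * pixel_size   # column axis
  y <- (seq_len(shape[1]) - 0.5) * pixel_size   # row axis
  u <- outer(y * sin(th), x * cos(th), "+")     # projection on variation axis
  matrix(evaluate_profile(as.vector(u), params), shape[1], shape[2])
}

#' Tabulated 1D reference profile
#'
#' Hook for reference patterns defined numerically instead of by the
#' analytic sine-power model: wraps a sampled profile into a periodic
#' interpolating function that can be rendered like the analytic pattern.
#' The profile is interpreted as one full period sampled at `x_nm` and is
#' extended periodically.
#'
#' @param x_nm sample positions in nanometres, strictly increasing, spanning
#'   one period.
#' @param intensity profile values at `x_nm`.
#' @param period_nm the period; defaults to `max(x_nm) - min(x_nm) +` one
#'   sample step.
#' @return A function `f(x)` evaluating the periodic profile at arbitrary
#'   positions (linear interpolation).
#' @export
tabulated_profile <- function(x_nm, intensity, period_nm = NULL) {
  if (length(x_nm) != length(intensity) || length(x_nm) < 2L)
    stop("'x_nm' and 'intensity' must have equal length >= 2", call. = FALSE)
  if (is.unsorted(x_nm, strictly = TRUE))
    stop("'x_nm' must be strictly increasing", call. = FALSE)
  if (is.null(period_nm)) {
    step <- diff(x_nm)
    period_nm <- diff(range(x_nm)) + step[length(step)]
  }
  x0 <- x_nm[1]
  # close the period for interpolation
  xs <- c(x_nm - x0, period_nm)
  ys <- c(intensity, intensity[1])
  function(x) {
    stats::approx(xs, ys, xout = ((x - x0) %% period_nm), rule = 2)$y
  }
}
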