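# internal helpers shared across modules

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`,
#' restoring the previous RNG state on exit so callers never observe a side
#' effect on the global stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream untouched.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# derive a child seed below 2^31 from a parent seed and a stream index
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * stream) %% 2147483587)
}

# wrap an angle in degrees to [0, 180)
wrap_theta <- function(theta_deg) {
  ((theta_deg %% 180) + 180) %% 180
}

# wrap a phase in radians to [0, 2*pi)
wrap_phi <- function(phi_rad) {
  tau <- 2 * pi
  ((phi_rad %% tau) + tau) %% tau
}

# circular distance between angles in degrees with the given period
circ_dist <- function(a, b, period = 180) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

# circular mean of angles in degrees on a circle of the given period
circ_mean <- function(theta_deg, period = 180) {
  scale <- 2 * pi / period
  z <- complex(argument = theta_deg * scale)
  wrap <- (Arg(mean(z)) / scale) %% period
  wrap
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}
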