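#' Calibrate the detection threshold from a null distribution
#'
#' Sets the detection threshold for the maximum correlation coefficient from
#' a sample of subregions known to lack the periodic structure: the
#' threshold is the null sample mean plus `n_sigma` sample standard
#' deviations (ddof = 1). With an approximately Gaussian null and the
#' default `n_sigma = 2.5`, the false-positive probability is limited to
#' about 0.6% (below the 1% design criterion). STED and STORM imaging get
#' separate calibrations, distinguished only by the free-text `modality`
#' label -- the arithmetic is identical.
#'
#' @param null_values numeric vector of best correlation coefficients from
#'   subregions without the structure (length >= 2).
#' @param n_sigma threshold level in null standard deviations (default 2.5).
#' @param positive_values optional coefficients from subregions known to
#'   carry the structure; enables the false-negative rate estimate.
#' @param modality free-text label (e.g. `"STORM"`, `"STED"`).
#' @return Object of class `"mps_calibration"`: list with `modality`,
#'   `null_mean`, `null_std`, `n_sigma`, `threshold`, `fpr`, `fnr` (`NA`
#'   when no positives supplied), `n_null`, `n_pos`.
#' @examples
#' fit_threshold(rnorm(1000, 0.1, 0.04))
#' @export
fit_threshold <- function(null_values, n_sigma = 2.5,
                          positive_values = NULL, modality = "") {
  null_values <- as.numeric(null_values)
  if (length(null_values) < 2L || !all(is.finite(null_values)))
    stop("need at least 2 finite null values", call. = FALSE)
  stopifnot_scalar_num(n_sigma, "n_sigma")
  m <- mean(null_values)
  s <- stats::sd(null_values)
  if (s == 0)
    warning("null values have zero variance; threshold equals their mean")
  thr <- m + n_sigma * s
  rates <- false_rates(null_values, positive_values, thr)
  structure(
    list(modality = modality, null_mean = m, null_std = s,
         n_sigma = n_sigma, threshold = thr,
         fpr = rates[["fpr"]], fnr = rates[["fnr"]],
         n_null = length(null_values),
         n_pos = length(positive_values)),
    class = "mps_calibration"
  )
}

#' False-positive and false-negative rates at a threshold
#'
#' Detection declares a subregion positive when its coefficient is strictly
#' above the threshold; accordingly the false-positive rate is the fraction
#' of null values `> threshold` and the false-negative rate the fraction of
#' positive values `<= threshold`, so the two rules partition every case.
#'
#' @param null_values coefficients from structure-free subregions.
#' @param positive_values coefficients from structure-bearing subregions,
#'   or `NULL` (false-negative rate then reported as `NA`, not 0).
#' @param threshold finite numeric threshold.
#' @return Named numeric vector `c(fpr = ..., fnr = ...)`.
#' @export
false_rates <- function(null_values, positive_values, threshold) {
  stopifnot_scalar_num(threshold, "threshold")
  fpr <- if (length(null_values)) mean(null_values > threshold) else NA_real_
  fnr <- if (length(positive_values)) mean(positive_values <= threshold)
         else NA_real_
  c(fpr = fpr, fnr = fnr)
}

#' @export
print.mps_calibration <- function(x, ...) {
  lab <- if (nzchar(x$modality)) paste0(" [", x$modality, "]") else ""
  cat(sprintf("Detection threshold calibration%s\n", lab))
  cat(sprintf("  null: mean %.4f, sd %.4f (n = %d)\n",
              x$null_mean, x$null_std, x$n_null))
  cat(sprintf("  threshold = mean + %g sd = %.4f\n", x$n_sigma, x$threshold))
  cat(sprintf("  false positives: %s   false negatives: %s\n",
              ifelse(is.na(x$fpr), "-", sprintf("%.2f%%", 100 * x$fpr)),
              ifelse(is.na(x$fnr), "-", sprintf("%.2f%%", 100 * x$fnr))))
  invisible(x)
}

#' Write / read a calibration record as JSON
#'
#' @param x an `"mps_calibration"` object.
#' @param path file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns the restored `"mps_calibration"` object.
#' @export
write_calibration <- function(x, path) {
  stopifnot(inherits(x, "mps_calibration"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$fpr <- if (is.null(obj$fpr)) NA_real_ else obj$fpr
  obj$fnr <- if (is.null(obj$fnr)) NA_real_ else obj$fnr
  structure(obj, class = "mps_calibration")
}
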