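#' Load a single-channel image from a TIFF file
#'
#' Reads a grayscale TIFF (8/16-bit integer or 32-bit float) as a numeric
#' matrix. Integer data are returned on their native count scale (not
#' rescaled to `[0, 1]`). Multi-page and RGB/multi-channel files are
#' rejected with an explanatory error, since the analysis is defined on
#' single-channel 2D images.
#'
#' @param path path to the TIFF file.
#' @return Numeric matrix of intensities.
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    stop("image file not found: ", path, call. = FALSE)
  info <- tiff::readTIFF(path, payload = FALSE)
  if (!is.data.frame(info)) info <- as.data.frame(info[[1]])
  # 32 bits per sample means float storage (the only 32-bit layout the tiff
  # package reads/writes); 8/16-bit integer data keep their native counts
  is_float <- any(info$bits.per.sample >= 32) ||
    identical(info$sample.format[1], "float")
  img <- tiff::readTIFF(path, all = TRUE, as.is = !is_float)
  if (length(img) != 1L)
    stop("multi-page TIFF not supported: ", path, call. = FALSE)
  img <- img[[1]]
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1]
    else stop("RGB / multi-channel TIFF not supported (",
              dim(img)[3], " channels): ", path, call. = FALSE)
  }
  if (length(dim(img)) != 2L)
    stop("expected 2D image data in ", path, call. = FALSE)
  storage.mode(img) <- "double"
  img
}

#' Write a matrix as a TIFF image
#'
#' Logical matrices (masks, detection maps) are written as 8-bit binary.
#' Integer-valued images -- photon/count data, the common case -- are written
#' as 16-bit TIFF and round-trip exactly through [load_image()]. Fractional
#' data must lie in `[0, 1]` (stored exactly as 32-bit float); other float
#' ranges cannot be represented faithfully by the underlying TIFF writer and
#' are rejected rather than silently distorted.
#'
#' @param image numeric or logical matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (is.logical(image)) {
    tiff::writeTIFF(image * 1, path, bits.per.sample = 8L)
  } else if (all(image == round(image)) && all(image >= 0) &&
             all(image <= 65535)) {
    tiff::writeTIFF(matrix(image / 65535, nrow(image), ncol(image)),
                    path, bits.per.sample = 16L)
  } else if (all(image >= 0) && all(image <= 1)) {
    tiff::writeTIFF(matrix(as.numeric(image), nrow(image), ncol(image)),
                    path, bits.per.sample = 32L)
  } else {
    stop("fractional image data must lie in [0, 1] (or be integer counts ",
         "in [0, 65535]) for faithful TIFF storage", call. = FALSE)
  }
  invisible(path)
}

#' Read / write an analysis configuration
#'
#' Configurations are stored as YAML or JSON (decided by file extension);
#' values not present in the file keep their [mps_config()] defaults, so a
#' partial file is valid. `write_config` / `load_config` round-trip exactly.
#'
#' @param path file path (`.yaml`, `.yml`, or `.json`).
#' @param config an [mps_config()] list.
#' @return `load_config` returns an `"mps_config"` list; `write_config`
#'   returns `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(mps_config, vals)
}

#' @rdname load_config
#' @export
write_config <- function(config, path) {
  if (!inherits(config, "mps_config")) config <- do.call(mps_config, config)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write per-tile records as CSV
#'
#' Emits the per-tile record table with the fixed column set `image_id,
#' tile_row, tile_col, neuronal, direction_valid, theta_n_deg, best_rp,
#' best_theta_deg, best_phi_rad, detected`.
#'
#' @param records an `"mps_analysis"` object or compatible data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  cols <- c("image_id", "tile_row", "tile_col", "neuronal",
            "direction_valid", "theta_n_deg", "best_rp", "best_theta_deg",
            "best_phi_rad", "detected")
  utils::write.csv(as.data.frame(records)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write a batch summary as JSON
#'
#' @param x an `"mps_summary"` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  stopifnot(inherits(x, "mps_summary"))
  out <- unclass(x)
  out$detection_map <- NULL  # kept as TIFF, not JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Analyze a directory of images
#'
#' Runs [analyze_image()] on every TIFF in a directory and concatenates the
#' per-tile records. Unreadable images are skipped with a message rather
#' than aborting the batch.
#'
#' @param dir directory containing single-channel TIFF images.
#' @param threshold detection threshold (see [fit_threshold()]).
#' @param config an [mps_config()] list; supplies the pixel size.
#' @param pattern filename pattern (default all `.tif`/`.tiff`).
#' @return data.frame of per-tile records across all images, with the
#'   analysis config and threshold in attributes.
#' @export
analyze_directory <- function(dir, threshold, config = mps_config(),
                              pattern = "\\.tiff?$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (!length(files)) stop("no TIFF images found in ", dir, call. = FALSE)
  recs <- list()
  for (f in files) {
    img <- tryCatch(load_image(f), error = function(e) {
      message("skipping ", basename(f), ": ", conditionMessage(e))
      NULL
    })
    if (is.null(img)) next
    recs[[f]] <- as.data.frame(
      analyze_image(img, config$pixel_size_nm, threshold = threshold,
                    config = config, image_id = basename(f)))
  }
  out <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  attr(out, "threshold") <- threshold
  attr(out, "config") <- config
  out
}
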