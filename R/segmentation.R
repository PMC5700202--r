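#' Segment an image into square subregions
#'
#' Splits the image into non-overlapping square tiles of physical side
#' `l_sr_nm` (default 1 um, a good compromise for a 190 nm period: small
#' enough for spatial resolution, large enough to hold several periods).
#' Only complete tiles are produced; edge remainders are discarded. Tiles
#' are emitted in row-major order.
#'
#' @param image_shape integer `c(rows, cols)` of the image in pixels.
#' @param pixel_size nm per pixel.
#' @param l_sr_nm subregion side length in nm; must be at least 4 pixels.
#' @return An object of class `"mps_grid"`: list with `tile_px` (tile side
#'   in pixels), `n_rows`, `n_cols`, `l_sr_nm`, `pixel_size`, and `tiles`, a
#'   data.frame with columns `tile_row`, `tile_col`, `row0`, `row1`, `col0`,
#'   `col1` (1-based inclusive pixel bounds).
#' @examples
#' g <- segment_grid(c(500, 500), 20, 1000)  # 10 x 10 grid of 50 px tiles
#' nrow(g$tiles)
#' @export
segment_grid <- function(image_shape, pixel_size, l_sr_nm = 1000) {
  stopifnot_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  stopifnot_scalar_num(l_sr_nm, "l_sr_nm", positive = TRUE)
  shape <- as.integer(image_shape)
  tile_px <- as.integer(round(l_sr_nm / pixel_size))
  if (tile_px < 4L)
    stop("subregion size must be at least 4 pixels across", call. = FALSE)
  n_rows <- shape[1] %/% tile_px
  n_cols <- shape[2] %/% tile_px
  if (n_rows < 1L || n_cols < 1L) {
    warning("subregion size exceeds the image; no tiles produced")
    tiles <- data.frame(tile_row = integer(), tile_col = integer(),
                        row0 = integer(), row1 = integer(),
                        col0 = integer(), col1 = integer())
  } else {
    idx <- expand.grid(tile_col = seq_len(n_cols), tile_row = seq_len(n_rows))
    tiles <- data.frame(
      tile_row = idx$tile_row,
      tile_col = idx$tile_col,
      row0 = (idx$tile_row - 1L) * tile_px + 1L,
      row1 = idx$tile_row * tile_px,
      col0 = (idx$tile_col - 1L) * tile_px + 1L,
      col1 = idx$tile_col * tile_px
    )
  }
  structure(
    list(tile_px = tile_px, n_rows = n_rows, n_cols = n_cols,
         l_sr_nm = l_sr_nm, pixel_size = pixel_size, tiles = tiles),
    class = "mps_grid"
  )
}

#' @export
print.mps_grid <- function(x, ...) {
  cat(sprintf("Subregion grid: %d x %d tiles of %d px (%g nm)\n",
              x$n_rows, x$n_cols, x$tile_px, x$l_sr_nm))
  invisible(x)
}

#' Flag a tile as containing neuronal material
#'
#' A tile is catalogued as neuronal when the fraction of its pixels covered
#' by the neuron discrimination mask is at least `min_fraction` (>=
#' convention at the boundary). The default of 0.2 retains thin neurites
#' crossing a tile corner-to-corner while rejecting tiles holding only
#' stray background pixels.
#'
#' @param tile one row of the `tiles` data.frame from [segment_grid()] (or
#'   any list with `row0`, `row1`, `col0`, `col1`).
#' @param mask logical matrix (or an [discriminate()] result).
#' @param min_fraction minimum masked fraction in `[0, 1]`.
#' @return Logical scalar.
#' @export
flag_neuronal <- function(tile, mask, min_fraction = 0.2) {
  if (inherits(mask, "mps_mask")) mask <- mask$mask
  if (min_fraction < 0 || min_fraction > 1)
    stop("'min_fraction' must be in [0, 1]", call. = FALSE)
  sub <- mask[tile$row0:tile$row1, tile$col0:tile$col1]
  mean(sub) >= min_fraction
}
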