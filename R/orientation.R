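#' Progressive probabilistic Hough transform for line segments
#'
#' Detects line segments in a binary (edge) image using the progressive
#' probabilistic Hough transform: edge pixels are visited in random order,
#' each casting votes over all orientation bins of a (theta, rho)
#' accumulator; whenever a bin passes the vote threshold, the pixels lying
#' along the corresponding line are gathered into a segment (allowing gaps
#' up to `max_gap`), removed from the edge set, and their votes retracted.
#' Segments shorter than `min_len` are dropped. The randomized visiting
#' order is controlled by `seed`, making results reproducible.
#'
#' Coordinates follow the package convention: x along columns, y along
#' rows, angles in degrees measured from the column axis toward the row
#' axis, modulo 180.
#'
#' @param edges logical matrix of edge pixels.
#' @param threshold accumulator vote count required to declare a line.
#' @param min_len minimum segment length in pixels.
#' @param max_gap largest tolerated gap (pixels) between points of one
#'   segment.
#' @param theta_res orientation bin width in degrees.
#' @param seed integer seed for the randomized pixel order (`NULL` to use
#'   the current RNG stream).
#' @return data.frame with one row per segment: endpoints `x0, y0, x1, y1`
#'   (pixel units), `length` (pixels), `angle` (degrees mod 180, from the
#'   endpoints), `n_pts` (supporting pixels).
#' @export
hough_segments <- function(edges, threshold = 10, min_len = 12,
                           max_gap = 5, theta_res = 1, seed = NULL) {
  if (!is.matrix(edges)) stop("'edges' must be a matrix", call. = FALSE)
  pts <- which(edges != 0, arr.ind = TRUE)
  out <- data.frame(x0 = numeric(), y0 = numeric(), x1 = numeric(),
                    y1 = numeric(), length = numeric(), angle = numeric(),
                    n_pts = integer())
  n <- nrow(pts)
  if (n == 0L) return(out)
  x <- pts[, 2]
  y <- pts[, 1]

  thetas <- seq(0, 180 - theta_res, by = theta_res) * pi / 180
  ct <- cos(thetas); st <- sin(thetas)
  nt <- length(thetas)
  rho_max <- ceiling(sqrt(max(x)^2 + max(y)^2)) + 1L
  nr <- 2L * rho_max + 1L
  acc <- matrix(0L, nt, nr)

  alive <- rep(TRUE, n)     # still in the edge set
  voted <- rep(FALSE, n)    # has cast its votes
  consumed <- rep(FALSE, n) # already used as a seed point

  rho_bins <- function(i) as.integer(round(x[i] * ct + y[i] * st)) + rho_max + 1L

  with_seed(seed, {
    order_pool <- sample.int(n)
    for (i in order_pool) {
      if (!alive[i] || consumed[i]) next
      consumed[i] <- TRUE
      rb <- rho_bins(i)
      idx <- cbind(seq_len(nt), rb)
      acc[idx] <- acc[idx] + 1L
      voted[i] <- TRUE
      peak <- which.max(acc[idx])
      if (acc[idx][peak] < threshold) next

      # candidate line: normal at angle thetas[peak], through the peak rho
      tn <- thetas[peak]
      rho0 <- rb[peak] - rho_max - 1L
      dist <- abs(x * ct[peak] + y * st[peak] - rho0)
      cand <- which(alive & dist <= 1.5)
      if (length(cand) < 2L) next
      # project candidates along the line direction and grow from the seed
      dx <- -st[peak]; dy <- ct[peak]
      proj <- x[cand] * dx + y[cand] * dy
      ord <- order(proj)
      cand <- cand[ord]; proj <- proj[ord]
      k0 <- which(cand == i)
      if (length(k0) == 0L) k0 <- which.min(abs(proj - (x[i] * dx + y[i] * dy)))
      lo <- hi <- k0[1]
      while (lo > 1L && proj[lo] - proj[lo - 1L] <= max_gap) lo <- lo - 1L
      while (hi < length(cand) && proj[hi + 1L] - proj[hi] <= max_gap) hi <- hi + 1L
      seg <- cand[lo:hi]
      seg_len <- proj[hi] - proj[lo]

      # remove the run from the edge set and retract its votes
      for (j in seg) {
        alive[j] <- FALSE
        if (voted[j]) {
          idj <- cbind(seq_len(nt), rho_bins(j))
          acc[idj] <- acc[idj] - 1L
          voted[j] <- FALSE
        }
      }
      if (seg_len >= min_len) {
        a <- cand[lo]; b <- cand[hi]
        ang <- wrap_theta(atan2(y[b] - y[a], x[b] - x[a]) * 180 / pi)
        out <- rbind(out, data.frame(
          x0 = x[a], y0 = y[a], x1 = x[b], y1 = y[b],
          length = seg_len, angle = ang, n_pts = length(seg)))
      }
    }
  })
  out
}

# boundary of a binary mask: pixels of the mask not in its 3x3 erosion
mask_boundary <- function(mask) {
  m <- mask * 1
  er <- EBImage::erode(m, EBImage::makeBrush(3, "box"))
  (m > 0) & !(as.matrix(er) > 0)
}

# single-linkage clustering of angles (degrees) on the 180-degree circle:
# sort, cut at circular gaps larger than tol, return cluster labels
cluster_angles <- function(angles, tol = 15) {
  n <- length(angles)
  if (n == 0L) return(integer())
  if (n == 1L) return(1L)
  ord <- order(angles)
  a <- angles[ord]
  gaps <- c(diff(a), a[1] + 180 - a[n])
  labels_sorted <- cumsum(c(1, as.numeric(gaps[-n] > tol))) # cuts between i,i+1
  # merge across the wraparound if the closing gap is small
  if (gaps[n] <= tol && max(labels_sorted) > 1L)
    labels_sorted[labels_sorted == max(labels_sorted)] <- 1L
  labels <- integer(n)
  labels[ord] <- labels_sorted
  labels
}

#' Estimate the local neurite direction in a subregion
#'
#' Estimates the axon/dendrite direction inside one tile of the neuron
#' discrimination image. The boundary pixels of the binary mask (mask minus
#' its 3x3 erosion) provide the linear intensity edges; a progressive
#' probabilistic Hough transform extracts line segments; segment angles
#' (mod 180 degrees) are clustered on the circle with a fixed angular
#' linkage tolerance. If one cluster holds strictly more than half of the
#' detected segments, the direction estimate is the circular mean (period
#' 180) of that cluster; otherwise the tile is flagged invalid and is
#' discarded from further analysis (the typical causes are strong curvature
#' or crossing neurites, where no single direction is meaningful).
#'
#' @param tile_mask logical matrix: the discrimination mask restricted to
#'   one tile.
#' @param min_len_frac minimum Hough segment length as a fraction of the
#'   tile side (default 0.25).
#' @param max_gap_frac largest tolerated gap as a fraction of the tile side
#'   (default 0.10).
#' @param threshold Hough accumulator vote threshold (default 10).
#' @param cluster_tol_deg angular linkage tolerance for clustering segment
#'   directions (default 15 degrees).
#' @param weight_by `"count"` (default) counts each segment once when
#'   sizing clusters; `"length"` weights segments by their length.
#' @param seed seed for the randomized Hough transform.
#' @return An object of class `"mps_orientation"`: list with `valid`
#'   (logical), `theta_n` (degrees mod 180, `NA` when invalid),
#'   `cluster_fraction`, `n_lines`, and `segments` (the Hough segment
#'   table).
#' @examples
#' m <- matrix(FALSE, 50, 50)
#' m[abs(row(m) - col(m)) < 6] <- TRUE   # 45-degree band
#' estimate_direction(m, seed = 1)
#' @export
estimate_direction <- function(tile_mask, min_len_frac = 0.25,
                               max_gap_frac = 0.10, threshold = 10,
                               cluster_tol_deg = 15,
                               weight_by = c("count", "length"),
                               seed = NULL) {
  weight_by <- match.arg(weight_by)
  tile_mask <- tile_mask != 0
  side <- min(dim(tile_mask))
  invalid <- function(segs) structure(
    list(valid = FALSE, theta_n = NA_real_, cluster_fraction = 0,
         n_lines = nrow(segs), segments = segs),
    class = "mps_orientation")

  if (!any(tile_mask)) return(invalid(hough_segments(matrix(FALSE, 1, 1))))
  edges <- mask_boundary(tile_mask)
  segs <- hough_segments(edges, threshold = threshold,
                         min_len = min_len_frac * side,
                         max_gap = max_gap_frac * side, seed = seed)
  if (nrow(segs) == 0L) return(invalid(segs))

  labels <- cluster_angles(segs$angle, tol = cluster_tol_deg)
  w <- if (weight_by == "length") segs$length else rep(1, nrow(segs))
  totals <- tapply(w, labels, sum)
  main <- as.integer(names(totals)[which.max(totals)])
  frac <- max(totals) / sum(w)
  if (frac <= 0.5) {
    res <- invalid(segs)
    res$cluster_fraction <- frac
    return(res)
  }
  theta_n <- circ_mean(segs$angle[labels == main], period = 180)
  structure(
    list(valid = TRUE, theta_n = theta_n, cluster_fraction = frac,
         n_lines = nrow(segs), segments = segs),
    class = "mps_orientation"
  )
}

#' @export
print.mps_orientation <- function(x, ...) {
  if (x$valid)
    cat(sprintf(
      "Neurite direction: theta_N = %.1f deg (%d segments, %.0f%% in main cluster)\n",
      x$theta_n, x$n_lines, 100 * x$cluster_fraction))
  else
    cat(sprintf(
      "Neurite direction: undetermined (%d segments, largest cluster %.0f%%)\n",
      x$n_lines, 100 * x$cluster_fraction))
  invisible(x)
}
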