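#' Coverage configuration
#'
#' Settings for the threshold-coverage diversity metric: ball radius
#' `epsilon` in normalized units (default 0.05), the normalization box used
#' to rescale descriptors to the unit square, and the integration grid
#' resolution. Degenerate box axes are floored at 1e-6 extent.
#'
#' @param epsilon ball radius after rescaling to the unit square.
#' @param box optional 2 x 2 matrix `rbind(low, high)` per axis; `NULL` means
#'   the unit box `[0,1]^2` (points assumed pre-normalized).
#' @param resolution integration grid cells per axis.
#' @return An object of class `grn_coverage_config`.
#' @export
coverage_config <- function(epsilon = 0.05, box = NULL, resolution = 2000L) {
  stopifnot(epsilon > 0, resolution >= 10)
  structure(list(epsilon = epsilon, box = box,
                 resolution = as.integer(resolution)),
            class = "grn_coverage_config")
}

normalize_points <- function(points, box, d = 2L) {
  points <- if (is.matrix(points)) points else matrix(points, ncol = d)
  if (is.null(box)) return(points)
  lo <- box[1, ]; ext <- pmax(box[2, ] - box[1, ], 1e-6)
  sweep(sweep(points, 2, lo), 2, ext, "/")
}

#' Threshold coverage (union of epsilon-balls)
#'
#' Diversity of a 2-D descriptor set: the area of the union of epsilon-disks
#' centered on the points (after rescaling to the unit square), divided by
#' the area `(1 + 2 epsilon)^2` of the epsilon-padded unit square. Four
#' mutually disjoint attractors thus score
#' `4 pi epsilon^2 / (1 + 2 epsilon)^2 = 0.026` at `epsilon = 0.05`. Computed
#' by deterministic uniform-grid integration over the padded square; disk
#' area overhanging the unit square still counts (it cannot exit the padded
#' square for in-box points).
#'
#' @param points N x 2 matrix of descriptors (rows with NA are dropped).
#' @param config a [coverage_config()].
#' @return coverage fraction in `[0, 1]`.
#' @export
threshold_coverage <- function(points, config = coverage_config()) {
  points <- if (is.matrix(points)) points else matrix(points, ncol = 2)
  points <- points[stats::complete.cases(points), , drop = FALSE]
  if (nrow(points) == 0) return(0)
  points <- normalize_points(points, config$box)
  eps <- config$epsilon
  G <- config$resolution
  cell <- (1 + 2 * eps) / G
  centers <- -eps + (seq_len(G) - 0.5) * cell
  covered <- matrix(FALSE, G, G)
  r_cells <- ceiling(eps / cell) + 1L
  for (k in seq_len(nrow(points))) {
    px <- points[k, 1]; py <- points[k, 2]
    ix <- which.min(abs(centers - px))
    iy <- which.min(abs(centers - py))
    xs <- max(1L, ix - r_cells):min(G, ix + r_cells)
    ys <- max(1L, iy - r_cells):min(G, iy + r_cells)
    dx2 <- (centers[xs] - px)^2
    dy2 <- (centers[ys] - py)^2
    covered[xs, ys] <- covered[xs, ys] | (outer(dx2, dy2, "+") <= eps^2)
  }
  sum(covered) / (G * G)
}

#' Binning-based coverage
#'
#' Fraction of occupied bins on a regular grid over the normalization box;
#' the standard diversity measure for behavior spaces above two dimensions
#' (20 bins per dimension for the 3-D oscillation space).
#'
#' @param points N x d matrix of descriptors (NA rows dropped; points outside
#'   the box are clipped to the boundary bins).
#' @param bins_per_dim bins per dimension.
#' @param box 2 x d matrix `rbind(low, high)`.
#' @return occupied-bin fraction in `[0, 1]`.
#' @export
binning_coverage <- function(points, bins_per_dim = 20L, box) {
  points <- if (is.matrix(points)) points else matrix(points, nrow = 1)
  points <- points[stats::complete.cases(points), , drop = FALSE]
  if (nrow(points) == 0) return(0)
  d <- ncol(points)
  stopifnot(ncol(box) == d, bins_per_dim >= 1)
  lo <- box[1, ]; ext <- pmax(box[2, ] - box[1, ], 1e-6)
  u <- sweep(sweep(points, 2, lo), 2, ext, "/")
  idx <- pmin(pmax(floor(u * bins_per_dim), 0), bins_per_dim - 1)
  keys <- apply(idx, 1, paste, collapse = ",")
  length(unique(keys)) / bins_per_dim^d
}
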