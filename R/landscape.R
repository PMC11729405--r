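#' Trajectory-based pseudopotential energy landscape
#'
#' Histograms every visited trajectory state, projected onto the 2-D
#' behavior plane, over a `G x G` grid; adds a pseudocount per cell;
#' normalizes into a visit probability `P`; and converts it to the
#' pseudopotential `U = -ln(P)`. Attractors appear as local minima of `U`.
#' Optional smoothing fits cubic smoothing splines along the grid rows and
#' columns (two-pass); the default `smoothing = 0` is interpolating, i.e.
#' leaves the gridded `U` untouched. All time points are weighted uniformly
#' (full trajectories are histogrammed, no burn-in discard).
#'
#' @param trajectories list of `grn_trajectory` (invalid ones are skipped).
#' @param nodes behavior plane node pair (1-based).
#' @param grid_size cells per axis `G`.
#' @param pseudocount count added to every cell before normalization.
#' @param box 2 x 2 normalization box `rbind(low, high)`; defaults to the
#'   bounding box of the visited states.
#' @param smoothing nonnegative spline smoothing parameter (`spar`-like;
#'   passed to [stats::smooth.spline()] when positive).
#' @return An object of class `grn_landscape` with fields `x`, `y` (cell
#'   centers), `P`, `U` (G x G matrices) and the settings used.
#' @export
estimate_energy_landscape <- function(trajectories, nodes = c(1L, 2L),
                                      grid_size = 100L, pseudocount = 0.5,
                                      box = NULL, smoothing = 0) {
  pts <- do.call(rbind, lapply(trajectories, function(tr) {
    if (!is_valid_trajectory(tr)) return(NULL)
    tr$states[, nodes, drop = FALSE]
  }))
  if (is.null(pts) || nrow(pts) == 0) stop("no valid trajectories")
  if (is.null(box))
    box <- rbind(apply(pts, 2, min), apply(pts, 2, max))
  G <- as.integer(grid_size)
  lo <- box[1, ]; ext <- pmax(box[2, ] - box[1, ], 1e-6)
  ix <- pmin(pmax(floor((pts[, 1] - lo[1]) / ext[1] * G), 0), G - 1)
  iy <- pmin(pmax(floor((pts[, 2] - lo[2]) / ext[2] * G), 0), G - 1)
  counts <- matrix(0, G, G)
  tab <- table(ix * G + iy)
  idx <- as.integer(names(tab))
  counts[cbind(idx %/% G + 1L, idx %% G + 1L)] <- as.numeric(tab)
  counts <- counts + pseudocount
  P <- counts / sum(counts)
  U <- -log(P)
  if (smoothing > 0) {
    xs <- seq_len(G)
    for (i in seq_len(G))
      U[i, ] <- stats::smooth.spline(xs, U[i, ], spar = smoothing)$y
    for (j in seq_len(G))
      U[, j] <- stats::smooth.spline(xs, U[, j], spar = smoothing)$y
  }
  structure(list(x = lo[1] + (seq_len(G) - 0.5) * ext[1] / G,
                 y = lo[2] + (seq_len(G) - 0.5) * ext[2] / G,
                 P = P, U = U, box = box, grid_size = G,
                 pseudocount = pseudocount, smoothing = smoothing,
                 occupied = sum(counts > pseudocount)),
            class = "grn_landscape")
}

#' @export
print.grn_landscape <- function(x, ...) {
  cat("Energy landscape:", x$grid_size, "x", x$grid_size, "grid,",
      x$occupied, "occupied cells, U in [",
      format(min(x$U)), ",", format(max(x$U)), "]\n")
  invisible(x)
}

#' Local minima of an energy landscape
#'
#' Cells whose energy is strictly below all 8-neighborhood neighbors, the
#' basin bottoms (attractors) of the pseudopotential. Cells never visited
#' (pseudocount-only, all sharing the maximal energy) are excluded.
#'
#' @param landscape a `grn_landscape`.
#' @return data.frame `(i, j, x, y, U)` of local minima.
#' @export
landscape_minima <- function(landscape) {
  U <- landscape$U
  G <- landscape$grid_size
  Umax <- max(U)
  out <- list()
  for (i in seq_len(G)) for (j in seq_len(G)) {
    if (U[i, j] >= Umax) next
    nb <- expand.grid(di = -1:1, dj = -1:1)
    nb <- nb[!(nb$di == 0 & nb$dj == 0), ]
    ii <- i + nb$di; jj <- j + nb$dj
    keep <- ii >= 1 & ii <= G & jj >= 1 & jj <= G
    if (all(U[i, j] < U[cbind(ii[keep], jj[keep])]))
      out[[length(out) + 1]] <- data.frame(
        i = i, j = j, x = landscape$x[i], y = landscape$y[j], U = U[i, j])
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(i = integer(0), j = integer(0), x = numeric(0),
                  y = numeric(0), U = numeric(0))
}

#' Export a landscape as a gridded table
#'
#' @param landscape a `grn_landscape`.
#' @return data.frame `(x, y, P, U)`, one row per cell, suitable for
#'   external surface rendering.
#' @export
landscape_table <- function(landscape) {
  g <- expand.grid(i = seq_len(landscape$grid_size),
                   j = seq_len(landscape$grid_size))
  data.frame(x = landscape$x[g$i], y = landscape$y[g$j],
             P = landscape$P[cbind(g$i, g$j)],
             U = landscape$U[cbind(g$i, g$j)])
}
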