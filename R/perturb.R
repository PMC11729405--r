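#' Default perturbation evaluation grid
#'
#' The 18-sub-family battery: six noise sub-families `(sigma_n, p_n)`, six
#' push sub-families `(m_p, n_p)` and six wall sub-families `(l_w, n_w)`,
#' with `r = 3` replicate draws per sub-family (P = 54 perturbations per
#' goal). The printed sextuples are read magnitude-first for the first three
#' entries and count-first for the last three (fractional event counts being
#' meaningless), which keeps the duplicated middle sub-family of each family.
#'
#' @param replicates draws per sub-family.
#' @return An object of class `grn_perturbation_grid`: a data.frame with
#'   columns `family`, `scale` (sigma_n / m_p / l_w), `aux` (period seconds /
#'   event count) plus a `replicates` attribute.
#' @export
default_perturbation_grid <- function(replicates = 3L) {
  g <- rbind(
    data.frame(family = "noise",
               scale = c(0.001, 0.005, 0.1, 0.005, 0.005, 0.005),
               aux = c(5, 5, 5, 10, 5, 1)),
    data.frame(family = "push",
               scale = c(0.05, 0.1, 0.15, 0.1, 0.1, 0.1),
               aux = c(1, 1, 1, 1, 2, 3)),
    data.frame(family = "wall",
               scale = c(0.05, 0.1, 0.15, 0.1, 0.1, 0.1),
               aux = c(1, 1, 1, 1, 2, 3)))
  perturbation_grid(g, replicates)
}

#' @rdname default_perturbation_grid
#' @param subfamilies data.frame with columns `family` (noise|push|wall),
#'   `scale`, `aux`; may be empty for a no-op battery.
#' @export
perturbation_grid <- function(subfamilies, replicates = 3L) {
  stopifnot(all(subfamilies$family %in% c("noise", "push", "wall")),
            all(subfamilies$scale >= 0), replicates >= 1)
  structure(subfamilies, replicates = as.integer(replicates),
            class = c("grn_perturbation_grid", "data.frame"))
}

# Per-dimension (max - min) of the reference trajectory in given coords.
reference_extent <- function(reference, coords) {
  apply(reference$states[, coords, drop = FALSE], 2,
        function(v) diff(range(v, na.rm = TRUE)))
}

# Settling time reusing the curation criterion on the perturbed coords:
# first t with ||y(t) - y(T)|| < 0.02 * ||y(T) - y(0)|| (horizon if never).
settling_time <- function(reference, coords, frac = 0.02) {
  S <- reference$states[, coords, drop = FALSE]
  M <- nrow(S)
  lim <- frac * sqrt(sum((S[M, ] - S[1, ])^2))
  dev <- sqrt(rowSums(sweep(S, 2, S[M, ])^2))
  k <- which(dev < lim)[1]
  if (is.na(k)) reference$T else reference$times[k]
}

#' Sample a trajectory-conditioned perturbation
#'
#' Realizes one perturbation instance of the given family, conditioned on the
#' unperturbed reference trajectory so magnitudes scale with the behavior the
#' system actually exhibits:
#' \itemize{
#'   \item noise: i.i.d. Gaussian kicks with per-coordinate standard
#'     deviation `scale * extent`, applied every `aux` seconds from t = 0
#'     until `window` seconds;
#'   \item push: `aux` instantaneous displacements at times drawn uniformly
#'     in the transient `[0, settling time]`, each of per-axis magnitude
#'     `scale * extent` along a uniformly random direction;
#'   \item wall: `aux` segments of length `scale * ||extent||`, centered at
#'     uniformly sampled fractions of the cumulative path length of the
#'     reference in the 2-D behavior plane, oriented perpendicular to the
#'     local motion direction.
#' }
#' A degenerate reference (zero extent) yields zero magnitudes and is
#' flagged.
#'
#' @param family `"noise"`, `"push"` or `"wall"`.
#' @param scale family magnitude scale (sigma_n, m_p or l_w).
#' @param aux noise period in seconds, or event/wall count.
#' @param reference the unperturbed `grn_trajectory`.
#' @param coords 1-based perturbed node indices (length 2 for walls).
#' @param window noise application window in seconds from t = 0.
#' @param seed optional RNG seed for exact replay.
#' @return An object of class `grn_perturbation` with the realized events.
#' @export
sample_perturbation <- function(family = c("noise", "push", "wall"),
                                scale, aux, reference, coords,
                                window = 80, seed = NULL) {
  family <- match.arg(family)
  stopifnot(is_valid_trajectory(reference))
  n <- ncol(reference$states)
  extent <- reference_extent(reference, coords)
  degenerate <- all(extent == 0)
  events <- NULL; walls <- NULL
  with_seed(seed, {
    if (family == "noise") {
      times <- seq(aux, min(window, reference$T), by = aux)
      disp <- matrix(0, length(times), n)
      disp[, coords] <- rnorm(length(times) * length(coords)) *
        rep(scale * extent, each = length(times))
      events <- list(times = times, disp = disp)
    } else if (family == "push") {
      np <- as.integer(aux)
      tset <- settling_time(reference, coords)
      times <- sort(runif(np, 0, tset))
      disp <- matrix(0, np, n)
      for (k in seq_len(np)) {
        u <- rnorm(length(coords))
        u <- u / max(sqrt(sum(u^2)), 1e-12)
        disp[k, coords] <- scale * extent * u
      }
      events <- list(times = times, disp = disp)
    } else {
      stopifnot(length(coords) == 2)
      nw <- as.integer(aux)
      path <- reference$states[, coords, drop = FALSE]
      seglen <- sqrt(rowSums(diff(path)^2))
      cum <- c(0, cumsum(seglen))
      total <- cum[length(cum)]
      len <- scale * sqrt(sum(extent^2))
      walls <- matrix(0, nw, 4)
      fracs <- runif(nw)
      for (k in seq_len(nw)) {
        s <- fracs[k] * total
        i <- max(1L, findInterval(s, cum, rightmost.closed = TRUE))
        i <- min(i, nrow(path) - 1L)
        denom <- max(cum[i + 1] - cum[i], 1e-300)
        w <- (s - cum[i]) / denom
        ctr <- (1 - w) * path[i, ] + w * path[i + 1, ]
        dirv <- path[i + 1, ] - path[i, ]
        dn <- sqrt(sum(dirv^2))
        dirv <- if (dn > 0) dirv / dn else c(1, 0)
        perp <- c(-dirv[2], dirv[1])
        walls[k, ] <- c(ctr - perp * len / 2, ctr + perp * len / 2)[c(1, 2, 3, 4)]
      }
    }
  })
  structure(list(family = family, scale = scale, aux = aux, coords = coords,
                 window = window, events = events, walls = walls,
                 extent = extent, degenerate = degenerate, seed = seed),
            class = "grn_perturbation")
}

#' Apply a realized perturbation to a rollout
#'
#' Re-runs the model from the same initial state with the sampled
#' perturbation active: noise and push events are instantaneous state
#' displacements (integration restarts after each on the adaptive path);
#' walls are hard constraints in the 2-D behavior plane (crossing steps are
#' projected back to the pre-crossing side with tangential sliding); all
#' other coordinates evolve freely.
#'
#' @param model a `grn_circuit`, `grn_ode` or `grn_map`.
#' @param y0 the reference initial state.
#' @param spec a `grn_perturbation`.
#' @param config a [rollout_config()].
#' @return A `grn_trajectory`.
#' @export
apply_perturbation <- function(model, y0, spec, config = rollout_config()) {
  walls <- spec$walls
  wall_coords <- if (!is.null(walls)) spec$coords else c(1L, 2L)
  if (inherits(model, "grn_circuit"))
    simulate_gene_circuit(model, y0, config, events = spec$events,
                          walls = walls, wall_coords = wall_coords)
  else simulate_ode(model, y0, config, events = spec$events,
                    walls = walls, wall_coords = wall_coords)
}
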