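#' Classify a trajectory: validity, settledness, periodicity
#'
#' Applies the curation criteria to one target node of a trajectory:
#' \itemize{
#'   \item valid: no NaN and no negative state anywhere in the trajectory;
#'   \item settled: no late time `t >= T - settle_window` with
#'     `|y(t) - y(T)| >= settle_frac * |y(T) - y(0)|` (per-node scalar
#'     absolute differences; defaults 100 s and 0.02, i.e. `t >= 2400` at the
#'     default horizon `T = 2500`);
#'   \item periodic: some non-DC bin of the unnormalized DFT of the
#'     second-half window `[T/2, T]` has magnitude `>= dft_threshold`
#'     (default 40, calibrated to the default grid's 12,501-point window;
#'     the window length used is recorded in the diagnostics).
#' }
#' Classification never raises; invalid trajectories report `settled` and
#' `periodic` as `FALSE`.
#'
#' @param traj a `grn_trajectory`.
#' @param node 1-based target node.
#' @param settle_window seconds before the horizon checked for settledness.
#' @param settle_frac settledness tolerance factor.
#' @param dft_threshold periodicity threshold on the unnormalized DFT
#'   magnitude.
#' @return list with flags `valid`, `settled`, `periodic` and `diagnostics`
#'   (offending time, peak frequency/magnitude, window length).
#' @export
classify_trajectory <- function(traj, node = 1L, settle_window = 100,
                                settle_frac = 0.02, dft_threshold = 40) {
  valid <- is_valid_trajectory(traj)
  if (!valid)
    return(list(valid = FALSE, settled = FALSE, periodic = FALSE,
                diagnostics = list()))
  x <- traj$states[, node]
  M <- length(x)
  late <- traj$times >= traj$T - settle_window
  dev <- abs(x[late] - x[M])
  lim <- settle_frac * abs(x[M] - x[1])
  # strict reading: |y(t)-y(T)| >= frac*|y(T)-y(0)|; a constant trajectory
  # (lim 0, dev 0) counts as settled
  unsettled <- dev >= lim & !(dev == 0 & lim == 0)
  settled <- !any(unsettled)
  s <- half_window_spectrum(traj, node)
  nw <- length(s)
  peak <- if (nw > 1) max(s[-1]) else 0
  fpk <- if (nw > 1) (which.max(s[-1])) / (nw * traj$dt) else 0
  list(valid = TRUE,
       settled = settled,
       periodic = peak >= dft_threshold,
       diagnostics = list(
         first_unsettled_time = if (settled) NA_real_ else
           traj$times[late][which(unsettled)[1]],
         peak_magnitude = peak, peak_frequency = fpk, window_length = nw))
}

#' Sustained-oscillation detector
#'
#' A trajectory node shows sustained oscillation iff it is valid and the
#' periodicity criterion fires (second-half unnormalized DFT with a non-DC
#' magnitude at or above the threshold). Decaying transients fall below the
#' threshold because only the settled half-window is transformed.
#'
#' @inheritParams classify_trajectory
#' @return logical flag.
#' @export
is_sustained_oscillator <- function(traj, node = 1L, dft_threshold = 40) {
  cl <- classify_trajectory(traj, node, dft_threshold = dft_threshold)
  isTRUE(cl$valid) && isTRUE(cl$periodic)
}

#' System-level curation filters F1/F2/F3
#'
#' Applies the three database filters to a batch of trajectories from random
#' initial states, for one behavior node pair:
#' \itemize{
#'   \item F1 fails when at least `f1_prop` (default 20%) of the trajectories
#'     are invalid, unsettled or periodic on either node of the pair;
#'   \item F2 fails when the endpoint range `max - min` is below `f2_range`
#'     (default 0.1) on either axis;
#'   \item F3 fails when the endpoints occupy at most `f3_bins` (default 4)
#'     bins of a 20 x 20 binning of the behavior plane (binned over the
#'     endpoint bounding box).
#' }
#'
#' @param trajectories list of `grn_trajectory` (the protocol uses 50 rollouts
#'   from initial states drawn uniformly in the intervention space).
#' @param nodes behavior node pair (1-based).
#' @param f1_prop,f2_range,f3_bins filter thresholds.
#' @return list with `pass` flag, failing `reason` (`NA` or `"F1"/"F2"/"F3"`,
#'   first failing filter), and per-filter diagnostics.
#' @export
apply_system_filters <- function(trajectories, nodes = c(1L, 2L),
                                 f1_prop = 0.2, f2_range = 0.1, f3_bins = 4L) {
  flagged <- vapply(trajectories, function(tr) {
    cls <- lapply(nodes, function(nd) classify_trajectory(tr, nd))
    !all(vapply(cls, `[[`, TRUE, "valid")) ||
      any(!vapply(cls, `[[`, TRUE, "settled")) ||
      any(vapply(cls, `[[`, TRUE, "periodic"))
  }, logical(1))
  prop <- mean(flagged)
  ok <- !flagged & vapply(trajectories, is_valid_trajectory, logical(1))
  ends <- t(vapply(trajectories[ok],
                   function(tr) tr$states[nrow(tr$states), nodes],
                   numeric(2)))
  ranges <- if (nrow(ends)) apply(ends, 2, function(v) diff(range(v))) else c(0, 0)
  nbins <- 0L
  if (nrow(ends)) {
    box <- rbind(apply(ends, 2, min), apply(ends, 2, max))
    nbins <- as.integer(round(binning_coverage(ends, 20L, box) * 400))
  }
  reason <- NA_character_
  if (prop >= f1_prop) reason <- "F1"
  else if (any(ranges < f2_range)) reason <- "F2"
  else if (nbins <= f3_bins) reason <- "F3"
  list(pass = is.na(reason), reason = reason,
       f1_proportion = prop, f2_ranges = ranges, f3_bin_count = nbins)
}

#' Run the full curation protocol on a model
#'
#' Simulates `n_rollouts` trajectories from initial states drawn uniformly in
#' the intervention space and applies [apply_system_filters()].
#'
#' @param model a `grn_circuit` or `grn_ode`.
#' @param ispace initial-state [intervention_space()].
#' @param nodes behavior node pair.
#' @param n_rollouts batch size (protocol default 50).
#' @param config a [rollout_config()].
#' @param seed RNG seed for the initial-state draws.
#' @return the [apply_system_filters()] verdict, plus the endpoint matrix.
#' @export
run_filter_protocol <- function(model, ispace, nodes = c(1L, 2L),
                                n_rollouts = 50L, config = rollout_config(),
                                seed = NULL) {
  y0s <- with_seed(seed, {
    matrix(runif(n_rollouts * ispace$d, rep(ispace$low, each = n_rollouts),
                 rep(ispace$high, each = n_rollouts)),
           nrow = n_rollouts)
  })
  trajs <- lapply(seq_len(n_rollouts), function(k) {
    if (inherits(model, "grn_circuit"))
      simulate_gene_circuit(model, y0s[k, ], config)
    else simulate_ode(model, y0s[k, ], config)
  })
  res <- apply_system_filters(trajs, nodes)
  res$endpoints <- t(vapply(trajs, function(tr) tr$states[nrow(tr$states), nodes],
                            numeric(2)))
  res
}
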