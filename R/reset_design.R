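#' Stepwise clamp schedule
#'
#' A piecewise-constant stimuli intervention: one node is clamped (hard
#' state overwrite at every output step) to a sequence of levels, switching
#' every `interval` seconds for `duration` seconds in total, then released.
#' The benchmark cadence is 10 levels, every 10 s for 100 s.
#'
#' @param node clamped node (1-based).
#' @param values nonnegative clamp levels, one per interval.
#' @param interval seconds between level switches.
#' @param duration total clamp time; `duration / interval` must equal
#'   `length(values)`.
#' @return An object of class `grn_clamp_schedule`.
#' @export
clamp_schedule <- function(node, values, interval = 10, duration = 100) {
  stopifnot(all(values >= 0),
            abs(duration / interval - length(values)) < 1e-8)
  structure(list(node = as.integer(node), values = as.numeric(values),
                 interval = interval, duration = duration),
            class = "grn_clamp_schedule")
}

# Expand a schedule into per-output-step clamp rows for the rollout hooks.
schedule_to_clamps <- function(schedule, config) {
  if (is.null(schedule)) return(NULL)
  times <- seq(config$dt, schedule$duration, by = config$dt)
  idx <- pmin(length(schedule$values),
              floor((times - 1e-9) / schedule$interval) + 1L)
  data.frame(time = times, node = schedule$node,
             value = schedule$values[idx])
}

#' Evaluate a setpoint-reset intervention
#'
#' Scores a clamp schedule on its ability to drive a set of (undesired)
#' steady states to a target setpoint in behavior space, robustly: for each
#' start state (crossed with each battery draw when a perturbation grid is
#' supplied), the model is rolled out with the clamp hooks active for the
#' schedule window and free evolution afterwards, and the score is the mean
#' Euclidean distance of the reached endpoints to the target. Lower is
#' better. With the battery disabled the evaluation is deterministic given
#' the schedule.
#'
#' @param model a `grn_circuit` or `grn_ode`.
#' @param start_states matrix of start states (rows), e.g. settled endpoints
#'   of prior rollouts.
#' @param schedule a [clamp_schedule()] (or `NULL` for the no-intervention
#'   null).
#' @param target length-2 target setpoint in the behavior plane.
#' @param nodes behavior node pair.
#' @param battery optional [perturbation_grid()] applied on top of the
#'   clamped rollouts.
#' @param config a [rollout_config()].
#' @param seed RNG seed for the battery draws.
#' @return list with `score` (mean endpoint distance to target), `endpoints`,
#'   and `n_invalid` (invalid rollouts, excluded from the mean).
#' @export
evaluate_reset <- function(model, start_states, schedule, target,
                           nodes = c(1L, 2L), battery = NULL,
                           config = rollout_config(), seed = NULL) {
  start_states <- as.matrix(start_states)
  clamps <- schedule_to_clamps(schedule, config)
  sim <- function(y0, events = NULL, walls = NULL) {
    if (inherits(model, "grn_circuit"))
      simulate_gene_circuit(model, y0, config, events = events,
                            clamps = clamps, walls = walls,
                            wall_coords = nodes)
    else simulate_ode(model, y0, config, events = events, clamps = clamps,
                      walls = walls, wall_coords = nodes)
  }
  dists <- c(); n_invalid <- 0L
  ends <- list()
  seeds <- derive_seeds(if (is.null(seed)) 0L else seed,
                        paste0("start", seq_len(nrow(start_states))))
  for (s in seq_len(nrow(start_states))) {
    y0 <- start_states[s, ]
    trajs <- list()
    if (is.null(battery) || nrow(battery) == 0) {
      trajs <- list(sim(y0))
    } else {
      ref <- sim(y0)
      reps <- attr(battery, "replicates")
      for (g in seq_len(nrow(battery))) for (r in seq_len(reps)) {
        sp <- sample_perturbation(
          battery$family[g], battery$scale[g], battery$aux[g], ref, nodes,
          seed = if (is.null(seed)) NULL else
            (seeds[[s]] + g * 1009L + r) %% 2147483647L)
        trajs[[length(trajs) + 1]] <- sim(y0, events = sp$events,
                                          walls = sp$walls)
      }
    }
    for (tr in trajs) {
      if (!is_valid_trajectory(tr)) { n_invalid <- n_invalid + 1L; next }
      z <- tr$states[nrow(tr$states), nodes]
      ends[[length(ends) + 1]] <- z
      dists <- c(dists, sqrt(sum((z - target)^2)))
    }
  }
  list(score = if (length(dists)) mean(dists) else Inf,
       endpoints = if (length(ends)) do.call(rbind, ends) else NULL,
       n_invalid = n_invalid)
}

#' Random search for a setpoint-reset schedule
#'
#' Samples candidate clamp-value sequences log-uniformly in
#' `[0.1x, 10x]` of the start states' clamp-node level (the "near the
#' current steady states" range) and returns the schedule with the best
#' (lowest) [evaluate_reset()] score.
#'
#' @inheritParams evaluate_reset
#' @param node clamped node.
#' @param candidate_count candidates evaluated (>= 1).
#' @param n_levels,interval,duration schedule shape (defaults: 10 levels
#'   every 10 s for 100 s).
#' @param range_factor half-decade span factor of the log-uniform range.
#' @return list with `schedule` (best [clamp_schedule()]), `score`, and the
#'   `null_score` of the no-clamp baseline.
#' @export
search_reset_intervention <- function(model, start_states, target, node,
                                      candidate_count = 50L,
                                      nodes = c(1L, 2L), battery = NULL,
                                      n_levels = 10L, interval = 10,
                                      duration = 100, range_factor = 10,
                                      config = rollout_config(),
                                      seed = NULL) {
  stopifnot(candidate_count >= 1)
  start_states <- as.matrix(start_states)
  base <- mean(start_states[, node])
  base <- max(base, 1e-6)
  lo <- log(base / range_factor); hi <- log(base * range_factor)
  cand_values <- with_seed(seed, {
    matrix(exp(runif(candidate_count * n_levels, lo, hi)),
           nrow = candidate_count)
  })
  null_score <- evaluate_reset(model, start_states, NULL, target, nodes,
                               battery, config, seed)$score
  best <- NULL; best_score <- Inf
  for (k in seq_len(candidate_count)) {
    sch <- clamp_schedule(node, cand_values[k, ], interval, duration)
    sc <- evaluate_reset(model, start_states, sch, target, nodes, battery,
                         config, seed)$score
    if (sc < best_score) { best_score <- sc; best <- sch }
  }
  list(schedule = best, score = best_score, null_score = null_score)
}
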