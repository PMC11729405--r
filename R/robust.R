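#' Select a diversity-maximizing representative subset
#'
#' Draws `draws` random K-subsets of the valid catalog records and returns
#' the subset with the maximal threshold coverage — the representative goal
#' states subjected to the robustness battery. `K = N/10` by default (the
#' full catalog is also admissible with `K = N`).
#'
#' @param catalog a `grn_catalog` with a 2-D (endpoint) descriptor space.
#' @param K subset size; must not exceed the valid record count.
#' @param draws number of random subsets scored.
#' @param epsilon coverage ball radius.
#' @param resolution coverage integration resolution used for subset scoring.
#' @param box normalization box for coverage (default: bounding box of all
#'   valid descriptors).
#' @param seed RNG seed.
#' @return integer vector of selected record indices (into the catalog).
#' @export
select_representative_subset <- function(catalog, K = NULL, draws = 500L,
                                         epsilon = 0.05, resolution = 512L,
                                         box = NULL, seed = NULL) {
  ok <- which(catalog$valid)
  if (is.null(K)) K <- max(1L, floor(length(ok) / 10))
  if (K > length(ok)) stop("K exceeds the number of valid records")
  if (K == length(ok)) return(ok)
  Z <- catalog$descriptors[ok, , drop = FALSE]
  if (is.null(box))
    box <- rbind(apply(Z, 2, min), apply(Z, 2, max))
  cfg <- coverage_config(epsilon, box, resolution)
  with_seed(seed, {
    best <- NULL; best_cov <- -1
    for (d in seq_len(draws)) {
      idx <- sample(length(ok), K)
      cov <- threshold_coverage(Z[idx, , drop = FALSE], cfg)
      if (cov > best_cov) { best_cov <- cov; best <- idx }
    }
    ok[sort(best)]
  })
}

#' Run the robustness battery on selected goals
#'
#' For each selected record, replays its unperturbed reference trajectory,
#' samples `replicates` perturbations from every sub-family of the grid
#' (conditioned on that reference), re-runs the rollout from the same
#' initial state with each perturbation applied, and attaches the
#' `(perturbation, descriptor)` outcomes to the catalog record.
#'
#' @param catalog a `grn_catalog` over an endpoint behavior space.
#' @param subset record indices (e.g. from
#'   [select_representative_subset()]).
#' @param grid a [perturbation_grid()]; an empty grid is a no-op.
#' @param window noise window in seconds.
#' @param seed RNG seed.
#' @return the catalog, augmented with per-record perturbation outcomes.
#' @export
run_robustness_battery <- function(catalog, subset,
                                   grid = default_perturbation_grid(),
                                   window = 80, seed = NULL) {
  if (nrow(grid) == 0) return(catalog)
  reps <- attr(grid, "replicates")
  system <- catalog$system
  stopifnot(system$bspace$encoder == "endpoint")
  coords <- system$bspace$nodes
  seeds <- derive_seeds(if (is.null(seed)) 0L else seed,
                        paste0("goal", subset))
  for (jj in seq_along(subset)) {
    k <- subset[jj]
    ref <- replay_record(catalog, k)
    y0 <- record_initial_state(catalog, k, ref)
    recs <- list()
    sub_seed <- seeds[[jj]]
    for (g in seq_len(nrow(grid))) {
      for (r in seq_len(reps)) {
        s <- (sub_seed + g * 1009L + r) %% 2147483647L
        spec <- sample_perturbation(grid$family[g], grid$scale[g], grid$aux[g],
                                    ref, coords, window = window,
                                    seed = if (is.null(seed)) NULL else s)
        ptraj <- apply_perturbation(perturbed_model(catalog, k), y0, spec,
                                    system$config)
        zp <- encode_behavior(ptraj, system$bspace)
        recs[[length(recs) + 1]] <-
          list(family = grid$family[g], scale = grid$scale[g],
               aux = grid$aux[g], replicate = r, spec = spec, z = zp,
               valid = is_valid_trajectory(ptraj) && all(is.finite(zp)))
      }
    }
    catalog$perturbations[[k]] <- recs
  }
  catalog
}

# The model and initial state a record's rollout used.
record_initial_state <- function(catalog, k, ref) {
  sp <- catalog$system$ispace
  if (sp$kind == "initial-state") catalog$interventions[k, ]
  else ref$states[1, ]
}

perturbed_model <- function(catalog, k) {
  sp <- catalog$system$ispace
  if (sp$kind == "initial-state") catalog$system$model
  else {
    n <- as.integer((-2 + sqrt(4 + 4 * sp$d)) / 2)
    unpack_circuit_intervention(catalog$interventions[k, ], n)$model
  }
}

#' Per-goal sensitivity to the perturbation battery
#'
#' Sensitivity of a goal state is the mean, over its valid perturbed
#' rollouts, of the endpoint displacement `||z_p - z||` in behavior space,
#' normalized by the extent of the unperturbed trajectory in Z (the
#' Euclidean norm of the per-axis max - min). Invalid perturbed rollouts are
#' excluded from the mean and counted separately. A zero-extent reference
#' reports absolute (unnormalized) sensitivity with a flag.
#'
#' @param catalog a battery-augmented `grn_catalog`.
#' @param subset record indices to score (default: all with attached
#'   perturbations).
#' @return data.frame with one row per (goal, family, sub-family, replicate)
#'   plus attributes; see [sensitivity_report()] for aggregates.
#' @export
compute_sensitivity <- function(catalog, subset = NULL) {
  if (is.null(subset))
    subset <- which(!vapply(catalog$perturbations, is.null, logical(1)))
  coords <- catalog$system$bspace$nodes
  out <- list()
  for (k in subset) {
    ref <- replay_record(catalog, k)
    extent <- sqrt(sum(reference_extent(ref, coords)^2))
    z <- catalog$descriptors[k, ]
    for (p in catalog$perturbations[[k]]) {
      disp <- if (p$valid) sqrt(sum((p$z - z)^2)) else NA_real_
      sens <- if (extent > 0) disp / extent else disp
      out[[length(out) + 1]] <-
        data.frame(goal = k, family = p$family, scale = p$scale,
                   aux = p$aux, replicate = p$replicate,
                   sensitivity = sens, valid = p$valid,
                   zero_extent = extent == 0)
    }
  }
  do.call(rbind, out)
}

#' Aggregate sensitivities: per goal, per sub-family, per system
#'
#' @param sens the long table from [compute_sensitivity()].
#' @return list with `per_goal` (pooled mean over all perturbations — the
#'   headline goal sensitivity), `per_subfamily` (mean per goal x
#'   sub-family), `per_goal_family` and `system_median` (median over goals of
#'   the pooled means).
#' @export
sensitivity_report <- function(sens) {
  ok <- sens[sens$valid & is.finite(sens$sensitivity), ]
  per_goal <- stats::aggregate(sensitivity ~ goal, ok, mean)
  per_fam <- stats::aggregate(sensitivity ~ goal + family, ok, mean)
  per_sub <- stats::aggregate(sensitivity ~ goal + family + scale + aux, ok, mean)
  list(per_goal = per_goal, per_goal_family = per_fam,
       per_subfamily = per_sub,
       system_median = stats::median(per_goal$sensitivity),
       n_invalid = sum(!sens$valid))
}

#' Versatility-robustness trade-off curve
#'
#' For each sensitivity threshold, the threshold coverage of the goal states
#' whose mean wall sensitivity is at or below the threshold: the area of
#' behavior space the system reaches *robustly*. Monotone nondecreasing in
#' the threshold; at an infinite threshold it equals the plain diversity of
#' the scored subset.
#'
#' @param catalog the battery-augmented catalog.
#' @param sens table from [compute_sensitivity()].
#' @param thresholds numeric thresholds.
#' @param epsilon coverage ball radius.
#' @param box normalization box (default: bounding box of valid
#'   descriptors).
#' @param resolution coverage grid resolution.
#' @param family sensitivity family defining robustness (walls by default,
#'   matching the versatility-vs-wall-robustness trade-off; `"all"` pools
#'   families).
#' @return data.frame `(threshold, coverage)`.
#' @export
versatility_robustness_curve <- function(catalog, sens, thresholds,
                                         epsilon = 0.05, box = NULL,
                                         resolution = 1000L,
                                         family = "wall") {
  use <- sens[sens$valid & is.finite(sens$sensitivity), ]
  if (family != "all") use <- use[use$family == family, ]
  per_goal <- stats::aggregate(sensitivity ~ goal, use, mean)
  Zall <- catalog$descriptors[catalog$valid, , drop = FALSE]
  if (is.null(box)) box <- rbind(apply(Zall, 2, min), apply(Zall, 2, max))
  cfg <- coverage_config(epsilon, box, resolution)
  cov <- vapply(thresholds, function(th) {
    goals <- per_goal$goal[per_goal$sensitivity <= th]
    if (length(goals) == 0) return(0)
    threshold_coverage(catalog$descriptors[goals, , drop = FALSE], cfg)
  }, numeric(1))
  data.frame(threshold = thresholds, coverage = cov)
}
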