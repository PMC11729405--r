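#' Define a (model, intervention space, behavior space) system
#'
#' The unit on which exploration and robustness analyses operate. For
#' `"initial-state"` intervention spaces the intervention sets the rollout's
#' initial state; for `"circuit-parameters"` spaces it sets `(y0, W, B)` of a
#' gene circuit with `tau = 1`.
#'
#' @param model a `grn_circuit`, `grn_ode` or `grn_map` (ignored for
#'   circuit-parameter spaces, where the intervention defines the model).
#' @param ispace an [intervention_space()].
#' @param bspace a [behavior_space()].
#' @param config a [rollout_config()].
#' @return An object of class `grn_system`.
#' @export
grn_system <- function(model, ispace, bspace, config = rollout_config()) {
  if (ispace$kind == "initial-state")
    stopifnot(!is.null(model))
  structure(list(model = model, ispace = ispace, bspace = bspace,
                 config = config),
            class = "grn_system")
}

# One experiment: intervention -> trajectory -> descriptor (+ oscillation flag
# when the run cares about sustained oscillations).
system_rollout <- function(system, i, flag_oscillation = FALSE) {
  sp <- system$ispace
  if (sp$kind == "circuit-parameters") {
    n <- as.integer((-2 + sqrt(4 + 4 * sp$d)) / 2)  # d = n^2 + 2n
    up <- unpack_circuit_intervention(i, n)
    traj <- simulate_gene_circuit(up$model, up$y0, system$config)
  } else if (inherits(system$model, "grn_circuit")) {
    traj <- simulate_gene_circuit(system$model, i, system$config)
  } else {
    traj <- simulate_ode(system$model, i, system$config)
  }
  z <- encode_behavior(traj, system$bspace)
  list(traj = traj, z = z, valid = is_valid_trajectory(traj) && all(is.finite(z)),
       sustained = if (flag_oscillation)
         is_sustained_oscillator(traj, system$bspace$nodes[1]) else NA)
}

new_catalog <- function(system, interventions, descriptors, valid, sustained,
                        provenance, trajectories = NULL) {
  structure(list(interventions = interventions, descriptors = descriptors,
                 valid = valid, sustained = sustained,
                 space_id = system$bspace$encoder,
                 perturbations = vector("list", nrow(interventions)),
                 trajectories = trajectories, provenance = provenance,
                 system = system),
            class = "grn_catalog")
}

#' @export
print.grn_catalog <- function(x, ...) {
  cat("Behavioral catalog:", nrow(x$interventions), "records (",
      sum(x$valid), "valid ),", x$space_id, "space\n")
  invisible(x)
}

#' Number of records in a catalog
#' @param catalog a `grn_catalog`.
#' @return integer count.
#' @export
catalog_size <- function(catalog) nrow(catalog$interventions)

#' Random-search exploration
#'
#' The naive screening baseline: draws `N` interventions uniformly in the
#' intervention space, rolls each out and records the reached behavior.
#' Invalid rollouts are stored (with NA descriptors) but excluded from
#' nearest-descriptor queries downstream.
#'
#' @param system a [grn_system()].
#' @param N experiment budget.
#' @param seed RNG seed.
#' @param store_trajectories keep full trajectories in the catalog (off by
#'   default; records are exactly replayable from the stored interventions).
#' @param flag_oscillation record the sustained-oscillation flag per rollout.
#' @return A `grn_catalog` with `N` records.
#' @export
run_random_search <- function(system, N, seed = NULL,
                              store_trajectories = FALSE,
                              flag_oscillation = FALSE) {
  stopifnot(N >= 1)
  sp <- system$ispace
  # same "bootstrap" substream as run_imgep, so an IMGEP with N_init = N is
  # record-identical to random search under a shared seed
  sub <- if (is.null(seed)) NULL else derive_seeds(seed, "bootstrap")[["bootstrap"]]
  interventions <- with_seed(sub, {
    matrix(runif(N * sp$d, rep(sp$low, each = N), rep(sp$high, each = N)),
           nrow = N)
  })
  run_catalog_rollouts(system, interventions, seed, store_trajectories,
                       flag_oscillation)
}

run_catalog_rollouts <- function(system, interventions, seed,
                                 store_trajectories, flag_oscillation) {
  N <- nrow(interventions)
  descriptors <- matrix(NA_real_, N, system$bspace$m)
  valid <- logical(N)
  sustained <- rep(NA, N)
  trajs <- if (store_trajectories) vector("list", N) else NULL
  for (k in seq_len(N)) {
    r <- system_rollout(system, interventions[k, ], flag_oscillation)
    descriptors[k, ] <- r$z
    valid[k] <- r$valid
    sustained[k] <- r$sustained
    if (store_trajectories) trajs[[k]] <- r$traj
  }
  new_catalog(system, interventions, descriptors, valid, sustained,
              list(seed = seed, strategy = "random"), trajs)
}

#' IMGEP configuration
#'
#' @param N total experiment budget.
#' @param N_init random bootstrap count (default 10% of `N`, at least 1).
#' @param box_scale goal-box scale factor about its center (default 1.3).
#' @param step_frac policy step scale: the local random step is
#'   `Normal(0, step_frac * (high - low))` per intervention dimension.
#' @return An object of class `grn_imgep_config`.
#' @export
imgep_config <- function(N, N_init = max(1L, ceiling(0.1 * N)),
                         box_scale = 1.3, step_frac = 0.1) {
  stopifnot(N >= 1, N_init >= 1, N_init <= N)
  structure(list(N = as.integer(N), N_init = as.integer(N_init),
                 box_scale = box_scale, step_frac = step_frac),
            class = "grn_imgep_config")
}

#' Sample a goal in the reached-goal bounding box
#'
#' Uniform draw in the bounding hyper-rectangle of the valid reached
#' descriptors, scaled by `box_scale` about its center so the sampler also
#' targets unexplored space just outside the reached cloud. Degenerate axes
#' are floored at 1e-6 of the axis scale.
#'
#' @param descriptors matrix of reached descriptors (valid rows only).
#' @param box_scale scale factor.
#' @param u optional pre-drawn uniforms (length m) for stream separation;
#'   drawn from the current RNG when `NULL`.
#' @return a goal descriptor vector.
#' @export
sample_goal <- function(descriptors, box_scale = 1.3, u = NULL) {
  if (nrow(descriptors) == 0)
    stop("no valid records to bound goals; increase N_init")
  lo <- apply(descriptors, 2, min)
  hi <- apply(descriptors, 2, max)
  ctr <- (lo + hi) / 2
  ext <- pmax((hi - lo) * box_scale, 1e-6 * pmax(abs(ctr), 1))
  if (is.null(u)) u <- runif(length(lo))
  ctr + (u - 0.5) * ext
}

#' Goal-conditioned intervention selection
#'
#' The simple goal-reaching policy: find the valid record whose descriptor is
#' nearest to the goal (Euclidean for endpoint spaces, mean absolute spectral
#' difference for Fourier spaces), take its intervention and perform a local
#' random step `Normal(0, step_frac * (high - low))` per dimension, clipped
#' to the space bounds.
#'
#' @param goal goal descriptor.
#' @param descriptors,interventions valid records (rows aligned).
#' @param space the [intervention_space()].
#' @param bspace the [behavior_space()] (distance choice).
#' @param step_frac step scale.
#' @param eps optional pre-drawn standard normals (length d).
#' @return an intervention vector.
#' @export
select_intervention_for_goal <- function(goal, descriptors, interventions,
                                         space, bspace, step_frac = 0.1,
                                         eps = NULL) {
  dists <- descriptor_distance(bspace, goal, descriptors)
  i <- interventions[which.min(dists), ]
  if (is.null(eps)) eps <- rnorm(length(i))
  step <- eps * step_frac * (space$high - space$low)
  pmin(pmax(i + step, space$low), space$high)
}

#' Curiosity-driven goal exploration (IMGEP)
#'
#' Intrinsically motivated goal exploration over the system's behavior
#' space: `N_init` random bootstrap interventions, then `N - N_init`
#' goal-directed iterations of sample-goal, select-intervention, rollout,
#' encode, append. Randomness is split into named substreams (bootstrap,
#' goal sampling, policy steps) derived from `seed`, so each component is
#' independently reproducible and the bootstrap records are identical to a
#' same-seed [run_random_search()] with budget `N_init`.
#'
#' @param system a [grn_system()].
#' @param config an [imgep_config()].
#' @param seed RNG seed.
#' @inheritParams run_random_search
#' @return A `grn_catalog` with `config$N` records.
#' @export
run_imgep <- function(system, config, seed = NULL,
                      store_trajectories = FALSE, flag_oscillation = FALSE) {
  sp <- system$ispace
  m <- system$bspace$m
  N <- config$N; N0 <- config$N_init
  streams <- derive_seeds(if (is.null(seed)) 0L else seed,
                          c("bootstrap", "goal", "policy"))
  boot <- with_seed(if (is.null(seed)) NULL else streams[["bootstrap"]], {
    matrix(runif(N0 * sp$d, rep(sp$low, each = N0), rep(sp$high, each = N0)),
           nrow = N0)
  })
  U_goal <- with_seed(if (is.null(seed)) NULL else streams[["goal"]],
                      matrix(runif((N - N0) * m), ncol = m))
  E_policy <- with_seed(if (is.null(seed)) NULL else streams[["policy"]],
                        matrix(rnorm((N - N0) * sp$d), ncol = sp$d))
  interventions <- matrix(NA_real_, N, sp$d)
  descriptors <- matrix(NA_real_, N, m)
  valid <- logical(N)
  sustained <- rep(NA, N)
  trajs <- if (store_trajectories) vector("list", N) else NULL
  interventions[seq_len(N0), ] <- boot
  for (k in seq_len(N)) {
    if (k > N0) {
      ok <- which(valid[seq_len(k - 1)])
      if (length(ok) == 0)
        stop("no valid bootstrap records; increase N_init")
      g <- sample_goal(descriptors[ok, , drop = FALSE], config$box_scale,
                       u = U_goal[k - N0, ])
      interventions[k, ] <- select_intervention_for_goal(
        g, descriptors[ok, , drop = FALSE],
        interventions[ok, , drop = FALSE], sp, system$bspace,
        config$step_frac, eps = E_policy[k - N0, ])
    }
    r <- system_rollout(system, interventions[k, ], flag_oscillation)
    descriptors[k, ] <- r$z
    valid[k] <- r$valid
    sustained[k] <- r$sustained
    if (store_trajectories) trajs[[k]] <- r$traj
  }
  new_catalog(system, interventions, descriptors, valid, sustained,
              list(seed = seed, strategy = "imgep", config = unclass(config)),
              trajs)
}

# Replay the reference trajectory of one catalog record from its stored
# intervention (catalogs are descriptor-only by default).
replay_record <- function(catalog, k) {
  system_rollout(catalog$system, catalog$interventions[k, ])$traj
}
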