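#' Transcriptional gene-circuit model
#'
#' A recurrent gene-circuit parameterization with interaction weights `W`,
#' biases `B` and per-node time constants `tau`. The discrete-time update is
#' \deqn{y_{t+1} = (\Delta t/\tau)\,\mathrm{sigmoid}(W y + B) + (1 - \Delta t/\tau)\,y}
#' so node activations stay in (0,1) whenever the initial state does and
#' `dt/tau <= 1`. Zero entries of `W` encode absent regulatory edges.
#'
#' @param W n x n numeric interaction matrix (row i = inputs to node i).
#' @param B length-n bias vector (recycled if scalar).
#' @param tau length-n positive time constants in seconds (scalar broadcast).
#' @param default_y0 optional default initial state; defaults to 0.5 for every
#'   node (the sigmoid midpoint).
#' @param metadata free-form list of tags (model id, node names, ...).
#' @return An object of class `grn_circuit`.
#' @export
gene_circuit <- function(W, B = 0, tau = 1, default_y0 = NULL, metadata = list()) {
  W <- as.matrix(W)
  n <- nrow(W)
  stopifnot(ncol(W) == n, n >= 1, all(is.finite(W)))
  B <- rep_len(as.numeric(B), n)
  tau <- rep_len(as.numeric(tau), n)
  if (any(!is.finite(B)) || any(!is.finite(tau)) || any(tau <= 0))
    stop("B must be finite and tau strictly positive")
  if (is.null(default_y0)) default_y0 <- rep(0.5, n)
  structure(list(n = n, W = W, B = B, tau = tau,
                 default_y0 = rep_len(as.numeric(default_y0), n),
                 metadata = metadata),
            class = "grn_circuit")
}

#' @export
print.grn_circuit <- function(x, ...) {
  cat("Gene circuit:", x$n, "nodes,",
      sum(x$W != 0), "edges, tau in [",
      format(min(x$tau)), ",", format(max(x$tau)), "]\n")
  invisible(x)
}

#' Generic ODE network model
#'
#' Wraps an arbitrary deterministic rate function into the rollout contract
#' used throughout the package. `rate_fn(y, t, params)` must return dy/dt as a
#' numeric vector of length `n`.
#'
#' @param n node count.
#' @param rate_fn function `(y, t, params) -> dy/dt`.
#' @param default_y0 length-n nonnegative finite initial state.
#' @param params parameters forwarded to `rate_fn`.
#' @param metadata free-form tags.
#' @return An object of class `grn_ode`.
#' @export
ode_model <- function(n, rate_fn, default_y0 = rep(0, n), params = NULL,
                      metadata = list()) {
  stopifnot(is.function(rate_fn), length(default_y0) == n,
            all(is.finite(default_y0)), all(default_y0 >= 0))
  structure(list(n = n, rate_fn = rate_fn, default_y0 = as.numeric(default_y0),
                 params = params, metadata = metadata),
            class = "grn_ode")
}

#' Direct intervention-to-state mapping model
#'
#' A synthetic model whose "rollout" is a constant trajectory at `fn(i)`,
#' where `i` is the initial-state intervention. Useful for constructing
#' systems with a known, analytically controlled intervention-to-behavior
#' mapping (e.g. highly redundant maps) when testing exploration strategies.
#'
#' @param fn function mapping an intervention vector to a length-n state.
#' @param n output node count.
#' @param metadata free-form tags.
#' @return An object of class `grn_map`.
#' @export
map_model <- function(fn, n, metadata = list()) {
  stopifnot(is.function(fn))
  structure(list(n = n, fn = fn, metadata = metadata), class = "grn_map")
}

#' Rollout configuration
#'
#' Defaults follow the package-wide rollout contract: horizon `T = 2500` s at
#' output step `dt = 0.1` s (25,001 output points including t0), adaptive-solver
#' absolute tolerance `1e-6`, relative tolerance `1e-12` and a 1000-step cap.
#' The tolerances are exposed exactly as configured values; note `rtol < atol`
#' by default. A longer horizon (e.g. `T = 25000`) is used when building
#' intervention bounds from a default time course.
#'
#' @param T horizon in seconds.
#' @param dt output step in seconds; `T/dt` must be integral within rounding.
#' @param atol,rtol solver tolerances (generic ODE models only).
#' @param max_steps solver step cap between output points.
#' @return An object of class `grn_rollout_config`.
#' @export
rollout_config <- function(T = 2500, dt = 0.1, atol = 1e-6, rtol = 1e-12,
                           max_steps = 1000) {
  stopifnot(T > 0, dt > 0)
  m <- T / dt
  if (abs(m - round(m)) > 1e-8) stop("T/dt must be integral")
  structure(list(T = T, dt = dt, atol = atol, rtol = rtol,
                 max_steps = max_steps, n_steps = as.integer(round(m))),
            class = "grn_rollout_config")
}

new_trajectory <- function(times, states, dt, T) {
  states <- as.matrix(states)
  flags <- list(has_nan = anyNA(states) || any(!is.finite(states[!is.na(states)])),
                has_negative = any(states < 0, na.rm = TRUE))
  structure(list(times = times, states = states, flags = flags, dt = dt, T = T),
            class = "grn_trajectory")
}

#' Is a trajectory valid (finite and nonnegative)?
#'
#' @param traj a `grn_trajectory`.
#' @return logical flag.
#' @export
is_valid_trajectory <- function(traj) {
  !traj$flags$has_nan && !traj$flags$has_negative
}

#' @export
print.grn_trajectory <- function(x, ...) {
  cat("Trajectory:", nrow(x$states), "points x", ncol(x$states), "nodes,",
      "T =", x$T, "dt =", x$dt,
      if (!is_valid_trajectory(x)) "[INVALID]" else "", "\n")
  invisible(x)
}

# Convert a clamp schedule / event list into the step-indexed vectors the C++
# rollout expects. Events: list(times = numeric, disp = K x n matrix).
events_to_steps <- function(events, dt, n_steps, n) {
  if (is.null(events) || length(events$times) == 0)
    return(list(step = integer(0), disp = matrix(0, 0, n)))
  step <- as.integer(pmax(1, pmin(n_steps, round(events$times / dt))))
  o <- order(step)
  list(step = step[o], disp = as.matrix(events$disp)[o, , drop = FALSE])
}

clamps_to_steps <- function(clamps, dt, n_steps) {
  if (is.null(clamps) || nrow(clamps) == 0)
    return(list(step = integer(0), node = integer(0), value = numeric(0)))
  step <- as.integer(pmax(1, pmin(n_steps, round(clamps$time / dt))))
  o <- order(step)
  list(step = step[o], node = as.integer(clamps$node[o]) - 1L,
       value = as.numeric(clamps$value[o]))
}

#' Simulate a gene circuit with the discrete explicit update
#'
#' Applies the discrete gene-circuit step exactly, with optional per-step
#' hooks in the fixed order: state update, then displacement events
#' (noise/push perturbations), then the wall constraint in the 2-D behavior
#' plane, then clamps. Non-finite states flag the trajectory invalid; no
#' error is raised.
#'
#' @param model a [gene_circuit()].
#' @param y0 initial state (defaults to the model's `default_y0`).
#' @param config a [rollout_config()]; requires `dt/tau <= 1` elementwise.
#' @param events optional `list(times =, disp =)` instantaneous state
#'   displacements (matrix row per event, column per node).
#' @param clamps optional data.frame `(time, node, value)`; node is 1-based.
#'   The clamp overwrites the node state at every output step whose time
#'   rounds to `time`.
#' @param walls optional w x 4 matrix of wall segments `(x1, y1, x2, y2)` in
#'   the behavior plane spanned by `wall_coords`.
#' @param wall_coords length-2 1-based node indices of the behavior plane.
#' @return A `grn_trajectory`.
#' @export
simulate_gene_circuit <- function(model, y0 = NULL, config = rollout_config(),
                                  events = NULL, clamps = NULL, walls = NULL,
                                  wall_coords = c(1L, 2L)) {
  stopifnot(inherits(model, "grn_circuit"))
  if (is.null(y0)) y0 <- model$default_y0
  stopifnot(length(y0) == model$n)
  a <- config$dt / model$tau
  if (any(a > 1 + 1e-12)) stop("dt/tau must be <= 1 for the explicit update")
  ev <- events_to_steps(events, config$dt, config$n_steps, model$n)
  cl <- clamps_to_steps(clamps, config$dt, config$n_steps)
  if (is.null(walls)) walls <- matrix(0, 0, 4)
  states <- cpp_rollout_circuit(model$W, model$B, a, as.numeric(y0),
                                config$n_steps, ev$step, ev$disp,
                                cl$step, cl$node, cl$value,
                                as.matrix(walls), as.integer(wall_coords) - 1L)
  new_trajectory(seq(0, config$T, by = config$dt), states, config$dt, config$T)
}

#' Simulate a generic ODE model with adaptive integration
#'
#' Integrates `rate_fn` with `deSolve::lsoda` at the configured tolerances,
#' sampling the solution on the uniform output grid. Integration restarts at
#' every hook application point (displacement event or clamp boundary) so
#' interventions and perturbations are respected exactly. When wall segments
#' are supplied the model is advanced one output step at a time and the wall
#' constraint applied per step. Solver failures or non-finite states flag the
#' trajectory invalid rather than raising.
#'
#' @inheritParams simulate_gene_circuit
#' @param model an [ode_model()] (a [gene_circuit()] is accepted and converted
#'   to its continuous-time analog via [circuit_to_ode()]; a [map_model()]
#'   returns its constant mapped trajectory).
#' @return A `grn_trajectory`.
#' @export
simulate_ode <- function(model, y0 = NULL, config = rollout_config(),
                         events = NULL, clamps = NULL, walls = NULL,
                         wall_coords = c(1L, 2L)) {
  if (inherits(model, "grn_map")) {
    z <- model$fn(as.numeric(y0))
    times <- seq(0, config$T, by = config$dt)
    states <- matrix(rep(z, each = length(times)), ncol = model$n)
    return(new_trajectory(times, states, config$dt, config$T))
  }
  if (inherits(model, "grn_circuit")) model <- circuit_to_ode(model)
  stopifnot(inherits(model, "grn_ode"))
  if (is.null(y0)) y0 <- model$default_y0
  stopifnot(length(y0) == model$n)
  times <- seq(0, config$T, by = config$dt)
  M <- length(times)
  n <- model$n
  func <- function(t, y, parms) list(model$rate_fn(y, t, model$params))
  ev <- events_to_steps(events, config$dt, config$n_steps, n)
  cl <- clamps_to_steps(clamps, config$dt, config$n_steps)
  have_walls <- !is.null(walls) && nrow(walls) > 0
  states <- matrix(NA_real_, M, n)
  states[1, ] <- y <- as.numeric(y0)
  # breakpoints where integration must restart (1-based output row indices)
  bp <- sort(unique(c(ev$step, cl$step))) + 1L
  if (have_walls) segs <- seq_len(config$n_steps) + 1L
  else segs <- sort(unique(c(bp, M)))
  run_piece <- function(y, t_idx0, t_idx1) {
    tt <- times[t_idx0:t_idx1]
    sol <- suppressWarnings(
      try(deSolve::lsoda(y, tt, func, parms = NULL,
                         rtol = config$rtol, atol = config$atol,
                         maxsteps = config$max_steps), silent = TRUE))
    if (inherits(sol, "try-error") || nrow(sol) < length(tt))
      return(NULL)
    unname(as.matrix(sol)[, -1, drop = FALSE])
  }
  idx0 <- 1L
  for (idx1 in segs) {
    piece <- run_piece(y, idx0, idx1)
    if (is.null(piece) || anyNA(piece)) {
      break  # leave remaining rows NA; trajectory is flagged invalid
    }
    states[idx0:idx1, ] <- piece
    y <- piece[nrow(piece), ]
    k <- idx1 - 1L  # step index of this output row
    for (e in which(ev$step == k)) y <- y + ev$disp[e, ]
    if (have_walls) {
      p_prev <- states[max(1L, idx1 - 1L), wall_coords]
      y[wall_coords] <- project_walls_r(walls, p_prev, y[wall_coords])
    }
    for (e in which(cl$step == k)) y[cl$node[e] + 1L] <- cl$value[e]
    states[idx1, ] <- y
    idx0 <- idx1
    if (idx1 >= M) break
  }
  new_trajectory(times, states, config$dt, config$T)
}

# R-side wall projection mirroring the C++ law (used only on the generic ODE
# path, which steps on the output grid when walls are present).
project_walls_r <- function(walls, p, q) {
  for (iter in 1:4) {
    hit <- FALSE
    tbest <- 2; wbest <- -1
    for (w in seq_len(nrow(walls))) {
      a <- walls[w, 1:2]; b <- walls[w, 3:4]
      d1 <- (b[1]-a[1])*(p[2]-a[2]) - (b[2]-a[2])*(p[1]-a[1])
      d2 <- (b[1]-a[1])*(q[2]-a[2]) - (b[2]-a[2])*(q[1]-a[1])
      d3 <- (q[1]-p[1])*(a[2]-p[2]) - (q[2]-p[2])*(a[1]-p[1])
      d4 <- (q[1]-p[1])*(b[2]-p[2]) - (q[2]-p[2])*(b[1]-p[1])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0) || (d1 != 0 && d2 == 0)) &&
          ((d3 >= 0 && d4 <= 0) || (d3 <= 0 && d4 >= 0))) {
        tt <- d1 / (d1 - d2)
        if (tt < tbest) { tbest <- tt; wbest <- w; hit <- TRUE }
      }
    }
    if (!hit) return(q)
    a <- walls[wbest, 1:2]; b <- walls[wbest, 3:4]
    X <- p + tbest * (q - p)
    d <- b - a; dn <- sqrt(sum(d^2))
    if (dn == 0) return(p)
    d <- d / dn
    tang <- sum((q - X) * d)
    nrm <- c(-d[2], d[1])
    sgn <- if (sum((p - X) * nrm) >= 0) 1 else -1
    eps <- 1e-9 * (1 + sqrt(sum((q - p)^2)))
    q <- X + tang * d + sgn * eps * nrm
  }
  p
}

#' Continuous-time analog of a gene circuit
#'
#' Returns the [ode_model()] with rate `dy/dt = (sigmoid(W y + B) - y) / tau`,
#' whose fixed points coincide with those of the discrete update.
#'
#' @param model a [gene_circuit()].
#' @return An `grn_ode`.
#' @export
circuit_to_ode <- function(model) {
  stopifnot(inherits(model, "grn_circuit"))
  W <- model$W; B <- model$B; tau <- model$tau
  ode_model(model$n,
            function(y, t, params) (sigmoid(drop(W %*% y) + B) - y) / tau,
            default_y0 = model$default_y0, metadata = model$metadata)
}

#' Sample a random gene circuit
#'
#' Randomizes the kinematic parameters of a transcriptional gene circuit:
#' nonzero weights `W ~ U[-30, 30]`, biases `B ~ U[-10, 10]`, time constants
#' `tau ~ U[1, 15]`. In-degree structure is enforced by zeroing weights: row i
#' keeps exactly `in_degrees[i]` nonzero entries, chosen uniformly without
#' replacement.
#'
#' @param n node count.
#' @param in_degrees length-n integer in-degrees, each in `[0, n]`; defaults
#'   to full connectivity.
#' @param seed optional integer seed (local RNG stream).
#' @return A `grn_circuit`.
#' @export
sample_random_gene_circuit <- function(n, in_degrees = rep(n, n), seed = NULL) {
  in_degrees <- rep_len(as.integer(in_degrees), n)
  bad <- which(in_degrees < 0 | in_degrees > n)
  if (length(bad))
    stop("invalid in-degree for node ", bad[1], ": ", in_degrees[bad[1]])
  with_seed(seed, {
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      k <- in_degrees[i]
      if (k > 0) {
        idx <- sample.int(n, k)
        W[i, idx] <- runif(k, -30, 30)
      }
    }
    gene_circuit(W, B = runif(n, -10, 10), tau = runif(n, 1, 15))
  })
}

#' Write / read a gene circuit as JSON
#'
#' @param model a `grn_circuit`.
#' @param path file path.
#' @return `read_circuit_json` returns a `grn_circuit`; `write_circuit_json`
#'   returns `path` invisibly.
#' @export
write_circuit_json <- function(model, path) {
  stopifnot(inherits(model, "grn_circuit"))
  jsonlite::write_json(
    list(n = model$n, W = model$W, B = model$B, tau = model$tau,
         default_y0 = model$default_y0, metadata = model$metadata),
    path, digits = I(17), auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_circuit_json
#' @export
read_circuit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gene_circuit(matrix(as.numeric(x$W), nrow = x$n, byrow = !is.matrix(x$W)),
               B = x$B, tau = x$tau, default_y0 = x$default_y0,
               metadata = as.list(x$metadata))
}
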