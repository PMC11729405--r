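#' Intervention space
#'
#' A hyper-rectangle of controllable inputs: either initial node states
#' (dimension n) or joint circuit parameters (dimension n^2 + 2n).
#'
#' @param low,high elementwise bounds, `low <= high`.
#' @param kind `"initial-state"` or `"circuit-parameters"`.
#' @return An object of class `grn_ispace`.
#' @export
intervention_space <- function(low, high,
                               kind = c("initial-state", "circuit-parameters")) {
  kind <- match.arg(kind)
  stopifnot(length(low) == length(high), all(low <= high))
  structure(list(low = as.numeric(low), high = as.numeric(high),
                 d = length(low), kind = kind),
            class = "grn_ispace")
}

#' Intervention bounds from a default time course
#'
#' Builds the initial-state intervention space from the per-node range of a
#' default (unintervened) trajectory: `low_i = min_t y_i(t) / r`,
#' `high_i = r * max_t y_i(t)`, with the conventional scale factor `r = 20`.
#'
#' @param default_traj a valid `grn_trajectory` from the model's default
#'   initial conditions (typically with a long horizon, e.g. `T = 25000`).
#' @param r scale factor.
#' @return A `grn_ispace` of kind `"initial-state"`.
#' @export
build_intervention_space <- function(default_traj, r = 20) {
  if (!is_valid_trajectory(default_traj))
    stop("default trajectory is invalid (NaN or negative states)")
  lo <- apply(default_traj$states, 2, min) / r
  hi <- r * apply(default_traj$states, 2, max)
  intervention_space(pmax(lo, 0), hi, "initial-state")
}

#' Joint circuit-parameter intervention space
#'
#' The n^2 + 2n dimensional space of (y0, W, B) used for gene-circuit
#' engineering, ordered as initial states, then `W` column-major, then `B`.
#' Defaults: `y0` in `[0,1]`, `W` in `[-30,30]`, `B` in `[-10,10]`, `tau = 1`.
#'
#' @param n node count.
#' @param y0_bounds,w_bounds,b_bounds length-2 `(min, max)` bounds.
#' @return A `grn_ispace` of kind `"circuit-parameters"`.
#' @export
circuit_param_space <- function(n, y0_bounds = c(0, 1), w_bounds = c(-30, 30),
                                b_bounds = c(-10, 10)) {
  low <- c(rep(y0_bounds[1], n), rep(w_bounds[1], n * n), rep(b_bounds[1], n))
  high <- c(rep(y0_bounds[2], n), rep(w_bounds[2], n * n), rep(b_bounds[2], n))
  intervention_space(low, high, "circuit-parameters")
}

# Unpack a circuit-parameter intervention vector into (y0, model with tau = 1).
unpack_circuit_intervention <- function(i, n) {
  list(y0 = i[seq_len(n)],
       model = gene_circuit(matrix(i[n + seq_len(n * n)], n, n),
                            B = i[n + n * n + seq_len(n)], tau = 1))
}

#' Behavior space
#'
#' Declares how a trajectory is encoded into a low-dimensional behavior
#' descriptor. Encoders: `"endpoint"` (final state of a node pair, m = 2),
#' `"fourier"` (amplitude spectrum of one node's settled half-window signal,
#' truncated to `n_bins` bins; catalog distance is the mean absolute spectral
#' difference), `"oscillation"` (the analytic (amplitude, main frequency,
#' offset) triple of one node).
#'
#' @param encoder encoder id.
#' @param nodes 1-based node indices: a pair for `"endpoint"`, a single node
#'   otherwise.
#' @param n_bins spectrum length kept for the Fourier encoder.
#' @return An object of class `grn_bspace`.
#' @export
behavior_space <- function(encoder = c("endpoint", "fourier", "oscillation"),
                           nodes = c(1L, 2L), n_bins = 256L) {
  encoder <- match.arg(encoder)
  nodes <- as.integer(nodes)
  m <- switch(encoder, endpoint = 2L, fourier = as.integer(n_bins),
              oscillation = 3L)
  if (encoder == "endpoint") stopifnot(length(nodes) == 2)
  else nodes <- nodes[1]
  structure(list(encoder = encoder, nodes = nodes, m = m,
                 n_bins = as.integer(n_bins)),
            class = "grn_bspace")
}

# Amplitude spectrum |DFT| of the settled half-window [T/2, T] of one node.
half_window_spectrum <- function(traj, node) {
  x <- traj$states[, node]
  M <- length(x)
  Mod(fft(x[(floor(M / 2) + 1):M]))
}

#' Endpoint behavior descriptor
#'
#' The reached goal state: final values `(y_i(T), y_j(T))` of the target
#' phenotype node pair. Invalid trajectories yield an NA descriptor.
#'
#' @param traj a `grn_trajectory`.
#' @param nodes 1-based node index pair.
#' @return numeric length-2 descriptor.
#' @export
encode_endpoint <- function(traj, nodes = c(1L, 2L)) {
  if (!is_valid_trajectory(traj)) return(rep(NA_real_, 2))
  as.numeric(traj$states[nrow(traj$states), nodes])
}

#' Fourier behavior descriptor
#'
#' Unnormalized amplitude spectrum of the node signal over the settled
#' half-window `[T/2, T]`, truncated to the first `n_bins` bins (DC first).
#'
#' @param traj a `grn_trajectory`.
#' @param node 1-based node index.
#' @param n_bins bins kept.
#' @return numeric descriptor of length `n_bins`.
#' @export
encode_fourier <- function(traj, node = 1L, n_bins = 256L) {
  if (!is_valid_trajectory(traj)) return(rep(NA_real_, n_bins))
  s <- half_window_spectrum(traj, node)
  head(c(s, rep(0, n_bins)), n_bins)
}

#' Analytic oscillation descriptor (amplitude, main frequency, offset)
#'
#' Computed on the settled half-window `[T/2, T]`: offset `b` is the mean,
#' amplitude `A = (max - min)/2`, and the main frequency `omega` (Hz) is the
#' frequency of the maximal non-DC amplitude bin (ties broken toward the
#' lower frequency; a constant signal reports `omega = 0` by convention).
#'
#' @param traj a `grn_trajectory`.
#' @param node 1-based node index.
#' @return numeric `(A, omega, b)`.
#' @export
extract_oscillation_descriptor <- function(traj, node = 1L) {
  if (!is_valid_trajectory(traj)) return(rep(NA_real_, 3))
  x <- traj$states[, node]
  M <- length(x)
  w <- x[(floor(M / 2) + 1):M]
  b <- mean(w)
  A <- (max(w) - min(w)) / 2
  s <- Mod(fft(w))
  nh <- floor(length(w) / 2)
  omega <- 0
  if (nh >= 1 && A > 0) {
    k <- which.max(s[2:(nh + 1)])  # non-DC bins; which.max takes first (lowest f) tie
    # refine to sub-bin precision: maximize |sum_t y(t) e^(-2 pi i f t)| over
    # the two bins around the peak (golden-section on continuous frequency)
    Mw <- length(w)
    tt <- (seq_len(Mw) - 1) * traj$dt
    wc <- w - b
    amp_at <- function(f) Mod(sum(wc * exp(-2i * pi * f * tt)))
    lo <- max(k - 1, 0.5) / (Mw * traj$dt)
    hi <- (k + 1) / (Mw * traj$dt)
    opt <- stats::optimize(amp_at, c(lo, hi), maximum = TRUE,
                           tol = 1e-4 / (Mw * traj$dt))
    omega <- opt$maximum
  }
  c(A = A, omega = omega, b = b)
}

#' Encode a trajectory into a behavior space
#'
#' Dispatches to the encoder declared by `space`. All encoders are
#' deterministic functions of the trajectory.
#'
#' @param traj a `grn_trajectory`.
#' @param space a [behavior_space()].
#' @return numeric descriptor of length `space$m`.
#' @export
encode_behavior <- function(traj, space) {
  switch(space$encoder,
         endpoint = encode_endpoint(traj, space$nodes),
         fourier = encode_fourier(traj, space$nodes, space$n_bins),
         oscillation = extract_oscillation_descriptor(traj, space$nodes))
}

#' Distance between behavior descriptors
#'
#' Euclidean for endpoint and oscillation spaces; mean absolute spectral
#' difference for Fourier spaces. `b` may be a matrix with one descriptor per
#' row, in which case a vector of distances is returned.
#'
#' @param space a [behavior_space()].
#' @param a single descriptor.
#' @param b descriptor or matrix of descriptors (rows).
#' @return numeric distance(s).
#' @export
descriptor_distance <- function(space, a, b) {
  b <- if (is.matrix(b)) b else matrix(b, nrow = 1)
  d <- sweep(b, 2, a)
  if (space$encoder == "fourier") rowMeans(abs(d)) else sqrt(rowSums(d^2))
}

#' Synthesize a cosine trajectory
#'
#' Utility fixture: a single-node trajectory `A cos(2 pi omega t) + b` on the
#' configured grid, for validating the oscillation encoders.
#'
#' @param A,omega,b amplitude, frequency (Hz), offset.
#' @param config a [rollout_config()].
#' @return A `grn_trajectory` with one node.
#' @export
synthesize_cosine <- function(A, omega, b, config = rollout_config()) {
  times <- seq(0, config$T, by = config$dt)
  new_trajectory(times, matrix(A * cos(2 * pi * omega * times) + b, ncol = 1),
                 config$dt, config$T)
}
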