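# Shared fixtures, built in code at test time.

# Short rollout grid for tests where the full default horizon is not the point.
short_config <- function(T = 200, dt = 0.1) rollout_config(T = T, dt = dt)

# Two-node toggle switch: mutual inhibition with self-consistent biases gives
# two symmetric attractors (one node high, the other low).
bistable_circuit <- function() {
  gene_circuit(W = rbind(c(0, -10), c(-10, 0)), B = c(5, 5), tau = 1)
}

# Highly redundant intervention-to-behavior mapping: 90% of the intervention
# square collapses onto one endpoint (plus a tiny linear spread so the goal
# box is nondegenerate); the last 10% of the first axis fans out over the
# whole unit square.
redundant_map_system <- function(config = short_config(T = 10)) {
  fn <- function(i) {
    if (i[1] < 0.9) c(0.5, 0.5) + 0.002 * i
    else c((i[1] - 0.9) * 10, i[2])
  }
  grn_system(map_model(fn, 2),
             intervention_space(c(0, 0), c(1, 1), "initial-state"),
             behavior_space("endpoint", c(1L, 2L)), config)
}

# Monte-Carlo dart-throwing oracle for threshold coverage: fraction of darts
# uniform in the epsilon-padded unit square that land within epsilon of a
# point. Independent of the grid-integration implementation.
mc_coverage <- function(points, epsilon = 0.05, n_darts = 1e6, seed = 1) {
  set.seed(seed)
  dx <- runif(n_darts, -epsilon, 1 + epsilon)
  dy <- runif(n_darts, -epsilon, 1 + epsilon)
  hit <- rep(FALSE, n_darts)
  for (k in seq_len(nrow(points)))
    hit <- hit | ((dx - points[k, 1])^2 + (dy - points[k, 2])^2 <= epsilon^2)
  mean(hit)
}

# Settled endpoints of the two-node toggle switch, one per basin.
toggle_attractors <- function(cfg = rollout_config(T = 500, dt = 0.1)) {
  m <- bistable_circuit()
  hi <- simulate_gene_circuit(m, c(0.9, 0.1), cfg)
  lo <- simulate_gene_circuit(m, c(0.1, 0.9), cfg)
  list(model = m,
       high = hi$states[nrow(hi$states), ],   # node 1 high, node 2 low
       low = lo$states[nrow(lo$states), ])
}

# A small endpoint system on a 3-node random circuit (fast, deterministic).
toy_circuit_system <- function(seed = 7, T = 200) {
  model <- sample_random_gene_circuit(3, seed = seed)
  grn_system(model, intervention_space(rep(0, 3), rep(1, 3), "initial-state"),
             behavior_space("endpoint", c(1L, 2L)), short_config(T = T))
}
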