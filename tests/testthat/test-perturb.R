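test_that("the default grid reproduces the printed 18 sub-families", {
  g <- default_perturbation_grid()
  expect_identical(nrow(g), 18L)
  expect_identical(attr(g, "replicates"), 3L)
  expect_identical(sum(g$family == "noise"), 6L)
  noise <- g[g$family == "noise", ]
  expect_equal(cbind(noise$scale, noise$aux),
               cbind(c(0.001, 0.005, 0.1, 0.005, 0.005, 0.005),
                     c(5, 5, 5, 10, 5, 1)))  # duplicate (0.005, 5) kept
  push <- g[g$family == "push", ]
  expect_setequal(push$scale, c(0.05, 0.1, 0.15))
  expect_setequal(push$aux, 1:3)
  expect_identical(nrow(perturbation_grid(g[0, ])), 0L)
})

test_that("realized perturbations are conditioned on the reference extent", {
  sys <- toy_circuit_system(seed = 7)
  ref <- simulate_gene_circuit(sys$model, c(0.1, 0.9, 0.5), sys$config)
  ext <- apply(ref$states[, 1:2], 2, function(v) diff(range(v)))

  # empirical std of noise kicks = sigma_n * extent within 5%
  kicks <- c()
  for (s in 1:120) {
    sp <- sample_perturbation("noise", 0.05, 1, ref, c(1L, 2L),
                              window = 80, seed = s)
    kicks <- rbind(kicks, sp$events$disp[, 1:2])
  }
  expect_equal(stats::sd(kicks[, 1]), 0.05 * ext[1], tolerance = 0.05)
  expect_equal(stats::sd(kicks[, 2]), 0.05 * ext[2], tolerance = 0.05)

  # doubling the reference extent doubles realized magnitudes exactly
  ref2 <- new_trajectory(ref$times, ref$states * 2, ref$dt, ref$T)
  s1 <- sample_perturbation("push", 0.1, 2, ref, c(1L, 2L), seed = 99)
  s2 <- sample_perturbation("push", 0.1, 2, ref2, c(1L, 2L), seed = 99)
  expect_equal(s2$events$disp, 2 * s1$events$disp, tolerance = 1e-12)
  w1 <- sample_perturbation("wall", 0.1, 2, ref, c(1L, 2L), seed = 99)
  w2 <- sample_perturbation("wall", 0.1, 2, ref2, c(1L, 2L), seed = 99)
  len <- function(w) sqrt((w[, 3] - w[, 1])^2 + (w[, 4] - w[, 2])^2)
  expect_equal(len(w2$walls), 2 * len(w1$walls), tolerance = 1e-12)

  # same seed, same realization
  expect_identical(s1$events,
                   sample_perturbation("push", 0.1, 2, ref, c(1L, 2L),
                                       seed = 99)$events)

  # degenerate (zero-extent) reference: flagged, zero magnitudes
  cst <- simulate_ode(map_model(function(i) i, 2), c(0.5, 0.5),
                      short_config(T = 10))
  sp <- sample_perturbation("noise", 0.1, 5, cst, c(1L, 2L), seed = 1)
  expect_true(sp$degenerate)
  expect_true(all(sp$events$disp == 0))
})

test_that("zero-magnitude perturbations leave the rollout unchanged", {
  sys <- toy_circuit_system(seed = 8)
  y0 <- c(0.2, 0.6, 0.4)
  ref <- simulate_gene_circuit(sys$model, y0, sys$config)
  for (fam in c("noise", "push", "wall")) {
    sp <- sample_perturbation(fam, 0, ifelse(fam == "noise", 5, 2), ref,
                              c(1L, 2L), seed = 3)
    per <- apply_perturbation(sys$model, y0, sp, sys$config)
    expect_identical(per$states, ref$states)
  }
})

test_that("walls block flows and never create discontinuities", {
  # flow from (0.1, 0.1) toward the attractor (0.5, 0.5) of a zero-weight
  # circuit; a full-width wall at x2 = 0.3 keeps the endpoint on the near side
  m <- gene_circuit(matrix(0, 2, 2))
  wall <- matrix(c(-1, 0.3, 2, 0.3), 1)
  tr <- simulate_gene_circuit(m, c(0.1, 0.1), short_config(T = 300),
                              walls = wall, wall_coords = c(1, 2))
  expect_true(is_valid_trajectory(tr))
  expect_lt(max(tr$states[, 2]), 0.3)
  expect_gt(tr$states[nrow(tr$states), 1], 0.45)  # slides freely along x1

  # continuity: no teleportation through walls on random 2-node systems
  set.seed(12)
  for (s in 1:20) {
    ms <- sample_random_gene_circuit(2, seed = 300 + s)
    ref <- simulate_gene_circuit(ms, runif(2), short_config(T = 100))
    sp <- sample_perturbation("wall", 0.15, 3, ref, c(1L, 2L), seed = s)
    per <- apply_perturbation(ms, ref$states[1, ], sp, short_config(T = 100))
    expect_true(is_valid_trajectory(per))
    steps <- sqrt(rowSums(diff(per$states)^2))
    ref_steps <- sqrt(rowSums(diff(ref$states)^2))
    expect_lte(max(steps), max(ref_steps) * 2 + 1e-6)
  }
})

test_that("perturbed rollouts restart from the reference initial state", {
  sys <- toy_circuit_system(seed = 9)
  y0 <- c(0.3, 0.3, 0.3)
  ref <- simulate_gene_circuit(sys$model, y0, sys$config)
  sp <- sample_perturbation("push", 0.2, 1, ref, c(1L, 2L), seed = 5)
  per <- apply_perturbation(sys$model, y0, sp, sys$config)
  expect_identical(per$states[1, ], ref$states[1, ])
})
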