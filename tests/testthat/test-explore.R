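test_that("random search fills the catalog with uniform interventions", {
  sys <- redundant_map_system()
  cat1 <- run_random_search(sys, 1, seed = 1)
  expect_identical(catalog_size(cat1), 1L)

  cat_ <- run_random_search(sys, 5000, seed = 2)
  expect_identical(catalog_size(cat_), 5000L)
  expect_true(all(cat_$interventions >= 0 & cat_$interventions <= 1))
  expect_gt(stats::ks.test(cat_$interventions[, 1], "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(cat_$interventions[, 2], "punif")$p.value, 0.01)

  # reproducibility: same seed, identical catalog
  cat2 <- run_random_search(sys, 50, seed = 3)
  cat3 <- run_random_search(sys, 50, seed = 3)
  expect_identical(cat2$interventions, cat3$interventions)
  expect_identical(cat2$descriptors, cat3$descriptors)
})

test_that("goal sampling covers the scaled bounding box", {
  # two reached goals (0,0) and (1,1), scale 1.3: uniform in [-0.15, 1.15]^2
  D <- rbind(c(0, 0), c(1, 1))
  set.seed(6)
  g <- t(replicate(10000, sample_goal(D, 1.3)))
  expect_gt(stats::ks.test(g[, 1], "punif", -0.15, 1.15)$p.value, 0.01)
  expect_gt(stats::ks.test(g[, 2], "punif", -0.15, 1.15)$p.value, 0.01)
  expect_true(all(g >= -0.15 - 1e-12 & g <= 1.15 + 1e-12))

  # degenerate single-point box: sample collapses to the point up to the floor
  g1 <- sample_goal(rbind(c(0.4, 0.7)), 1.3)
  expect_equal(g1, c(0.4, 0.7), tolerance = 1e-5)

  expect_error(sample_goal(matrix(numeric(0), 0, 2)), "N_init")
})

test_that("goal-conditioned selection takes the nearest record plus a local step", {
  set.seed(8)
  D <- matrix(runif(20), ncol = 2)
  I <- matrix(runif(30), ncol = 3)
  sp <- intervention_space(rep(0, 3), rep(1, 3), "initial-state")
  bs <- behavior_space("endpoint", c(1L, 2L))
  goal <- c(0.5, 0.5)
  # step_frac = 0 returns exactly the brute-force nearest record's intervention
  nearest <- which.min(sqrt(rowSums(sweep(D, 2, goal)^2)))
  pick <- select_intervention_for_goal(goal, D, I, sp, bs, step_frac = 0)
  expect_equal(pick, I[nearest, ])
  # steps stay inside the bounds
  for (k in 1:20) {
    pick <- select_intervention_for_goal(runif(2), D, I, sp, bs, 0.1)
    expect_true(all(pick >= 0 & pick <= 1))
  }
})

test_that("IMGEP with N_init = N is record-identical to random search", {
  sys <- redundant_map_system()
  a <- run_imgep(sys, imgep_config(40, N_init = 40), seed = 11)
  b <- run_random_search(sys, 40, seed = 11)
  expect_identical(a$interventions, b$interventions)
  expect_identical(a$descriptors, b$descriptors)
})

test_that("IMGEP out-covers random search on a highly redundant mapping", {
  sys <- redundant_map_system()
  box <- rbind(c(0, 0), c(1, 1))
  cfg <- coverage_config(box = box, resolution = 600)
  wins <- 0; n_seeds <- 12
  cov_i <- cov_r <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    ci <- run_imgep(sys, imgep_config(60, N_init = 10), seed = s)
    cr <- run_random_search(sys, 60, seed = s)
    cov_i[s] <- threshold_coverage(ci$descriptors[ci$valid, ], cfg)
    cov_r[s] <- threshold_coverage(cr$descriptors[cr$valid, ], cfg)
  }
  expect_gt(mean(cov_i), mean(cov_r))
  expect_gte(mean(cov_i >= cov_r), 0.75)
})

test_that("catalog bootstrap discoveries are preserved by the goal phase", {
  sys <- redundant_map_system()
  cat_ <- run_imgep(sys, imgep_config(50, N_init = 10), seed = 4)
  boot <- run_random_search(sys, 10, seed = 4)
  expect_identical(cat_$interventions[1:10, ], boot$interventions)
  expect_identical(catalog_size(cat_), 50L)
})
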