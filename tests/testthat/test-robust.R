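make_battery_catalog <- function(seed = 5, N = 30, grid = NULL, K = 3) {
  sys <- toy_circuit_system(seed = seed, T = 200)
  cat_ <- run_random_search(sys, N, seed = seed)
  if (is.null(grid)) grid <- default_perturbation_grid()
  sub <- select_representative_subset(cat_, K = K, draws = 50,
                                      resolution = 200, seed = seed)
  run_robustness_battery(cat_, sub, grid, seed = seed)
}

test_that("representative subset selection maximizes threshold coverage", {
  sys <- redundant_map_system()
  cat_ <- run_random_search(sys, 5, seed = 13)
  # N = 5, K = 2: enough draws must find the best of all C(5,2) = 10 subsets
  box <- rbind(apply(cat_$descriptors, 2, min), apply(cat_$descriptors, 2, max))
  cfg <- coverage_config(box = box, resolution = 400)
  combs <- utils::combn(5, 2)
  best <- max(apply(combs, 2, function(ix)
    threshold_coverage(cat_$descriptors[ix, ], cfg)))
  sub <- select_representative_subset(cat_, K = 2, draws = 60, box = box,
                                      resolution = 400, seed = 1)
  expect_equal(threshold_coverage(cat_$descriptors[sub, ], cfg), best)

  # K = N returns everything; K beyond the valid count errors
  expect_identical(select_representative_subset(cat_, K = 5), 1:5)
  expect_error(select_representative_subset(cat_, K = 6), "valid")
})

test_that("the battery attaches P = s*r perturbed outcomes per goal", {
  cat_ <- make_battery_catalog(seed = 5, N = 20, K = 2)
  done <- which(!vapply(cat_$perturbations, is.null, logical(1)))
  expect_identical(length(done), 2L)
  for (k in done)
    expect_identical(length(cat_$perturbations[[k]]), 54L)

  # empty grid is a no-op
  sys <- toy_circuit_system(seed = 5, T = 100)
  cat0 <- run_random_search(sys, 5, seed = 1)
  cat1 <- run_robustness_battery(cat0, 1:2,
                                 perturbation_grid(default_perturbation_grid()[0, ]))
  expect_identical(cat1$perturbations, cat0$perturbations)
})

test_that("sensitivity is the normalized mean endpoint displacement", {
  grid0 <- perturbation_grid(
    data.frame(family = c("noise", "push", "wall"),
               scale = 0, aux = c(5, 1, 1)), replicates = 2L)
  cat_ <- make_battery_catalog(seed = 6, N = 15, grid = grid0, K = 2)
  sens <- compute_sensitivity(cat_)
  expect_true(all(sens$valid))
  expect_true(all(sens$sensitivity == 0))  # zero-magnitude battery

  # a single perturbation displacing the endpoint by d scores d / extent
  cat2 <- make_battery_catalog(seed = 6, N = 15, K = 1)
  k <- which(!vapply(cat2$perturbations, is.null, logical(1)))[1]
  ref <- grnavigate:::replay_record(cat2, k)
  extent <- sqrt(sum(grnavigate:::reference_extent(ref, c(1, 2))^2))
  p <- cat2$perturbations[[k]][[10]]
  d <- sqrt(sum((p$z - cat2$descriptors[k, ])^2))
  sens2 <- compute_sensitivity(cat2)
  row <- sens2[sens2$goal == k & sens2$family == p$family &
                 sens2$scale == p$scale & sens2$aux == p$aux &
                 sens2$replicate == p$replicate, ]
  expect_equal(row$sensitivity, d / extent)

  # invariance under a common affine rescaling of both behavior axes is
  # structural: numerator and denominator both scale by c (checked via the
  # explicit ratio above)
  rep <- sensitivity_report(sens2)
  expect_gte(rep$system_median, min(rep$per_goal$sensitivity))
  expect_lte(rep$system_median, max(rep$per_goal$sensitivity))
})

test_that("the versatility-robustness curve is monotone nondecreasing", {
  cat_ <- make_battery_catalog(seed = 7, N = 20, K = 3)
  sens <- compute_sensitivity(cat_)
  th <- c(0, 0.01, 0.05, 0.2, 1, Inf)
  curve <- versatility_robustness_curve(cat_, sens, th, resolution = 300)
  expect_true(all(diff(curve$coverage) >= -1e-12))
  # infinite threshold equals the plain diversity of the scored subset
  goals <- unique(sens$goal)
  Zall <- cat_$descriptors[cat_$valid, , drop = FALSE]
  box <- rbind(apply(Zall, 2, min), apply(Zall, 2, max))
  plain <- threshold_coverage(cat_$descriptors[goals, , drop = FALSE],
                              coverage_config(box = box, resolution = 300))
  expect_equal(curve$coverage[length(th)], plain)
})

test_that("pushes on a globally attracting fixed point leave the goal intact", {
  # dy/dt = -(y - c): every push is absorbed; endpoint displacement ~ 0
  cc <- c(0.6, 0.3)
  om <- ode_model(2, function(y, t, p) -(y - cc), cc)
  cfg <- rollout_config(T = 200, dt = 0.1)
  ref <- simulate_ode(om, c(0.1, 0.9), cfg)
  z <- encode_endpoint(ref, c(1, 2))
  for (s in 1:5) {
    sp <- sample_perturbation("push", 0.2, 2, ref, c(1L, 2L), seed = s)
    per <- simulate_ode(om, c(0.1, 0.9), cfg, events = sp$events)
    zp <- encode_endpoint(per, c(1, 2))
    expect_equal(zp, z, tolerance = 1e-3)
  }
})
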