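test_that("gene-circuit update matches the discrete recursion", {
  m <- gene_circuit(matrix(0, 1, 1), B = 0, tau = 1)
  tr <- simulate_gene_circuit(m, 0.5, short_config(T = 10))
  expect_true(all(tr$states == 0.5))  # sigmoid(0) = 0.5 fixed point

  # W = 0, B = 0, y0 = 0: y_k = 0.5 (1 - 0.9^k) for dt/tau = 0.1
  tr <- simulate_gene_circuit(m, 0, short_config(T = 5))
  k <- c(1, 5, 17, 50)
  expect_equal(tr$states[k + 1, 1], 0.5 * (1 - 0.9^k), tolerance = 1e-12)

  # one audited step against the printed update on random (W, B, y)
  set.seed(11)
  W <- matrix(runif(9, -30, 30), 3); B <- runif(3, -10, 10)
  tau <- runif(3, 1, 15); y0 <- runif(3)
  m3 <- gene_circuit(W, B, tau)
  tr <- simulate_gene_circuit(m3, y0, short_config(T = 0.2))
  a <- 0.1 / tau
  manual <- a * (1 / (1 + exp(-(W %*% y0 + B)))) + (1 - a) * y0
  expect_equal(tr$states[2, ], as.numeric(manual), tolerance = 1e-14)
})

test_that("rollout grid and validity contracts hold", {
  tr <- simulate_gene_circuit(gene_circuit(matrix(0, 2, 2)), c(0.3, 0.7))
  expect_identical(nrow(tr$states), 25001L)
  expect_true(is_valid_trajectory(tr))
  expect_equal(diff(tr$times)[1], 0.1)

  # dt/tau > 1 violates the explicit-update precondition
  expect_error(simulate_gene_circuit(gene_circuit(matrix(0, 1, 1), tau = 0.01),
                                     0.5, short_config(T = 1)),
               "dt/tau")

  # a displacement event driving the state non-finite flags, never raises
  m <- gene_circuit(matrix(0, 1, 1))
  tr <- simulate_gene_circuit(m, 0.5, short_config(T = 2),
                              events = list(times = 1, disp = matrix(Inf, 1, 1)))
  expect_false(is_valid_trajectory(tr))
})

test_that("states stay in (0,1) and rollouts are reproducible", {
  set.seed(2)
  for (s in 1:10) {
    m <- sample_random_gene_circuit(3, seed = s)
    y0 <- runif(3, 0.01, 0.99)
    tr <- simulate_gene_circuit(m, y0, short_config(T = 100))
    expect_true(all(tr$states > 0 & tr$states < 1))
  }
  m <- sample_random_gene_circuit(4, seed = 3)
  t1 <- simulate_gene_circuit(m, rep(0.5, 4), short_config(T = 50))
  t2 <- simulate_gene_circuit(m, rep(0.5, 4), short_config(T = 50))
  expect_identical(t1$states, t2$states)
})

test_that("adaptive ODE rollout meets its contract", {
  om <- ode_model(1, function(y, t, p) 0 * y, 0.7)
  tr <- simulate_ode(om, 0.7, short_config(T = 5))
  expect_true(all(tr$states == 0.7))

  om <- ode_model(1, function(y, t, p) -y, 1)
  tr <- simulate_ode(om, 1, rollout_config(T = 5, dt = 0.1))
  expect_equal(tr$states[51, 1], exp(-5), tolerance = 1e-5)
  expect_identical(nrow(tr$states), 51L)

  # solver blow-up flags invalid instead of raising
  om <- ode_model(1, function(y, t, p) y^2, 1)
  tr <- simulate_ode(om, 2, rollout_config(T = 5, dt = 0.1))
  expect_false(is_valid_trajectory(tr))
})

test_that("discrete circuit and its continuous analog share fixed points", {
  agree <- 0; tested <- 0
  for (s in 1:20) {
    m <- sample_random_gene_circuit(3, seed = 100 + s)
    y0 <- rep(0.5, 3)
    cfg <- rollout_config(T = 2500, dt = 0.1)
    td <- simulate_gene_circuit(m, y0, cfg)
    settled <- all(vapply(1:3, function(nd)
      classify_trajectory(td, nd)$settled, logical(1)))
    if (!settled) next
    tc <- simulate_ode(circuit_to_ode(m), y0, cfg)
    tested <- tested + 1
    if (max(abs(td$states[25001, ] - tc$states[25001, ])) < 1e-3)
      agree <- agree + 1
  }
  expect_gte(tested, 10)
  expect_identical(agree, tested)
})

test_that("random circuit sampling follows the stated laws", {
  # in-degree structure
  m <- sample_random_gene_circuit(5, in_degrees = c(0, 1, 2, 5, 3), seed = 1)
  expect_equal(rowSums(m$W != 0), c(0, 1, 2, 5, 3))
  expect_error(sample_random_gene_circuit(3, in_degrees = c(1, 4, 1)),
               "node 2")

  # marginals: nonzero W ~ U[-30,30], B ~ U[-10,10], tau ~ U[1,15]
  set.seed(5)
  ws <- bs <- ts <- c()
  for (k in 1:1200) {
    m <- sample_random_gene_circuit(3)
    ws <- c(ws, m$W[m$W != 0]); bs <- c(bs, m$B); ts <- c(ts, m$tau)
  }
  expect_gt(stats::ks.test(ws, "punif", -30, 30)$p.value, 0.01)
  expect_gt(stats::ks.test(bs, "punif", -10, 10)$p.value, 0.01)
  expect_gt(stats::ks.test(ts, "punif", 1, 15)$p.value, 0.01)
})

test_that("circuit JSON round-trips losslessly", {
  m <- sample_random_gene_circuit(4, in_degrees = c(2, 1, 4, 0), seed = 9)
  p <- withr::local_tempfile(fileext = ".json")
  write_circuit_json(m, p)
  m2 <- read_circuit_json(p)
  expect_equal(m2$W, m$W)
  expect_equal(m2$B, m$B)
  expect_equal(m2$tau, m$tau)
})
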