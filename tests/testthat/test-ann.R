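# Network primitives, training and topology search.

test_that("activation functions match their definitions", {
  expect_equal(activation("logistic", 0), 0.5)
  expect_equal(activation("tanh", 0), 0)
  expect_equal(activation("gaussian", 0), 1)
  x <- seq(-3, 3, 0.5)
  expect_equal(activation("linear", x), x)
  expect_equal(activation("exponential", x), exp(x))
  expect_equal(activation("logistic", x), 1 / (1 + exp(-x)))
  expect_error(activation("step", 1), "unknown activation")
})

test_that("parameter count follows Nin*Nh + Nh + Nout*Nh + Nout", {
  expect_equal(count_parameters(network_spec("mlp", 9)), 46L)
  expect_equal(count_parameters(network_spec("mlp", 1)), 6L)
  expect_equal(count_parameters(network_spec("mlp", 16)), 81L)
})

test_that("hidden-size rule of thumb matches independent arithmetic", {
  expect_equal(estimate_hidden_nodes(243, 3, 1), (243 - 5) / 25)
  expect_equal(estimate_hidden_nodes(243, 3, 1), 9.52)
  expect_equal(estimate_hidden_nodes(30, 3, 1), 1)
  # algebraic inverse of the five-cases-per-parameter rule
  for (H in c(1L, 3L, 9L, 16L)) {
    L <- 5L * count_parameters(network_spec("mlp", H))
    expect_equal(estimate_hidden_nodes(L, 3, 1), H)
  }
  expect_error(estimate_hidden_nodes(5, 3, 1), "exceed")
})

test_that("network spec validates its fields", {
  expect_error(network_spec("mlp", 0), ">= 1")
  expect_error(network_spec("rbf", 3, "logistic"), "gaussian")
  expect_equal(network_spec("rbf", 3)$hidden_activation, "gaussian")
})

test_that("forward pass agrees with a hand-computed composition", {
  # all-zero weights: constant output = unscale(output bias)
  sc <- list(x_min = c(0.75, 12, 0), x_max = c(0.90, 30, 72),
             y_min = 2, y_max = 8)
  flat <- manual_mlp(matrix(0, 3, 2), c(0, 0), c(0, 0), 0.25, sc)
  conds <- data.frame(water_activity = c(0.8, 0.88),
                      temperature_C = c(15, 29), time_days = c(0, 60))
  expect_equal(as.numeric(predict(flat, conds)), rep(2 + 0.25 * 6, 2))

  # one hidden node, hand-set weights, identity scaling
  w1 <- c(0.3, -0.2, 0.5); b1 <- 0.1; w2 <- 1.7; b2 <- -0.4
  net <- manual_mlp(matrix(w1, 3, 1), b1, w2, b2, identity_scaling)
  x <- c(0.2, 0.9, 0.4)
  hand <- w2 * (1 / (1 + exp(-(sum(w1 * x) + b1)))) + b2
  got <- predict(net, data.frame(water_activity = x[1], temperature_C = x[2],
                                 time_days = x[3]))
  expect_equal(as.numeric(got), hand, tolerance = 1e-12)
})

test_that("out-of-bounds conditions are flagged as extrapolation", {
  sc <- list(x_min = c(0.75, 12, 0), x_max = c(0.90, 30, 72),
             y_min = 2, y_max = 8)
  net <- manual_mlp(matrix(0.1, 3, 2), c(0, 0), c(0.5, 0.5), 0, sc)
  p <- predict(net, data.frame(water_activity = c(0.8, 0.95),
                               temperature_C = c(20, 20),
                               time_days = c(10, 10)))
  expect_equal(attr(p, "extrapolated"), c(FALSE, TRUE))
})

test_that("an RBF node centred at the input responds with 1", {
  ds <- small_dataset(noise_sd = 0, seed = 31, split_seed = 32)
  L <- ds[ds$role == "learning", ][1:10, ]
  net <- train_rbf(network_spec("rbf", 3), L, init_seed = 1)
  # evaluate the hidden layer at the first centre itself
  centre_scaled <- net$centers[1L, ]
  rng <- net$scaling$x_max - net$scaling$x_min
  conds <- data.frame(
    water_activity = centre_scaled[1] * rng[1] + net$scaling$x_min[1],
    temperature_C = centre_scaled[2] * rng[2] + net$scaling$x_min[2],
    time_days = centre_scaled[3] * rng[3] + net$scaling$x_min[3])
  X <- psdeg:::scale_inputs(psdeg:::condition_matrix(conds), net$scaling)
  Phi <- psdeg:::rbf_hidden(net, X)
  expect_equal(Phi[1, 1], 1, tolerance = 1e-12)
})

test_that("MLP training represents linear data exactly", {
  ds <- small_dataset(noise_sd = 0, seed = 41, split_seed = 42)
  lin <- ds
  lin$ps_mg_per_g <- 3 + 2 * lin$water_activity + 0.05 * lin$temperature_C -
    0.01 * lin$time_days
  L <- lin[lin$role == "learning", ]
  Tt <- lin[lin$role == "test", ]
  net <- train_mlp(network_spec("mlp", 3, "linear"), L, Tt,
                   init_seed = 5, max_iterations = 500)
  expect_lt(net$errors[["learning"]], 1e-6)
})

test_that("MLP training is deterministic and honours max_iterations = 0", {
  ds <- small_dataset(seed = 51, split_seed = 52)
  L <- ds[ds$role == "learning", ]
  Tt <- ds[ds$role == "test", ]
  spec <- network_spec("mlp", 4)

  a <- train_mlp(spec, L, Tt, init_seed = 9, max_iterations = 60)
  b <- train_mlp(spec, L, Tt, init_seed = 9, max_iterations = 60)
  expect_identical(a$hidden_weights, b$hidden_weights)
  expect_identical(a$output_weights, b$output_weights)

  init <- train_mlp(spec, L, Tt, init_seed = 9, max_iterations = 0)
  set.seed(9)
  theta0 <- runif(count_parameters(spec), -0.5, 0.5)
  expect_equal(as.vector(init$hidden_weights), theta0[1:12])
  expect_gt(init$errors[["learning"]], a$errors[["learning"]])
})

test_that("early stopping keeps the best test-error snapshot", {
  ds <- small_dataset(seed = 61, split_seed = 62)
  L <- ds[ds$role == "learning", ]
  Tt <- ds[ds$role == "test", ]
  net <- train_mlp(network_spec("mlp", 8), L, Tt, init_seed = 3,
                   max_iterations = 150)
  # the snapshot's test error can never exceed the initial network's
  init <- train_mlp(network_spec("mlp", 8), L, Tt, init_seed = 3,
                    max_iterations = 0)
  expect_lte(net$errors[["test"]], init$errors[["test"]])
})

test_that("RBF networks interpolate when every point is a centre", {
  ds <- small_dataset(noise_sd = 0.05, seed = 71, split_seed = 72)
  L <- ds[ds$role == "learning", ][1:25, ]
  net <- train_rbf(network_spec("rbf", 25), L, init_seed = 2)
  expect_lt(net$errors[["learning"]], 1e-8)
})

test_that("RBF training reproduces a constant target and is deterministic", {
  ds <- small_dataset(seed = 81, split_seed = 82)
  L <- ds[ds$role == "learning", ]
  const <- L
  const$ps_mg_per_g <- rep(5.5, nrow(const))
  # constant target: degenerate y-scaling, output must still be exact
  net <- train_rbf(network_spec("rbf", 6), const, init_seed = 4)
  expect_lt(net$errors[["learning"]], 1e-10)
  expect_equal(as.numeric(predict(net, const[1:4, ])), rep(5.5, 4),
               tolerance = 1e-4)

  a <- train_rbf(network_spec("rbf", 10), L, init_seed = 6)
  b <- train_rbf(network_spec("rbf", 10), L, init_seed = 6)
  expect_identical(a$centers, b$centers)
  expect_identical(a$output_weights, b$output_weights)

  expect_error(train_rbf(network_spec("rbf", 100), L[1:20, ]), "exceeds")
})

test_that("architecture search selects by weighted error with role shares", {
  ds <- small_dataset(seed = 91, split_seed = 92)
  grid <- list(network_spec("mlp", 2), network_spec("mlp", 5))
  sr <- architecture_search(ds, grid, restarts = 3, base_seed = 100,
                            max_iterations = 60)
  expect_equal(sum(sr$weights), 1)
  expect_equal(unname(sr$weights), unname(set_shares(ds)))

  # exhaustive check: retrain every (topology, restart) with the derived
  # seeds and confirm nothing beats the selected network
  L <- ds[ds$role == "learning", ]; Tt <- ds[ds$role == "test", ]
  V <- ds[ds$role == "validation", ]
  werrs <- c()
  for (i in seq_along(grid)) for (j in 1:3) {
    net <- train_mlp(grid[[i]], L, Tt, V,
                     init_seed = 100L + (i - 1L) * 3L + (j - 1L),
                     max_iterations = 60)
    werrs <- c(werrs, sum(sr$weights * net$errors))
  }
  best_w <- sum(sr$weights * sr$best$errors)
  expect_lte(best_w, min(werrs) + 1e-12)

  # single-topology grid returns that topology
  one <- architecture_search(ds, list(network_spec("mlp", 3)), restarts = 2,
                             base_seed = 5, max_iterations = 40)
  expect_equal(one$best$spec$n_hidden, 3L)
  expect_equal(nrow(one$curves), 1L)
})

test_that("the best-over-restarts error is monotone in the restart budget", {
  ds <- small_dataset(seed = 93, split_seed = 94)
  grid <- list(network_spec("mlp", 4))
  w2 <- architecture_search(ds, grid, restarts = 2, base_seed = 7,
                            max_iterations = 60)
  w4 <- architecture_search(ds, grid, restarts = 4, base_seed = 7,
                            max_iterations = 60)
  # seeds {7,8} nest inside {7,8,9,10} for a single-topology grid
  expect_lte(sum(w4$weights * w4$best$errors),
             sum(w2$weights * w2$best$errors))
})

test_that("equal per-set errors give a weighted error equal to that error", {
  w <- c(learning = 0.52, test = 0.23, validation = 0.25)
  e <- c(learning = 0.013, test = 0.013, validation = 0.013)
  expect_equal(psdeg:::weighted_error(e, w), 0.013)
})

test_that("network JSON round-trips to identical predictions", {
  ds <- small_dataset(seed = 95, split_seed = 96)
  L <- ds[ds$role == "learning", ]; Tt <- ds[ds$role == "test", ]
  conds <- ds[seq(1, nrow(ds), length.out = 9), ]
  for (net in list(train_mlp(network_spec("mlp", 5, "tanh"), L, Tt,
                             init_seed = 1, max_iterations = 50),
                   train_rbf(network_spec("rbf", 7), L, Tt, init_seed = 1))) {
    path <- withr::local_tempfile(fileext = ".json")
    write_network_json(net, path)
    back <- read_network_json(path)
    expect_equal(as.numeric(predict(back, conds)),
                 as.numeric(predict(net, conds)), tolerance = 0)
    expect_equal(back$errors, net$errors, tolerance = 0)
  }
})
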