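# GNN-GRU model: graph convolution, forward pass, training, PSO.

test_that("gcn_forward collapses to an affine map on a single self-loop node", {
  g <- list(node_features = matrix(c(1, 2, 3), 1, 3),
            edge_index = matrix(c(1, 1), 1, 2))
  W <- matrix(seq(0.1, 0.6, length.out = 6), 3, 2)
  b <- c(0.5, -1)
  expect_equal(gcn_forward(g, W, b), matrix(c(1, 2, 3) %*% W + b, 1, 2),
               ignore_attr = TRUE)
})

test_that("identical features on a complete graph give identical embeddings", {
  feats <- matrix(rep(c(1, -2, 0.5), each = 101), 101, 3)
  src <- rep(1:101, each = 101)
  dst <- rep(1:101, 101)
  g <- list(node_features = feats,
            edge_index = cbind(src, dst)[src != dst, ])
  withr::local_seed(4)
  W <- matrix(rnorm(6), 3, 2)
  out <- gcn_forward(g, W, activation = "relu")
  expect_equal(max(apply(out, 2, sd)), 0)
})

test_that("gcn_forward matches the dense normalized-adjacency oracle", {
  # property test over random graphs with <= 10 nodes
  withr::local_seed(11)
  for (i in 1:100) {
    n <- sample(2:10, 1)
    d <- sample(1:4, 1)
    k <- sample(1:3, 1)
    g <- random_toy_graph(n, d)
    W <- matrix(rnorm(d * k), d, k)
    b <- rnorm(k)
    # dense oracle: explicit D^-1/2 (A + I) D^-1/2 X W + b
    A <- matrix(0, n, n)
    A[g$edge_index] <- 1
    diag(A) <- 1
    Dm <- diag(1 / sqrt(rowSums(A)))
    oracle <- Dm %*% A %*% Dm %*% g$node_features %*% W +
      matrix(b, n, k, byrow = TRUE)
    expect_lt(max(abs(gcn_forward(g, W, b) - oracle)), 1e-6)
  }
})

test_that("forward emits 1 x 101 curves; zero weights give zero output", {
  world <- small_world()
  model <- toy_model(seed = 2)
  y <- predict(model, world$graphs[[1]])
  expect_equal(dim(y), c(1, 101))

  zero <- model
  zero$params <- serveload:::tree_map2(zero$params, zero$params, function(a, b) a * 0)
  expect_equal(unname(predict(zero, world$graphs[[1]])), matrix(0, 1, 101))

  # deterministic given weights and input
  expect_identical(predict(model, world$graphs[[1]]), y)
})

test_that("the GRU recurrence matches the hand-computed gate equations", {
  # 2 inputs, 2 hidden units, 2 steps; independently coded update
  withr::local_seed(7)
  wts <- toy_gru_weights(2, 2)
  wts$br <- c(0.1, -0.2)
  wts$bz <- c(0.05, 0.3)
  wts$bc <- c(-0.1, 0.2)
  x1 <- c(0.5, -1)
  x2 <- c(1.5, 0.25)

  sig <- function(v) 1 / (1 + exp(-v))
  h0 <- c(0, 0)
  step <- function(x, h) {
    r <- sig(as.numeric(x %*% wts$Wxr + h %*% wts$Whr) + wts$br)
    z <- sig(as.numeric(x %*% wts$Wxz + h %*% wts$Whz) + wts$bz)
    cc <- tanh(as.numeric(x %*% wts$Wxc + (r * h) %*% wts$Whc) + wts$bc)
    (1 - z) * h + z * cc
  }
  h1 <- step(x1, h0)
  h2 <- step(x2, h1)

  params <- list(gcn = list(), gru = wts, head = list(w = matrix(c(1, 0), 2, 1), b = 0))
  X <- array(0, c(1, 2, 2))
  X[1, 1, ] <- x1
  X[1, 2, ] <- x2
  fw <- serveload:::forward_batch(params, X, diag(2), baseline_mode = TRUE,
                                  cache = TRUE)
  expect_lt(max(abs(fw$gates$h[1, 1, ] - h1)), 1e-9)
  expect_lt(max(abs(fw$gates$h[1, 2, ] - h2)), 1e-9)
  expect_lt(abs(fw$Y[1, 2] - h2[1]), 1e-9)
})

test_that("training gradients agree with finite differences", {
  # spot-check a handful of coordinates of every parameter block
  withr::local_seed(13)
  config <- model_config(n_gcn_layers = 2, gcn_width = 3, gru_width = 3,
                         seed = 5, zscore = FALSE)
  params <- serveload:::init_params(config, d_in = 6L)
  B <- 2
  X <- array(rnorm(B * 101 * 6, sd = 0.5), c(B, 101, 6))
  targets <- matrix(rnorm(B * 101), B, 101)
  Ahat <- serveload:::normalized_adjacency(build_graph(matrix(0, 6, 101))$edge_index, 101)
  loss_fn <- function(p) {
    fw <- serveload:::forward_batch(p, X, Ahat, FALSE)
    mean((fw$Y - targets)^2)
  }
  fw <- serveload:::forward_batch(params, X, Ahat, FALSE, cache = TRUE)
  grads <- serveload:::backward_batch(params, fw, X, Ahat, targets, FALSE)
  eps <- 1e-6
  check <- function(path_get, path_set, idx) {
    g_an <- path_get(grads)[idx]
    p_plus <- path_set(params, idx, eps)
    p_minus <- path_set(params, idx, -eps)
    g_num <- (loss_fn(p_plus) - loss_fn(p_minus)) / (2 * eps)
    expect_equal(g_an, g_num, tolerance = 1e-4)
  }
  bump <- function(get, assign) {
    function(p, idx, d) {
      v <- get(p)
      v[idx] <- v[idx] + d
      assign(p, v)
    }
  }
  check(function(g) g$gcn[[1]]$W,
        bump(function(p) p$gcn[[1]]$W, function(p, v) { p$gcn[[1]]$W <- v; p }), 3)
  check(function(g) g$gcn[[2]]$b,
        bump(function(p) p$gcn[[2]]$b, function(p, v) { p$gcn[[2]]$b <- v; p }), 2)
  check(function(g) g$gru$Wxc,
        bump(function(p) p$gru$Wxc, function(p, v) { p$gru$Wxc <- v; p }), 5)
  check(function(g) g$gru$Whr,
        bump(function(p) p$gru$Whr, function(p, v) { p$gru$Whr <- v; p }), 4)
  check(function(g) g$gru$bz,
        bump(function(p) p$gru$bz, function(p, v) { p$gru$bz <- v; p }), 1)
  check(function(g) g$head$w,
        bump(function(p) p$head$w, function(p, v) { p$head$w <- v; p }), 2)
})

test_that("training fits a linearly-solvable toy and is seed-reproducible", {
  # noiseless targets, affine in the node features, baseline GRU
  withr::local_seed(21)
  coefs <- c(0.4, -0.3, 0.2, 0.1, -0.2, 0.3)
  graphs <- lapply(1:12, function(i) {
    feats <- matrix(rnorm(6 * 101, sd = 0.5), 6, 101)
    graph_from_features(feats, target = as.numeric(coefs %*% feats))
  })
  config <- model_config(gru_width = 24, epochs = 100, learning_rate = 0.01,
                         batch_size = 4, seed = 3, baseline_mode = TRUE)
  st <- train_model(graphs, config)
  expect_lt(tail(st$loss_history$train, 1), 1e-3)
  expect_equal(nrow(st$loss_history), 100)

  config1 <- model_config(gru_width = 8, epochs = 1, seed = 4, baseline_mode = TRUE)
  st1 <- train_model(graphs, config1)
  expect_equal(nrow(st1$loss_history), 1)

  st_a <- train_model(graphs[1:6], model_config(gru_width = 8, epochs = 3, seed = 9))
  st_b <- train_model(graphs[1:6], model_config(gru_width = 8, epochs = 3, seed = 9))
  expect_identical(st_a$loss_history, st_b$loss_history)
})

test_that("model checkpoints round-trip through JSON", {
  world <- small_world()
  graphs <- world$graphs[1:6]
  st <- train_model(graphs, model_config(gcn_width = 4, gru_width = 4, epochs = 2,
                                         seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(st$model, path)
  back <- load_model(path)
  expect_equal(predict(back, world$graphs[[7]]), predict(st$model, world$graphs[[7]]),
               tolerance = 1e-12)
  expect_identical(back$config$gcn_width, 4L)
})

test_that("PSO minimizes the sphere function and honours bounds", {
  sphere <- function(x) sum(x^2)
  res <- pso_optimize(sphere, lower = c(-5, -5), upper = c(5, 5),
                      swarm_size = 20, iterations = 50, seed = 2)
  expect_lt(res$best_value, 1e-4)
  expect_true(all(abs(res$best_x) <= 5))

  # 1 particle, 0 iterations: the seeded initial point comes back
  res0 <- pso_optimize(sphere, c(-1, -1), c(1, 1), swarm_size = 1,
                       iterations = 0, seed = 8)
  init <- serveload:::with_seed(serveload:::derive_seed(8, 41L), {
    c(runif(1, -1, 1), runif(1, -1, 1))
  })
  expect_equal(res0$best_x, init)
  expect_equal(res0$best_value, sphere(init))

  # same seed, same trajectory
  r1 <- pso_optimize(sphere, c(-2, -2), c(2, 2), 5, 10, seed = 3)
  r2 <- pso_optimize(sphere, c(-2, -2), c(2, 2), 5, 10, seed = 3)
  expect_identical(r1, r2)

  expect_error(pso_optimize(sphere, numeric(), numeric()),
               class = "serveload_argument_error")
})

test_that("pso_tune decodes typed search spaces", {
  space <- list(
    lr = list(type = "log", lower = 1e-4, upper = 1e-2),
    width = list(type = "choice", values = c(16, 32, 64))
  )
  # objective prefers high lr and width 32
  obj <- function(cfg) abs(log10(cfg$lr) + 2.2) + abs(cfg$width - 32) / 16
  res <- pso_tune(space, obj, swarm_size = 12, iterations = 20, seed = 5)
  expect_true(res$best_config$width %in% c(16, 32, 64))
  expect_equal(res$best_config$width, 32)
  expect_gt(res$best_config$lr, 1e-4)
  expect_lt(res$best_config$lr, 1e-2)
  expect_error(pso_tune(list(), obj), class = "serveload_argument_error")
})
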