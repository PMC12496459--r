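# Layer-wise relevance propagation rules and end-to-end explanation.

test_that("lrp_linear conserves relevance and matches the brute-force rule", {
  withr::local_seed(31)
  x <- rnorm(4)
  W <- matrix(rnorm(12), 4, 3)
  R_out <- rnorm(3)

  # bias-free, epsilon = 0: exact conservation
  R_in <- lrp_linear(x, W, numeric(3), R_out, epsilon = 0)
  expect_equal(sum(R_in), sum(R_out), tolerance = 1e-9)

  # single positive output: relevance proportional to x_i * W_i
  xp <- abs(rnorm(4)) + 0.1
  Wp <- matrix(abs(rnorm(4)) + 0.1, 4, 1)
  Rp <- lrp_linear(xp, Wp, 0, R_out = 2, epsilon = 0)
  expect_equal(Rp / (xp * Wp[, 1]), rep(Rp[1] / (xp[1] * Wp[1, 1]), 4))

  # brute-force index-by-index oracle, with bias and epsilon
  b <- rnorm(3)
  eps <- 1e-3
  oracle <- numeric(4)
  for (i in 1:4) {
    for (j in 1:3) {
      z_j <- sum(x * W[, j]) + b[j]
      oracle[i] <- oracle[i] +
        x[i] * W[i, j] / (z_j + eps * sign(z_j)) * R_out[j]
    }
  }
  expect_lt(max(abs(lrp_linear(x, W, b, R_out, eps) - oracle)), 1e-12)

  expect_error(lrp_linear(x, W, numeric(3), R_out[1:2]),
               class = "serveload_argument_error")
})

test_that("the GRU step rule honours the gate limit cases and conserves", {
  withr::local_seed(32)
  nh <- 3
  wts <- toy_gru_weights(2, nh)
  h_prev <- rnorm(nh)
  x <- rnorm(2)
  r <- sigmoid_like <- runif(nh, 0.2, 0.8)
  R_ht <- rnorm(nh)

  # z = 1: all relevance through the candidate map, none on the carry
  cand <- tanh(as.numeric(x %*% wts$Wxc + (r * h_prev) %*% wts$Whc))
  step1 <- lrp_gru_step(
    list(x = x, h_prev = h_prev, r = r, z = rep(1, nh), c = cand),
    wts, R_ht, epsilon = 0
  )
  expect_equal(sum(step1$R_x) + sum(step1$R_h_prev), sum(R_ht), tolerance = 1e-9)
  # carry share is exactly zero: relevance on h_prev only via the candidate
  R_cand_split <- lrp_linear(c(x, r * h_prev), rbind(wts$Wxc, wts$Whc),
                             numeric(nh), R_ht, 0)
  expect_equal(step1$R_h_prev, R_cand_split[3:5])

  # z = 0: pure carry, h_t = h_prev
  step0 <- lrp_gru_step(
    list(x = x, h_prev = h_prev, r = r, z = rep(0, nh), c = cand),
    wts, R_ht, epsilon = 0
  )
  expect_equal(step0$R_h_prev, R_ht)
  expect_equal(step0$R_x, c(0, 0))

  expect_error(lrp_gru_step(list(x = x), wts, R_ht),
               class = "serveload_state_error")
})

test_that("a 2-step bias-free toy GRU conserves relevance end to step", {
  withr::local_seed(33)
  nh <- 3
  wts <- toy_gru_weights(2, nh, scale = 0.5)
  h0 <- numeric(nh)
  xs <- list(rnorm(2), rnorm(2))
  states <- list()
  h <- h0
  for (t in 1:2) {
    r <- 1 / (1 + exp(-(as.numeric(xs[[t]] %*% wts$Wxr + h %*% wts$Whr))))
    z <- 1 / (1 + exp(-(as.numeric(xs[[t]] %*% wts$Wxz + h %*% wts$Whz))))
    cc <- tanh(as.numeric(xs[[t]] %*% wts$Wxc + (r * h) %*% wts$Whc))
    h_new <- (1 - z) * h + z * cc
    states[[t]] <- list(x = xs[[t]], h_prev = h, r = r, z = z, c = cc)
    h <- h_new
  }
  R_h2 <- rnorm(nh)
  s2 <- lrp_gru_step(states[[2]], wts, R_h2, epsilon = 0)
  expect_equal(sum(s2$R_x) + sum(s2$R_h_prev), sum(R_h2), tolerance = 1e-9)
  s1 <- lrp_gru_step(states[[1]], wts, s2$R_h_prev, epsilon = 0)
  # h0 = 0 carries nothing, so input relevance alone carries the total
  expect_equal(sum(s1$R_x) + sum(s2$R_x), sum(R_h2), tolerance = 1e-9)
})

test_that("lrp_gcn equals lrp_linear on a single self-loop node and
           matches the dense epsilon-rule oracle", {
  withr::local_seed(34)
  g1 <- list(node_features = matrix(rnorm(3), 1, 3),
             edge_index = matrix(c(1, 1), 1, 2))
  W <- matrix(rnorm(6), 3, 2)
  R_out <- matrix(rnorm(2), 1, 2)
  got <- lrp_gcn(g1, g1$node_features, W, numeric(2), R_out, epsilon = 1e-6)
  want <- lrp_linear(g1$node_features[1, ], W, numeric(2), R_out[1, ], 1e-6)
  expect_equal(as.numeric(got), want, tolerance = 1e-12)

  # 3-node toy graph vs explicit dense map (Ahat kron W) oracle
  g3 <- list(node_features = matrix(rnorm(6), 3, 2),
             edge_index = matrix(c(1, 2, 2, 1, 2, 3, 3, 2), 4, 2, byrow = TRUE))
  W2 <- matrix(rnorm(4), 2, 2)
  R3 <- matrix(rnorm(6), 3, 2)
  A <- matrix(0, 3, 3)
  A[g3$edge_index] <- 1
  diag(A) <- 1
  Dm <- diag(1 / sqrt(rowSums(A)))
  Ahat <- Dm %*% A %*% Dm
  X <- g3$node_features
  Z <- Ahat %*% X %*% W2
  eps <- 1e-6
  oracle <- matrix(0, 3, 2)
  for (u in 1:3) {
    for (i in 1:2) {
      for (v in 1:3) {
        for (j in 1:2) {
          zvj <- Z[v, j]
          oracle[u, i] <- oracle[u, i] +
            Ahat[v, u] * X[u, i] * W2[i, j] / (zvj + eps * sign(zvj)) * R3[v, j]
        }
      }
    }
  }
  expect_lt(max(abs(lrp_gcn(g3, X, W2, numeric(2), R3, eps) - oracle)), 1e-9)

  # bias-free conservation
  cons <- lrp_gcn(g3, X, W2, numeric(2), R3, epsilon = 0)
  expect_equal(sum(cons), sum(R3), tolerance = 1e-9)
})

test_that("explain produces a 101 x 6 map and conserves on a bias-free model", {
  world <- small_world()
  graph <- world$graphs[[3]]
  model <- toy_model(gcn_width = 6, gru_width = 5, n_gcn_layers = 2,
                     bias_free = TRUE, seed = 6)
  rmap <- explain(model, graph, epsilon = 0)
  expect_s3_class(rmap, "relevance_map")
  expect_equal(dim(rmap$raw), c(101, 6))
  expect_true(all(rmap$normalized >= 0 & rmap$normalized <= 1))
  expect_equal(max(rmap$normalized), 1)
  # end-to-end conservation: total input relevance = total seeded relevance
  expect_equal(sum(rmap$raw) / sum(rmap$y), 1, tolerance = 1e-4)
})

test_that("layerwise conservation holds through every rule at epsilon 0", {
  # assemble head -> GRU -> GCN relevance flow on a tiny bias-free model
  world <- small_world()
  graph <- world$graphs[[1]]
  model <- toy_model(gcn_width = 4, gru_width = 4, n_gcn_layers = 1,
                     bias_free = TRUE, seed = 9)
  fw <- forward_cached(model, graph)
  R_y <- fw$y
  total_in <- sum(explain(model, graph, epsilon = 0)$raw)
  expect_equal(total_in / sum(R_y), 1, tolerance = 1e-6)
})

test_that("an identically-zero input feature receives zero relevance", {
  world <- small_world()
  feats <- world$ntrials[[1]]$angles
  feats[4, ] <- 0 # r_ankle silenced
  graph <- build_graph(feats)
  model <- toy_model(gcn_width = 5, gru_width = 4, n_gcn_layers = 2,
                     bias_free = TRUE, seed = 12)
  rmap <- explain(model, graph, epsilon = 0)
  expect_equal(max(abs(rmap$raw[, 4])), 0)
})

test_that("aggregate_and_normalize spans [0, 1] and is scale invariant", {
  withr::local_seed(35)
  maps <- lapply(1:3, function(i) matrix(rnorm(101 * 6), 101, 6))
  agg <- aggregate_and_normalize(maps)
  expect_equal(min(agg), 0)
  expect_equal(max(agg), 1)
  scaled <- aggregate_and_normalize(lapply(maps, function(m) 7 * m))
  expect_equal(scaled, agg, tolerance = 1e-12)

  per_feat <- aggregate_and_normalize(maps, method = "per_feature")
  expect_equal(unname(apply(per_feat, 2, max)), rep(1, 6))

  # constant raw maps: all zeros by convention
  expect_equal(max(aggregate_and_normalize(list(matrix(2, 101, 6)))), 0)
  expect_error(aggregate_and_normalize(list()), class = "serveload_argument_error")
})

test_that("contribution curves round-trip through the CSV writer", {
  withr::local_seed(36)
  contrib <- aggregate_and_normalize(list(matrix(rnorm(101 * 6), 101, 6)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_contributions_csv(contrib, path, epsilon = 1e-6)
  back <- read.csv(path)
  expect_equal(nrow(back), 101)
  expect_equal(as.matrix(back[serveload:::JOINT_NAMES]), contrib,
               tolerance = 1e-10, ignore_attr = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$epsilon, 1e-6)
})
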