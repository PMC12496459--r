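# Shared fixtures, built in code and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small simulated dataset with its normalized trials and graphs.
small_world <- function() {
  cached("small_world", function() {
    config <- sim_config(n_participants = 12, trials_per_participant = 4,
                         seed = 42)
    trials <- simulate_dataset(config)
    ntrials <- lapply(trials, assemble_matrices)
    graphs <- lapply(ntrials, build_graph)
    list(
      config = config, trials = trials, ntrials = ntrials, graphs = graphs,
      participants = vapply(trials, `[[`, 1L, "participant_id")
    )
  })
}

# A tiny random graph (n nodes, edge probability p, both directions).
random_toy_graph <- function(n, d_feat = 3, p = 0.5) {
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  edge_index <- rbind(keep, keep[, 2:1, drop = FALSE])
  if (nrow(edge_index) == 0) edge_index <- matrix(c(1, 2, 2, 1), 2, 2, byrow = TRUE)
  list(
    node_features = matrix(rnorm(n * d_feat), n, d_feat),
    edge_index = edge_index
  )
}

# Hand-buildable GRU weights of width nh over d inputs, zero biases.
toy_gru_weights <- function(d, nh, scale = 0.4) {
  list(
    Wxr = matrix(rnorm(d * nh), d) * scale,
    Wxz = matrix(rnorm(d * nh), d) * scale,
    Wxc = matrix(rnorm(d * nh), d) * scale,
    Whr = matrix(rnorm(nh * nh), nh) * scale,
    Whz = matrix(rnorm(nh * nh), nh) * scale,
    Whc = matrix(rnorm(nh * nh), nh) * scale,
    br = numeric(nh), bz = numeric(nh), bc = numeric(nh)
  )
}

# A small untrained (random-weight) model with optional zero biases, wired
# for direct use with explain()/forward_cached() on standard serve graphs.
toy_model <- function(gcn_width = 8, gru_width = 8, n_gcn_layers = 2,
                      bias_free = FALSE, baseline_mode = FALSE, seed = 1) {
  config <- model_config(
    n_gcn_layers = n_gcn_layers, gcn_width = gcn_width,
    gru_width = gru_width, baseline_mode = baseline_mode,
    seed = seed, zscore = FALSE
  )
  params <- serveload:::init_params(config, d_in = 6L)
  if (bias_free) {
    params$gcn <- lapply(params$gcn, function(l) {
      l$b <- numeric(length(l$b))
      l
    })
    params$gru$br <- numeric(gru_width)
    params$gru$bz <- numeric(gru_width)
    params$gru$bc <- numeric(gru_width)
    params$head$b <- 0
  }
  structure(
    list(
      params = params, config = config,
      scaler = list(mean = rep(0, 6), sd = rep(1, 6),
                    target_mean = 0, target_sd = 1),
      format_version = "serveload-model-1"
    ),
    class = "serveload_model"
  )
}

# A standard 101-node serve graph with given feature matrix (6 x 101).
graph_from_features <- function(feats6x101, target = NULL) {
  g <- build_graph(feats6x101)
  g$target <- target
  g
}
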