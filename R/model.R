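# GNN-GRU regression model, implemented from scratch so that every
# intermediate quantity (aggregated node features, GRU gates, hidden
# states) is available to the relevance-propagation engine.
#
# Architecture: three graph-convolution layers (symmetric-normalized
# aggregation D^-1/2 (A+I) D^-1/2, 64 units, ReLU) -> 64-unit GRU over the
# 101 temporal nodes -> shared affine head emitting one scalar per node.
# Baseline mode skips the graph convolutions and feeds the raw 6-dim node
# features to the GRU.

#' Model configuration
#'
#' @param n_gcn_layers Number of graph-convolution layers (default 3).
#' @param gcn_width Units per graph-convolution layer (default 64).
#' @param gru_width GRU hidden units (default 64).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs Training epochs (default 100).
#' @param batch_size Graphs per gradient step (default 32; see the methods
#'   vignette for why minibatching replaces per-graph iteration).
#' @param loss_name Training loss; only `"mse"` is implemented.
#' @param seed Integer seed for initialization and batch shuffling.
#' @param baseline_mode Skip the graph convolutions (standalone GRU
#'   baseline).
#' @param zscore Standardize input features with train-split statistics
#'   (default TRUE).
#' @return A `model_config` object.
#' @export
model_config <- function(n_gcn_layers = 3, gcn_width = 64, gru_width = 64,
                         learning_rate = 0.001, epochs = 100, batch_size = 32,
                         loss_name = "mse", seed = 1L, baseline_mode = FALSE,
                         zscore = TRUE) {
  if (!is_count(n_gcn_layers) || !is_count(gcn_width) || !is_count(gru_width)) {
    abort_argument("layer counts and widths must be positive integers")
  }
  if (learning_rate <= 0) abort_argument("learning_rate must be positive")
  if (!is_count(epochs)) abort_argument("epochs must be a positive integer")
  if (!identical(loss_name, "mse")) abort_argument("only the 'mse' loss is implemented")
  structure(
    list(
      n_gcn_layers = as.integer(n_gcn_layers),
      gcn_width = as.integer(gcn_width),
      gru_width = as.integer(gru_width),
      learning_rate = learning_rate,
      epochs = as.integer(epochs),
      batch_size = as.integer(batch_size),
      loss_name = loss_name,
      seed = as.integer(seed),
      baseline_mode = isTRUE(baseline_mode),
      zscore = isTRUE(zscore)
    ),
    class = "model_config"
  )
}

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)

# uniform fan-in initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_mat <- function(nr, nc) {
  matrix(runif(nr * nc, -1, 1) / sqrt(nr), nr, nc)
}

init_params <- function(config, d_in = 6L) {
  with_seed(derive_seed(config$seed, 11L), {
    p <- list()
    if (!config$baseline_mode) {
      d <- d_in
      p$gcn <- lapply(seq_len(config$n_gcn_layers), function(l) {
        layer <- list(W = init_mat(d, config$gcn_width),
                      b = numeric(config$gcn_width))
        d <<- config$gcn_width
        layer
      })
      d_gru <- config$gcn_width
    } else {
      p$gcn <- list()
      d_gru <- d_in
    }
    H <- config$gru_width
    p$gru <- list(
      Wxr = init_mat(d_gru, H), Wxz = init_mat(d_gru, H), Wxc = init_mat(d_gru, H),
      Whr = init_mat(H, H), Whz = init_mat(H, H), Whc = init_mat(H, H),
      br = numeric(H), bz = numeric(H), bc = numeric(H)
    )
    p$head <- list(w = init_mat(H, 1L), b = 0)
    p
  })
}

# --- batched tensor helpers (arrays are (batch, node, feature)) -----------

amul <- function(A, Ahat) {
  d <- dim(A)
  m <- matrix(aperm(A, c(2, 1, 3)), nrow = d[2])
  out <- Ahat %*% m
  aperm(array(out, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
}

slice_t <- function(A, t) {
  d <- dim(A)
  matrix(A[, t, ], nrow = d[1], ncol = d[3])
}

flat2 <- function(A) {
  d <- dim(A)
  dim(A) <- c(d[1] * d[2], d[3])
  A
}

addb <- function(M, b) M + rep(b, each = nrow(M))

#' Graph-convolution forward pass
#'
#' One symmetric-normalized graph convolution:
#' `D^(-1/2) (A + I) D^(-1/2) X W + b`, optionally followed by ReLU. Works
#' on any graph given as a list with `node_features` (n x d) and
#' `edge_index` (E x 2, 1-based), so small toy graphs can be checked
#' against a dense linear-algebra oracle.
#'
#' @param graph List with `node_features` and `edge_index`.
#' @param W Weight matrix (d x width).
#' @param b Bias vector (length width).
#' @param activation `"relu"` or `"identity"` (default).
#' @return n x width embedding matrix.
#' @export
gcn_forward <- function(graph, W, b = numeric(ncol(W)),
                        activation = c("identity", "relu")) {
  activation <- match.arg(activation)
  X <- as.matrix(graph$node_features)
  if (ncol(X) != nrow(W)) abort_argument("weight shape does not match feature width")
  if (length(b) != ncol(W)) abort_argument("bias length does not match width")
  Ahat <- normalized_adjacency(graph$edge_index, nrow(X))
  out <- addb(Ahat %*% X %*% W, b)
  if (activation == "relu") out <- relu(out) else out
}

# Batched forward pass. X: (B, 101, 6) standardized features.
# Returns predictions (B x 101) and, when cache = TRUE, all intermediates
# needed for backprop and LRP.
forward_batch <- function(params, X, Ahat, baseline_mode, cache = FALSE) {
  B <- dim(X)[1]
  H_in <- X
  gcn_cache <- list()
  if (!baseline_mode) {
    for (l in seq_along(params$gcn)) {
      AX <- amul(H_in, Ahat)
      d <- dim(AX)
      W <- params$gcn[[l]]$W
      Z <- array(flat2(AX) %*% W, dim = c(d[1], d[2], ncol(W)))
      Z <- Z + rep(params$gcn[[l]]$b, each = d[1] * d[2])
      Hout <- relu(Z)
      if (cache) gcn_cache[[l]] <- list(X_in = H_in, AX = AX, H_out = Hout)
      H_in <- Hout
    }
  }
  g <- params$gru
  nh <- ncol(g$Whr)
  n_t <- dim(X)[2]
  h <- matrix(0, B, nh)
  Y <- matrix(0, B, n_t)
  if (cache) {
    Rc <- array(0, c(B, n_t, nh))
    Zc <- array(0, c(B, n_t, nh))
    Cc <- array(0, c(B, n_t, nh))
    Hc <- array(0, c(B, n_t, nh))
  }
  for (t in seq_len(n_t)) {
    x <- slice_t(H_in, t)
    r <- sigmoid(addb(x %*% g$Wxr + h %*% g$Whr, g$br))
    z <- sigmoid(addb(x %*% g$Wxz + h %*% g$Whz, g$bz))
    cc <- tanh(addb(x %*% g$Wxc + (r * h) %*% g$Whc, g$bc))
    h <- (1 - z) * h + z * cc
    Y[, t] <- h %*% params$head$w + params$head$b
    if (cache) {
      Rc[, t, ] <- r; Zc[, t, ] <- z; Cc[, t, ] <- cc; Hc[, t, ] <- h
    }
  }
  if (!cache) return(list(Y = Y))
  list(Y = Y, gcn = gcn_cache, Xg = H_in,
       gates = list(r = Rc, z = Zc, c = Cc, h = Hc))
}

# Backward pass for the MSE loss; returns gradients in the params layout.
backward_batch <- function(params, fw, X, Ahat, targets, baseline_mode) {
  B <- dim(X)[1]
  n_t <- dim(X)[2]
  g <- params$gru
  nh <- ncol(g$Whr)
  dY <- 2 * (fw$Y - targets) / (B * n_t)

  gr <- list(
    Wxr = 0 * g$Wxr, Wxz = 0 * g$Wxz, Wxc = 0 * g$Wxc,
    Whr = 0 * g$Whr, Whz = 0 * g$Whz, Whc = 0 * g$Whc,
    br = 0 * g$br, bz = 0 * g$bz, bc = 0 * g$bc
  )
  dw_head <- 0 * params$head$w
  db_head <- 0
  dXg <- array(0, dim(fw$Xg))
  dh <- matrix(0, B, nh)
  wvec <- as.numeric(params$head$w)
  for (t in n_t:1) {
    h_t <- slice_t(fw$gates$h, t)
    dyt <- dY[, t]
    dw_head <- dw_head + crossprod(h_t, dyt)
    db_head <- db_head + sum(dyt)
    dh <- dh + outer(dyt, wvec)
    h_prev <- if (t > 1) slice_t(fw$gates$h, t - 1) else matrix(0, B, nh)
    r <- slice_t(fw$gates$r, t)
    z <- slice_t(fw$gates$z, t)
    cc <- slice_t(fw$gates$c, t)
    x <- slice_t(fw$Xg, t)
    dz_pre <- dh * (cc - h_prev) * z * (1 - z)
    dc_pre <- dh * z * (1 - cc^2)
    drh <- dc_pre %*% t(g$Whc)
    dr_pre <- drh * h_prev * r * (1 - r)
    dXg[, t, ] <- dc_pre %*% t(g$Wxc) + dr_pre %*% t(g$Wxr) + dz_pre %*% t(g$Wxz)
    gr$Wxc <- gr$Wxc + crossprod(x, dc_pre)
    gr$Whc <- gr$Whc + crossprod(r * h_prev, dc_pre)
    gr$bc <- gr$bc + colSums(dc_pre)
    gr$Wxr <- gr$Wxr + crossprod(x, dr_pre)
    gr$Whr <- gr$Whr + crossprod(h_prev, dr_pre)
    gr$br <- gr$br + colSums(dr_pre)
    gr$Wxz <- gr$Wxz + crossprod(x, dz_pre)
    gr$Whz <- gr$Whz + crossprod(h_prev, dz_pre)
    gr$bz <- gr$bz + colSums(dz_pre)
    dh <- dh * (1 - z) + drh * r + dr_pre %*% t(g$Whr) + dz_pre %*% t(g$Whz)
  }

  grads <- list(gru = gr, head = list(w = dw_head, b = db_head))
  if (!baseline_mode && length(params$gcn)) {
    dH <- dXg
    gcn_grads <- vector("list", length(params$gcn))
    for (l in length(params$gcn):1) {
      cache_l <- fw$gcn[[l]]
      mask <- cache_l$H_out > 0
      dpre <- dH * mask
      fa <- flat2(cache_l$AX)
      fd <- flat2(dpre)
      gcn_grads[[l]] <- list(W = crossprod(fa, fd), b = colSums(fd))
      dAX <- array(fd %*% t(params$gcn[[l]]$W),
                   dim = dim(cache_l$X_in))
      dH <- amul(dAX, Ahat) # Ahat is symmetric
    }
    grads$gcn <- gcn_grads
  } else {
    grads$gcn <- list()
  }
  grads
}

# --- Adam over the nested parameter list ----------------------------------

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    # align by name where names exist (grads and params may order
    # sublists differently), else positionally
    if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
    out <- mapply(tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, tree_zero) else a * 0
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  mv <- tree_map2(state$m, state$v, function(m, v) {
    (m / bc1) / (sqrt(v / bc2) + eps)
  })
  state$params <- tree_map2(params, mv, function(p, u) p - lr * u)
  state
}

# --- training --------------------------------------------------------------

graphs_to_arrays <- function(graphs) {
  B <- length(graphs)
  X <- array(0, c(B, N_NODES, 6))
  targets <- matrix(NA_real_, B, N_NODES)
  for (i in seq_len(B)) {
    X[i, , ] <- graphs[[i]]$node_features
    if (!is.null(graphs[[i]]$target)) targets[i, ] <- graphs[[i]]$target
  }
  list(X = X, targets = targets)
}

apply_scaler <- function(X, scaler) {
  d <- dim(X)
  Xf <- flat2(X)
  Xf <- (Xf - rep(scaler$mean, each = nrow(Xf))) /
    rep(scaler$sd, each = nrow(Xf))
  array(Xf, d)
}

#' Train the GNN-GRU model (or the GRU baseline)
#'
#' Minimizes the mean-squared error between the predicted and target
#' 1 x 101 moment curves on the training split with Adam, recording the
#' training and validation loss each epoch. All randomness (weight
#' initialization, minibatch shuffling) is keyed to `config$seed`, so a
#' fixed seed reproduces the loss trajectory exactly.
#'
#' @param graphs List of `serve_graph` objects with non-NULL targets.
#' @param config A [model_config()].
#' @param split A `split_indices` from [split_dataset()] (validation losses
#'   use its validation set; pass NULL to train on everything).
#' @return A `train_state`: list with `model` (a `serveload_model` holding
#'   the weights, config and feature scaler), `loss_history` (data frame
#'   epoch/train/validation), `best_epoch` (lowest validation loss, for
#'   information only; no early stopping).
#' @export
train_model <- function(graphs, config = model_config(), split = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (length(graphs) == 0) abort_argument("no graphs supplied")
  arr <- graphs_to_arrays(graphs)
  if (anyNA(arr$targets)) abort_data("all training graphs need a target curve")
  train_idx <- if (is.null(split)) seq_along(graphs) else split$train
  val_idx <- if (is.null(split)) integer() else split$validation
  if (length(train_idx) == 0) abort_argument("empty training split")

  Xtr_raw <- arr$X[train_idx, , , drop = FALSE]
  scaler <- if (config$zscore) {
    f <- flat2(Xtr_raw)
    ttr <- arr$targets[train_idx, ]
    list(mean = colMeans(f), sd = pmax(apply(f, 2, sd), 1e-8),
         target_mean = mean(ttr), target_sd = max(sd(ttr), 1e-8))
  } else {
    list(mean = rep(0, 6), sd = rep(1, 6), target_mean = 0, target_sd = 1)
  }
  X <- apply_scaler(arr$X, scaler)
  targets_sc <- (arr$targets - scaler$target_mean) / scaler$target_sd
  Ahat <- normalized_adjacency(graphs[[1]]$edge_index, N_NODES)

  params <- init_params(config, d_in = 6L)
  state <- list(params = params, m = tree_zero(params), v = tree_zero(params))
  n_train <- length(train_idx)
  bs <- min(config$batch_size, n_train)
  loss_tr <- loss_val <- numeric(config$epochs)
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, 17L, ep), sample(train_idx))
    batches <- split(ord, ceiling(seq_along(ord) / bs))
    ep_loss <- 0
    for (bidx in batches) {
      Xb <- X[bidx, , , drop = FALSE]
      Tb <- targets_sc[bidx, , drop = FALSE]
      fw <- forward_batch(state$params, Xb, Ahat, config$baseline_mode, cache = TRUE)
      loss <- mean((fw$Y - Tb)^2)
      if (!is.finite(loss)) {
        abort_numeric(sprintf("training diverged (non-finite loss) at epoch %d", ep))
      }
      ep_loss <- ep_loss + loss * length(bidx)
      grads <- backward_batch(state$params, fw, Xb, Ahat, Tb, config$baseline_mode)
      step <- step + 1L
      state <- adam_step(state$params, grads, state, config$learning_rate, step)
    }
    # losses reported in original target units (N.m squared)
    loss_tr[ep] <- ep_loss / n_train * scaler$target_sd^2
    if (length(val_idx)) {
      Yv <- forward_batch(state$params, X[val_idx, , , drop = FALSE], Ahat,
                          config$baseline_mode)$Y
      loss_val[ep] <- mean((Yv - targets_sc[val_idx, , drop = FALSE])^2) *
        scaler$target_sd^2
    } else {
      loss_val[ep] <- NA_real_
    }
  }
  model <- structure(
    list(
      params = state$params,
      config = config,
      scaler = scaler,
      format_version = "serveload-model-1"
    ),
    class = "serveload_model"
  )
  structure(
    list(
      model = model,
      loss_history = data.frame(
        epoch = seq_len(config$epochs),
        train = loss_tr,
        validation = loss_val
      ),
      best_epoch = if (all(is.na(loss_val))) which.min(loss_tr) else which.min(loss_val),
      config = config
    ),
    class = "train_state"
  )
}

#' Predict moment curves for serve graphs
#'
#' @param object A `serveload_model`.
#' @param graphs A single `serve_graph` or a list of them.
#' @param ... Unused.
#' @return A matrix (n_graphs x 101) of predicted resultant-moment curves.
#' @export
predict.serveload_model <- function(object, graphs, ...) {
  if (inherits(graphs, "serve_graph")) graphs <- list(graphs)
  arr <- graphs_to_arrays(graphs)
  X <- apply_scaler(arr$X, object$scaler)
  Ahat <- normalized_adjacency(graphs[[1]]$edge_index, N_NODES)
  Y <- forward_batch(object$params, X, Ahat, object$config$baseline_mode)$Y
  Y * object$scaler$target_sd + object$scaler$target_mean
}

#' Single-graph forward pass with cached intermediates
#'
#' Runs the model on one graph and keeps every intermediate quantity
#' (standardized inputs, aggregated features, GRU gates and hidden states)
#' for the relevance-propagation engine.
#'
#' @param model A `serveload_model`.
#' @param graph A `serve_graph`.
#' @return List with `y` (length-101 prediction) and the caches.
#' @export
forward_cached <- function(model, graph) {
  stopifnot(inherits(model, "serveload_model"), inherits(graph, "serve_graph"))
  arr <- graphs_to_arrays(list(graph))
  X <- apply_scaler(arr$X, model$scaler)
  Ahat <- normalized_adjacency(graph$edge_index, N_NODES)
  fw <- forward_batch(model$params, X, Ahat, model$config$baseline_mode, cache = TRUE)
  list(
    y = as.numeric(fw$Y[1, ]),
    X0 = matrix(X[1, , ], N_NODES, 6),
    gcn = lapply(fw$gcn, function(cc) list(
      X_in = matrix(cc$X_in[1, , ], N_NODES),
      AX = matrix(cc$AX[1, , ], N_NODES),
      H_out = matrix(cc$H_out[1, , ], N_NODES)
    )),
    Xg = matrix(fw$Xg[1, , ], N_NODES),
    gates = lapply(fw$gates, function(a) matrix(a[1, , ], N_NODES)),
    Ahat = Ahat
  )
}

#' Save / load a model checkpoint
#'
#' Single-file JSON checkpoint holding the weights, configuration, feature
#' scaler and a format-version string.
#'
#' @param model A `serveload_model`.
#' @param path Checkpoint path (.json).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "serveload_model"))
  payload <- list(
    format_version = model$format_version,
    config = unclass(model$config),
    scaler = model$scaler,
    params = model$params
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  if (!identical(payload$format_version, "serveload-model-1")) {
    abort_data("unrecognized checkpoint format version")
  }
  cfg <- payload$config
  config <- model_config(
    n_gcn_layers = cfg$n_gcn_layers, gcn_width = cfg$gcn_width,
    gru_width = cfg$gru_width, learning_rate = cfg$learning_rate,
    epochs = cfg$epochs, batch_size = cfg$batch_size,
    loss_name = cfg$loss_name, seed = cfg$seed,
    baseline_mode = cfg$baseline_mode, zscore = cfg$zscore
  )
  p <- payload$params
  fix <- function(m) if (is.null(dim(m))) matrix(m, nrow = length(m)) else m
  params <- list(
    gcn = lapply(p$gcn, function(layer) {
      list(W = fix(layer$W), b = as.numeric(layer$b))
    }),
    gru = list(),
    head = list(w = fix(p$head$w), b = as.numeric(p$head$b))
  )
  for (nm in c("Wxr", "Wxz", "Wxc", "Whr", "Whz", "Whc")) {
    params$gru[[nm]] <- fix(p$gru[[nm]])
  }
  for (nm in c("br", "bz", "bc")) params$gru[[nm]] <- as.numeric(p$gru[[nm]])
  structure(
    list(
      params = params, config = config,
      scaler = list(mean = as.numeric(payload$scaler$mean),
                    sd = as.numeric(payload$scaler$sd),
                    target_mean = as.numeric(payload$scaler$target_mean %||% 0),
                    target_sd = as.numeric(payload$scaler$target_sd %||% 1)),
      format_version = payload$format_version
    ),
    class = "serveload_model"
  )
}
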