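# Layer-wise relevance propagation through the GNN-GRU model.
#
# Rules: epsilon rule for every affine map (head, GRU candidate map, graph
# convolutions treated as the dense map (Ahat (x) W)); gated-signal rule for
# the GRU step (the hidden state is the additive combination
# h_t = (1-z) h_{t-1} + z c_t, relevance splits proportionally between the
# carry and candidate terms, gates themselves receive none); element-wise
# nonlinearities (tanh, ReLU) pass relevance through unchanged, so inactive
# ReLU units — whose activation is zero — automatically receive zero.

eps_stab <- function(z, epsilon) {
  z + epsilon * ifelse(z >= 0, 1, -1)
}

#' Epsilon-rule relevance propagation through an affine map
#'
#' For `z_j = sum_i x_i W_ij + b_j`, redistributes the output relevance as
#' `R_in[i] = sum_j x_i W_ij / (z_j + eps * sign(z_j)) * R_out[j]`. With
#' `b = 0` and `epsilon = 0` the rule conserves total relevance exactly.
#'
#' @param x Input vector (length d).
#' @param W Weight matrix (d x k).
#' @param b Bias vector (length k).
#' @param R_out Output relevance (length k).
#' @param epsilon Stabilizer (>= 0).
#' @return Input relevance vector (length d).
#' @export
lrp_linear <- function(x, W, b = numeric(ncol(W)), R_out, epsilon = 1e-6) {
  if (length(x) != nrow(W) || length(R_out) != ncol(W) || length(b) != ncol(W)) {
    abort_argument("lrp_linear: inconsistent shapes")
  }
  if (epsilon < 0) abort_argument("epsilon must be nonnegative")
  z <- as.numeric(crossprod(W, x)) + b
  if (epsilon == 0 && any(z == 0 & R_out != 0)) {
    abort_numeric("lrp_linear: zero pre-activation with nonzero relevance and epsilon = 0")
  }
  s <- ifelse(z == 0 & R_out == 0, 0, R_out / eps_stab(z, epsilon))
  x * as.numeric(W %*% s)
}

#' Gated-signal relevance propagation through one GRU step
#'
#' Splits the relevance of `h_t = (1-z) * h_prev + z * c` per unit between
#' the carry term and the candidate term in proportion to each term's
#' epsilon-stabilized contribution; the gates act as constants and receive
#' no relevance. The candidate share passes unchanged through the tanh and
#' is redistributed by the epsilon rule over the candidate's affine inputs
#' `[x_t, r * h_prev]`, the latter share assigned to `h_prev`.
#'
#' @param cache List with the cached forward quantities of the step:
#'   `x` (GRU input), `h_prev`, `r`, `z`, `c` (candidate, post-tanh).
#' @param weights GRU parameter list (needs `Wxc`, `Whc`, `bc`).
#' @param R_ht Relevance of `h_t` (length = hidden width).
#' @param epsilon Stabilizer.
#' @return List with `R_h_prev` and `R_x`.
#' @export
lrp_gru_step <- function(cache, weights, R_ht, epsilon = 1e-6) {
  need <- c("x", "h_prev", "r", "z", "c")
  if (!all(need %in% names(cache))) {
    abort_state("lrp_gru_step: missing cached forward quantities")
  }
  carry <- (1 - cache$z) * cache$h_prev
  cand <- cache$z * cache$c
  tot <- carry + cand
  share <- ifelse(tot == 0 & R_ht == 0, 0, R_ht / eps_stab(tot, epsilon))
  if (epsilon == 0 && any(tot == 0 & R_ht != 0)) {
    abort_numeric("lrp_gru_step: zero denominator with nonzero relevance and epsilon = 0")
  }
  R_carry <- carry * share
  R_cand <- cand * share
  # candidate affine map over the concatenated input [x, r * h_prev]
  xin <- c(cache$x, cache$r * cache$h_prev)
  Wcat <- rbind(weights$Wxc, weights$Whc)
  R_split <- lrp_linear(xin, Wcat, weights$bc, R_cand, epsilon)
  dx <- length(cache$x)
  list(
    R_h_prev = R_carry + R_split[(dx + 1):length(R_split)],
    R_x = R_split[seq_len(dx)]
  )
}

#' Epsilon-rule relevance propagation through a graph convolution
#'
#' Treats the convolution `Z = Ahat X W + b` as the dense linear map
#' `(Ahat (x) W)` from the flattened input to the flattened output and
#' applies the epsilon rule, so relevance is redistributed across both
#' neighbouring nodes and input features:
#' `R_in[u,i] = X[u,i] * (Ahat' S W')[u,i]` with
#' `S = R_out / (Z + eps sign Z)`.
#'
#' @param graph A `serve_graph` (or any list with `edge_index` and
#'   `node_features` giving the node count).
#' @param X Cached layer input (n x d).
#' @param W,b Layer parameters.
#' @param R_out Output relevance (n x width).
#' @param epsilon Stabilizer.
#' @return Input relevance (n x d).
#' @export
lrp_gcn <- function(graph, X, W, b = numeric(ncol(W)), R_out, epsilon = 1e-6) {
  X <- as.matrix(X)
  R_out <- as.matrix(R_out)
  n <- nrow(X)
  if (nrow(R_out) != n || ncol(R_out) != ncol(W) || nrow(W) != ncol(X)) {
    abort_argument("lrp_gcn: inconsistent shapes")
  }
  Ahat <- normalized_adjacency(graph$edge_index, n)
  Z <- addb(Ahat %*% X %*% W, b)
  if (epsilon == 0 && any(Z == 0 & R_out != 0)) {
    abort_numeric("lrp_gcn: zero pre-activation with nonzero relevance and epsilon = 0")
  }
  S <- ifelse(Z == 0 & R_out == 0, 0, R_out / eps_stab(Z, epsilon))
  X * (t(Ahat) %*% S %*% t(W))
}

#' Explain a prediction with layer-wise relevance propagation
#'
#' Initializes relevance at the 101 output scalars (by default each node is
#' seeded with its predicted value, giving signed magnitude-weighted
#' attributions), propagates it back through the affine head, the
#' time-unrolled GRU (accumulating the per-step input relevance), and the
#' graph-convolution stack, down to the 101 x 6 standardized input
#' features.
#'
#' @param model A trained `serveload_model`.
#' @param graph A `serve_graph`.
#' @param epsilon Stabilizer for every epsilon-rule application
#'   (default 1e-6).
#' @param output_weights Length-101 initial output relevance, or NULL to
#'   seed each node with its predicted value, or `"uniform"` for all-ones
#'   seeding.
#' @return A `relevance_map`: list with `raw` (101 x 6 signed relevance),
#'   `normalized` (101 x 6 in [0, 1]; absolute relevance, global min-max),
#'   `epsilon`, `explained_output` (description of the seeding), and the
#'   prediction `y`.
#' @export
explain <- function(model, graph, epsilon = 1e-6, output_weights = NULL) {
  fw <- forward_cached(model, graph)
  nh <- ncol(fw$gates$h)
  if (is.null(output_weights)) {
    R_y <- fw$y
    seeding <- "predicted value at each of the 101 output nodes"
  } else if (identical(output_weights, "uniform")) {
    R_y <- rep(1, N_NODES)
    seeding <- "uniform unit relevance at each of the 101 output nodes"
  } else {
    if (length(output_weights) != N_NODES) {
      abort_argument("output_weights must have length 101")
    }
    R_y <- as.numeric(output_weights)
    seeding <- "user-supplied output relevance"
  }

  # head: relevance of h_t from the explained scalar at node t
  w_head <- model$params$head$w
  b_head <- model$params$head$b
  R_head <- matrix(0, N_NODES, nh)
  for (t in seq_len(N_NODES)) {
    R_head[t, ] <- lrp_linear(fw$gates$h[t, ], w_head, b_head, R_y[t], epsilon)
  }

  # unrolled GRU, from the last step backwards
  R_x_all <- matrix(0, N_NODES, ncol(fw$Xg))
  R_h <- numeric(nh)
  for (t in N_NODES:1) {
    R_h <- R_h + R_head[t, ]
    cache <- list(
      x = fw$Xg[t, ],
      h_prev = if (t > 1) fw$gates$h[t - 1, ] else numeric(nh),
      r = fw$gates$r[t, ],
      z = fw$gates$z[t, ],
      c = fw$gates$c[t, ]
    )
    step <- lrp_gru_step(cache, model$params$gru, R_h, epsilon)
    R_x_all[t, ] <- step$R_x
    R_h <- step$R_h_prev
  }

  # graph-convolution stack
  R <- R_x_all
  if (!model$config$baseline_mode) {
    for (l in length(model$params$gcn):1) {
      if (any(!is.finite(R))) {
        abort_numeric(sprintf("non-finite relevance entering GCN layer %d", l))
      }
      R <- lrp_gcn(graph, fw$gcn[[l]]$X_in,
                   model$params$gcn[[l]]$W, model$params$gcn[[l]]$b,
                   R, epsilon)
    }
  }
  if (any(!is.finite(R))) abort_numeric("non-finite relevance at the input layer")
  colnames(R) <- JOINT_NAMES
  structure(
    list(
      raw = R,
      normalized = minmax_normalize(abs(R), "global"),
      epsilon = epsilon,
      explained_output = seeding,
      y = fw$y
    ),
    class = "relevance_map"
  )
}

minmax_normalize <- function(M, method = c("global", "per_feature")) {
  method <- match.arg(method)
  norm1 <- function(A) {
    rng <- range(A)
    if (diff(rng) == 0) {
      A * 0 # constant map: all zeros by convention
    } else {
      (A - rng[1]) / diff(rng)
    }
  }
  if (method == "global") norm1(M) else apply(M, 2, norm1)
}

#' Aggregate relevance maps into normalized contribution curves
#'
#' Takes absolute raw relevance, averages across maps (typically the test
#' trials), then min-max normalizes to [0, 1] — over the whole 101 x 6
#' array (`"global"`, the default) or per feature column
#' (`"per_feature"`). A constant aggregate maps to all zeros by convention.
#'
#' @param maps List of `relevance_map` objects (or bare 101 x 6 matrices).
#' @param method Normalization scope.
#' @return 101 x 6 matrix of contribution curves in [0, 1].
#' @export
aggregate_and_normalize <- function(maps, method = c("global", "per_feature")) {
  method <- match.arg(method)
  if (length(maps) == 0) abort_argument("need at least one relevance map")
  mats <- lapply(maps, function(m) {
    raw <- if (inherits(m, "relevance_map")) m$raw else as.matrix(m)
    if (!all(dim(raw) == c(N_NODES, 6))) {
      abort_argument("all relevance maps must be 101 x 6")
    }
    abs(raw)
  })
  avg <- Reduce(`+`, mats) / length(mats)
  out <- minmax_normalize(avg, method)
  colnames(out) <- JOINT_NAMES
  out
}

#' Phase-averaged contribution summary
#'
#' Mean normalized contribution of each joint within each serve phase.
#'
#' @param contributions 101 x 6 contribution matrix.
#' @param phase_annotation Length-101 factor with levels PP/FP/LP.
#' @return 3 x 6 matrix (phases x joints).
#' @export
phase_contribution_summary <- function(contributions, phase_annotation) {
  stopifnot(length(phase_annotation) == N_NODES)
  out <- t(vapply(
    PHASE_NAMES,
    function(p) colMeans(contributions[phase_annotation == p, , drop = FALSE]),
    numeric(6)
  ))
  dimnames(out) <- list(PHASE_NAMES, JOINT_NAMES)
  out
}

#' Write contribution curves as CSV with a JSON sidecar
#'
#' 101 rows x 7 columns (`node_index` + six joints), plus
#' `<path>.meta.json` recording epsilon, relevance seeding and the
#' normalization method.
#'
#' @param contributions 101 x 6 contribution matrix.
#' @param path Output CSV path.
#' @param epsilon,seeding,method Metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_contributions_csv <- function(contributions, path, epsilon = 1e-6,
                                    seeding = "predicted", method = "global") {
  df <- data.frame(node_index = 0:(N_NODES - 1), contributions)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], format_sig)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(epsilon = epsilon, output_seeding = seeding, normalization = method),
    paste0(path, ".meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
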