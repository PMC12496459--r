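# Particle swarm optimization for hyperparameter search. Standard
# constricted PSO (inertia + cognitive + social velocity terms) with bound
# clamping; dimensions may be continuous, log-scaled, or snapped to a
# discrete choice set when evaluated.

#' Particle swarm optimization
#'
#' Minimizes `objective` over a box. Velocities follow the classic update
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with inertia
#' `w = 0.7298` and `c1 = c2 = 1.49618` (Clerc constriction values);
#' positions are clamped to the bounds after each move, so every evaluated
#' point stays inside the box. With `iterations = 0` the seeded initial
#' swarm is evaluated and the best initial particle returned.
#'
#' @param objective Function taking a numeric vector, returning a scalar.
#' @param lower,upper Bound vectors (equal length, finite, lower < upper).
#' @param swarm_size Number of particles (default 10).
#' @param iterations Velocity/position updates after the initial
#'   evaluation (default 10).
#' @param seed Integer seed.
#' @return List with `best_x`, `best_value`, and `history` (best value per
#'   iteration, length `iterations + 1`).
#' @export
pso_optimize <- function(objective, lower, upper, swarm_size = 10,
                         iterations = 10, seed = 1L) {
  d <- length(lower)
  if (d == 0 || length(upper) != d || any(!is.finite(c(lower, upper))) ||
      any(upper <= lower)) {
    abort_argument("search space must be a non-empty finite box with lower < upper")
  }
  if (!is_count(swarm_size)) abort_argument("swarm_size must be a positive integer")
  w <- 0.7298
  c1 <- c2 <- 1.49618
  with_seed(derive_seed(seed, 41L), {
    X <- matrix(0, swarm_size, d)
    for (j in seq_len(d)) X[, j] <- runif(swarm_size, lower[j], upper[j])
    V <- matrix(0, swarm_size, d)
    for (j in seq_len(d)) {
      span <- upper[j] - lower[j]
      V[, j] <- runif(swarm_size, -span, span) / 10
    }
    fvals <- apply(X, 1, objective)
    pbest_x <- X
    pbest_f <- fvals
    gi <- which.min(pbest_f)
    gbest_x <- pbest_x[gi, ]
    gbest_f <- pbest_f[gi]
    history <- numeric(iterations + 1)
    history[1] <- gbest_f
    if (iterations > 0) {
      for (it in seq_len(iterations)) {
        r1 <- matrix(runif(swarm_size * d), swarm_size, d)
        r2 <- matrix(runif(swarm_size * d), swarm_size, d)
        V <- w * V +
          c1 * r1 * (pbest_x - X) +
          c2 * r2 * (matrix(gbest_x, swarm_size, d, byrow = TRUE) - X)
        X <- X + V
        for (j in seq_len(d)) X[, j] <- pmin(pmax(X[, j], lower[j]), upper[j])
        fvals <- apply(X, 1, objective)
        improved <- fvals < pbest_f
        pbest_x[improved, ] <- X[improved, , drop = FALSE]
        pbest_f[improved] <- fvals[improved]
        gi <- which.min(pbest_f)
        if (pbest_f[gi] < gbest_f) {
          gbest_f <- pbest_f[gi]
          gbest_x <- pbest_x[gi, ]
        }
        history[it + 1] <- gbest_f
      }
    }
    list(best_x = gbest_x, best_value = gbest_f, history = history)
  })
}

#' Default hyperparameter search space
#'
#' Learning rate on a log10 scale in `[1e-4, 1e-2]`, layer widths in
#' `{16, 32, 64, 128}`, and 1-3 graph-convolution layers.
#'
#' @return A search-space list understood by [pso_tune()].
#' @export
default_search_space <- function() {
  list(
    learning_rate = list(type = "log", lower = 1e-4, upper = 1e-2),
    gcn_width = list(type = "choice", values = c(16, 32, 64, 128)),
    gru_width = list(type = "choice", values = c(16, 32, 64, 128)),
    n_gcn_layers = list(type = "choice", values = 1:3)
  )
}

decode_particle <- function(x, space) {
  out <- list()
  for (j in seq_along(space)) {
    s <- space[[j]]
    out[[names(space)[j]]] <- switch(s$type,
      continuous = x[j],
      log = 10^x[j],
      choice = s$values[pmin(pmax(ceiling(x[j]), 1), length(s$values))],
      abort_argument(sprintf("unknown search-space type '%s'", s$type))
    )
  }
  out
}

space_bounds <- function(space) {
  lower <- upper <- numeric(length(space))
  for (j in seq_along(space)) {
    s <- space[[j]]
    if (s$type == "choice") {
      lower[j] <- 1e-9
      upper[j] <- length(s$values)
    } else if (s$type == "log") {
      lower[j] <- log10(s$lower)
      upper[j] <- log10(s$upper)
    } else {
      lower[j] <- s$lower
      upper[j] <- s$upper
    }
  }
  list(lower = lower, upper = upper)
}

#' PSO hyperparameter search over model configurations
#'
#' Runs [pso_optimize()] over a typed search space and returns the best
#' decoded configuration. `objective` receives a named list of decoded
#' hyperparameter values (e.g. `learning_rate`, `gcn_width`) and must
#' return the validation objective to minimize.
#'
#' @param search_space Named list of dimensions, each
#'   `list(type = "continuous"|"log"|"choice", ...)` with `lower`/`upper`
#'   or `values`. See [default_search_space()].
#' @param objective Function of a decoded configuration list.
#' @param swarm_size,iterations,seed Passed to [pso_optimize()].
#' @return List with `best_config` (decoded named list), `best_value`,
#'   `history`.
#' @export
pso_tune <- function(search_space, objective, swarm_size = 10,
                     iterations = 10, seed = 1L) {
  if (length(search_space) == 0) abort_argument("empty search space")
  bounds <- space_bounds(search_space)
  wrapped <- function(x) objective(decode_particle(x, search_space))
  res <- pso_optimize(wrapped, bounds$lower, bounds$upper,
                      swarm_size = swarm_size, iterations = iterations,
                      seed = seed)
  list(
    best_config = decode_particle(res$best_x, search_space),
    best_value = res$best_value,
    history = res$history
  )
}
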