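# Internal helpers shared across modules.

# Canonical joint/feature order. Rows of the 6 x T angle matrix, columns of
# the 101 x 6 node-feature matrix, and all relevance maps use this order.
JOINT_NAMES <- c("l_ankle", "l_knee", "l_hip", "r_ankle", "r_knee", "r_hip")
PHASE_NAMES <- c("PP", "FP", "LP")
N_NODES <- 101L

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_serveload <- function(msg, class) {
  stop(structure(
    class = c(class, "serveload_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_argument <- function(msg) stop_serveload(msg, "serveload_argument_error")
abort_data <- function(msg) stop_serveload(msg, "serveload_data_error")
abort_config <- function(msg) stop_serveload(msg, "serveload_config_error")
abort_numeric <- function(msg) stop_serveload(msg, "serveload_numeric_error")
abort_state <- function(msg) stop_serveload(msg, "serveload_state_error")

# Derive a child RNG seed (< 2^31) from a base seed and integer tags.
# Simple splitmix-style integer mixing in double precision; keeps per-trial
# streams independent of iteration order so simulate_trial(config, i, j) is
# reproducible in isolation.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  h <- (seed %% 2147483647) + 1
  mult <- c(2654435761, 2246822519, 3266489917, 668265263, 374761393)
  for (k in seq_along(tags)) {
    m <- mult[((k - 1) %% length(mult)) + 1]
    h <- (h * 31 + (tags[k] %% 2147483647) * m) %% 2147483629
  }
  as.integer(h %% 2147483587) + 1L
}

# Evaluate expr with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# Format numbers for CSV output at a fixed significant precision so that
# write -> read round-trips are stable across platforms.
format_sig <- function(x, digits = 12) {
  formatC(x, digits = digits, format = "g")
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}
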