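# Signal chain: zero-phase Butterworth low-pass, 101-point time
# normalization, resultant joint moment, 8:1:1 cross-validation splits, and
# assembly of the 6 x 101 / 1 x 101 model matrices.

#' Digital Butterworth low-pass coefficients
#'
#' Designs an order-`n` digital Butterworth low-pass filter by the bilinear
#' transform with frequency pre-warping (the classic butter() design).
#'
#' @param order Filter order (default 4).
#' @param cutoff Cutoff frequency in Hz (-3 dB point of a single pass).
#' @param fs Sampling rate in Hz.
#' @return List with numerator `b` and denominator `a` coefficient vectors
#'   (length `order + 1`), normalized so `a[1] = 1` and DC gain is 1.
#' @export
butter_lowpass <- function(order = 4, cutoff, fs) {
  if (cutoff <= 0 || cutoff >= fs / 2) {
    abort_argument("cutoff must lie strictly between 0 and the Nyquist frequency")
  }
  if (!is_count(order)) abort_argument("order must be a positive integer")
  # analog prototype poles on the unit circle, left half plane
  k <- seq_len(order)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  p_analog <- complex(modulus = 1, argument = theta)
  warped <- 2 * fs * tan(pi * cutoff / fs) # pre-warped analog cutoff (rad/s)
  p <- warped * p_analog
  # bilinear transform: s -> 2*fs*(z-1)/(z+1)
  pz <- (2 * fs + p) / (2 * fs - p)
  # order zeros at z = -1
  poly_from_roots <- function(r) {
    coef <- 1 + 0i
    for (ri in r) coef <- c(coef, 0) - c(0, coef * ri)
    coef
  }
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  a <- Re(poly_from_roots(pz))
  a <- a / a[1]
  b <- b * (sum(a) / sum(b)) # unit DC gain
  list(b = b, a = a)
}

# Direct-form II transposed IIR filter with optional initial state.
iir_filter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  z <- if (is.null(zi)) rep(0, n - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 2) {
      z[1:(n - 2)] <- b[2:(n - 1)] * xi + z[2:(n - 1)] - a[2:(n - 1)] * yi
    }
    z[n - 1] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

# Steady-state initial filter state for a unit-amplitude constant input
# (same construction as scipy.signal.lfilter_zi): removes start-up
# transients when scaled by the first padded sample.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  comp <- matrix(0, n - 1, n - 1) # companion matrix of a
  comp[1, ] <- -a[2:n] / a[1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  iminusa <- diag(n - 1) - t(comp)
  bsum <- b[2:n] - a[2:n] * b[1]
  solve(iminusa, bsum)
}

#' Zero-phase low-pass filter a series
#'
#' Applies a Butterworth low-pass filter forward and backward (zero phase,
#' so the effective magnitude response is the squared single-pass response),
#' with odd-reflection edge padding and steady-state initial conditions to
#' suppress end transients. This is the conventional smoothing applied to
#' motion-capture kinematics and kinetics before time normalization.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz (default 10).
#' @param order Filter order (default 4).
#' @param zero_phase Apply forward-backward filtering (default TRUE). When
#'   FALSE a single causal pass is used.
#' @return Filtered series of identical length.
#' @export
#' @examples
#' lowpass_filter(rep(2, 50), fs = 200) # constant in, constant out
lowpass_filter <- function(x, fs, cutoff = 10, order = 4, zero_phase = TRUE) {
  if (any(!is.finite(x))) abort_data("series contains NaN/Inf; cannot filter")
  if (length(x) <= 3 * order) {
    abort_argument("series too short for the requested filter order")
  }
  coefs <- butter_lowpass(order, cutoff, fs)
  b <- coefs$b
  a <- coefs$a
  zi <- lfilter_zi(b, a)
  pad <- min(3 * (max(length(a), length(b))), length(x) - 1)
  # odd reflection about the endpoints
  ext <- c(
    2 * x[1] - x[(pad + 1):2],
    x,
    2 * x[length(x)] - x[(length(x) - 1):(length(x) - pad)]
  )
  y <- iir_filter(b, a, ext, zi * ext[1])
  if (zero_phase) {
    y <- rev(y)
    y <- iir_filter(b, a, y, zi * y[1])
    y <- rev(y)
  }
  y[(pad + 1):(pad + length(x))]
}

#' Resample a series onto the 101-point cycle grid
#'
#' Time-normalizes a movement series to `n` points spanning 0-100% of the
#' cycle. Monotone cubic (Fritsch-Carlson) interpolation is the default;
#' endpoints are preserved exactly.
#'
#' @param x Numeric series of length >= 2.
#' @param n Output length (default 101).
#' @param method `"monotone_cubic"` (default) or `"linear"`.
#' @return Series of length `n`.
#' @export
time_normalize <- function(x, n = N_NODES, method = c("monotone_cubic", "linear")) {
  method <- match.arg(method)
  m <- length(x)
  if (m < 2) abort_data("time_normalize needs at least 2 samples")
  if (any(!is.finite(x))) abort_data("series contains NaN/Inf; cannot normalize")
  if (m == n) return(as.numeric(x))
  grid_in <- seq(0, 1, length.out = m)
  grid_out <- seq(0, 1, length.out = n)
  if (method == "linear") {
    approx(grid_in, x, xout = grid_out)$y
  } else {
    splinefun(grid_in, x, method = "monoH.FC")(grid_out)
  }
}

#' Resultant joint moment
#'
#' Pointwise Euclidean norm of the three joint-moment components
#' (sagittal, frontal, transverse): `sqrt(mx^2 + my^2 + mz^2)`. The scalar
#' summary of net joint load used as the prediction target.
#'
#' @param mx,my,mz Equal-length numeric series (N.m).
#' @return Nonnegative series of the same length.
#' @export
#' @examples
#' resultant_moment(3, 4, 0) # 5
resultant_moment <- function(mx, my, mz) {
  if (length(mx) != length(my) || length(mx) != length(mz)) {
    abort_data("moment components must have equal length")
  }
  if (any(!is.finite(c(mx, my, mz)))) abort_data("moment components contain NaN/Inf")
  sqrt(mx^2 + my^2 + mz^2)
}

#' 8:1:1 rotating cross-validation split
#'
#' Splits `n_trials` indices into train/validation/test at the 8:1:1 ratio.
#' Sizes follow the rule test = validation = `floor(n/10)`, train =
#' remainder, so 360 trials give 288/36/36. The trial order is shuffled once
#' per `seed`; the ten `fold_id`s then rotate which shuffled tenth serves as
#' test (and the following tenth as validation), so over fold_ids 0..9 every
#' trial appears exactly once as test when `n` is divisible by 10. When a
#' `groups` vector is supplied (e.g. participant ids) whole groups are
#' rotated instead, keeping all of a participant's trials in one partition;
#' with equal-sized groups whose count is divisible by 10 the 8:1:1 trial
#' arithmetic is preserved exactly.
#'
#' @param n_trials Number of trials (>= 10).
#' @param ratio Split ratio, fixed at `c(8, 1, 1)`.
#' @param fold_id Integer 0..9 selecting the rotation.
#' @param seed Integer seed for the shuffle.
#' @param groups Optional length-`n_trials` grouping vector for
#'   participant-level splitting.
#' @return A `split_indices` object: list with integer vectors `train`,
#'   `validation`, `test`, plus `fold_id` and `seed`.
#' @export
split_dataset <- function(n_trials, ratio = c(8, 1, 1), fold_id = 0, seed = 1,
                          groups = NULL) {
  if (!is_count(n_trials) || n_trials < 10) {
    abort_argument("n_trials must be an integer >= 10")
  }
  if (!identical(as.numeric(ratio), c(8, 1, 1))) {
    abort_argument("only the 8:1:1 ratio is supported")
  }
  if (!(fold_id %in% 0:9)) abort_argument("fold_id must be in 0..9")
  take_block <- function(ord, start, len) {
    # contiguous block of the shuffled order, wrapping around
    idx <- ((start - 1 + seq_len(len) - 1) %% length(ord)) + 1
    ord[idx]
  }
  if (is.null(groups)) {
    ord <- with_seed(derive_seed(seed, 91L), sample.int(n_trials))
    m <- floor(n_trials / 10)
    test <- take_block(ord, fold_id * m + 1, m)
    validation <- take_block(ord, ((fold_id + 1) %% 10) * m + 1, m)
    train <- setdiff(ord, c(test, validation))
  } else {
    if (length(groups) != n_trials) {
      abort_argument("groups must have one entry per trial")
    }
    gl <- unique(groups)
    ng <- length(gl)
    if (ng < 10) abort_argument("participant-grouped splitting needs >= 10 groups")
    gord <- with_seed(derive_seed(seed, 92L), sample(gl))
    mg <- floor(ng / 10)
    gtest <- take_block(gord, fold_id * mg + 1, mg)
    gval <- take_block(gord, ((fold_id + 1) %% 10) * mg + 1, mg)
    test <- which(groups %in% gtest)
    validation <- which(groups %in% gval)
    train <- setdiff(seq_len(n_trials), c(test, validation))
  }
  structure(
    list(
      train = sort(as.integer(train)),
      validation = sort(as.integer(validation)),
      test = sort(as.integer(test)),
      fold_id = as.integer(fold_id),
      seed = as.integer(seed)
    ),
    class = "split_indices"
  )
}

#' Assemble the 6 x 101 / 1 x 101 model matrices for one trial
#'
#' Runs the full signal chain on a raw serve trial: zero-phase Butterworth
#' low-pass on every angle and moment-component row at the trial's native
#' sampling rate, 101-point time normalization of each filtered row, then
#' the resultant moment of the three normalized components. Phase
#' boundaries are mapped onto the normalized grid by nearest-index rounding
#' and expanded into a per-node PP/FP/LP annotation.
#'
#' @param trial A `serve_trial`.
#' @param cutoff,order Filter parameters (defaults 10 Hz, order 4).
#' @param interp Interpolation method passed to [time_normalize()].
#' @return A `normalized_trial` object: list with `angles` (6 x 101),
#'   `resultant_moment` (length 101, nonnegative), `phase_annotation`
#'   (length-101 factor with levels PP/FP/LP), `phase_nodes` (last node of
#'   PP and FP on the 0..100 grid), and the trial identifiers.
#' @export
assemble_matrices <- function(trial, cutoff = 10, order = 4,
                              interp = "monotone_cubic") {
  stopifnot(inherits(trial, "serve_trial"))
  n_raw <- ncol(trial$angles_raw)
  fs <- trial$sampling_rate_hz
  chain <- function(row) {
    time_normalize(lowpass_filter(row, fs, cutoff, order), N_NODES, interp)
  }
  angles <- t(apply(trial$angles_raw, 1, chain))
  rownames(angles) <- JOINT_NAMES
  comps <- t(apply(trial$moment_components_raw, 1, chain))
  res <- resultant_moment(comps[1, ], comps[2, ], comps[3, ])
  # nearest normalized node (0..100) for each phase boundary
  pb <- round((trial$phase_boundaries - 1) / (n_raw - 1) * (N_NODES - 1))
  pb <- pmin(pmax(pb, c(1, 2)), c(N_NODES - 3, N_NODES - 2))
  annotation <- factor(
    rep(PHASE_NAMES, c(pb[1] + 1, pb[2] - pb[1], N_NODES - 1 - pb[2])),
    levels = PHASE_NAMES
  )
  structure(
    list(
      angles = angles,
      resultant_moment = res,
      phase_annotation = annotation,
      phase_nodes = as.integer(pb),
      participant_id = trial$participant_id,
      trial_id = trial$trial_id
    ),
    class = "normalized_trial"
  )
}

#' Write / read a normalized trial as CSV
#'
#' 101 rows with columns `node_index` (0..100), the six joint angles, the
#' resultant moment, and the phase label; values at 12 significant digits so
#' write -> read round-trips reproduce the numbers to that precision.
#'
#' @param ntrial A `normalized_trial`.
#' @param path Output CSV path.
#' @return `write_normalized_csv` returns `path` invisibly;
#'   `read_normalized_csv` returns a `normalized_trial`.
#' @export
write_normalized_csv <- function(ntrial, path) {
  stopifnot(inherits(ntrial, "normalized_trial"))
  df <- data.frame(
    node_index = 0:(N_NODES - 1),
    t(ntrial$angles),
    resultant_moment = ntrial$resultant_moment,
    phase = as.character(ntrial$phase_annotation)
  )
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], format_sig)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_normalized_csv
#' @export
read_normalized_csv <- function(path) {
  df <- read.csv(path)
  need <- c("node_index", JOINT_NAMES, "resultant_moment", "phase")
  if (!all(need %in% names(df)) || nrow(df) != N_NODES) {
    abort_data(sprintf("%s is not a valid normalized-trial CSV", path))
  }
  angles <- t(as.matrix(df[JOINT_NAMES]))
  rownames(angles) <- JOINT_NAMES
  annotation <- factor(df$phase, levels = PHASE_NAMES)
  structure(
    list(
      angles = angles,
      resultant_moment = df$resultant_moment,
      phase_annotation = annotation,
      phase_nodes = c(
        max(which(annotation == "PP")) - 1L,
        max(which(annotation != "LP")) - 1L
      ),
      participant_id = NA_integer_,
      trial_id = NA_integer_
    ),
    class = "normalized_trial"
  )
}
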