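# Synthetic serve simulator.
#
# Emulates the data the prediction model assumes: per-trial bilateral
# sagittal-plane joint-angle curves over a three-phase serve cycle
# (Preparation / Flight / Landing), plus three joint-moment components
# produced by a known per-phase generative mapping from angles and angular
# velocities. Because the generative weights are known, relevance-recovery
# tests have a ground truth.

# Relative per-phase excursion of each joint (rows follow JOINT_NAMES,
# columns PP/FP/LP). Fixed part of the stated world: knees flex deeply in
# preparation and landing, ankles and hips dominate the flight/propulsion
# phase. Multiplied by the per-joint amplitude from the config.
PHASE_SHAPE <- matrix(
  c(
    0.4, 1.0, 0.8, # l_ankle
    1.0, 0.6, 0.9, # l_knee
    0.8, 1.0, 0.5, # l_hip
    0.5, 1.0, 0.3, # r_ankle
    0.9, 0.7, 0.4, # r_knee
    0.7, 1.0, 0.3  # r_hip
  ),
  nrow = 6, byrow = TRUE,
  dimnames = list(JOINT_NAMES, PHASE_NAMES)
)

# Mixing coefficients turning the common per-phase weighted angle/velocity
# combination into the three moment components (sagittal, frontal,
# transverse). Sagittal dominates, mirroring landing mechanics.
MOMENT_MIX <- matrix(
  c(
    1.0, 0.5, # mx: angle term, velocity term
    0.4, 0.2, # my
    0.2, 0.1  # mz
  ),
  nrow = 3, byrow = TRUE,
  dimnames = list(c("mx", "my", "mz"), c("angle", "velocity"))
)

#' Simulation configuration for synthetic serve trials
#'
#' Builds and validates the configuration of the synthetic serve generator.
#' Defaults state the emulated study design: 30 participants performing 12
#' serves each, captured at 200 Hz, with the serve cycle divided into the
#' Preparation (PP), Flight (FP) and Landing (LP) phases.
#'
#' @param n_participants Number of participants (default 30).
#' @param trials_per_participant Serves per participant (default 12).
#' @param sampling_rate_hz Capture rate in Hz (default 200).
#' @param n_samples Raw trial length in samples (default 240, i.e. 1.2 s).
#' @param phase_fractions Three positive fractions summing to 1 giving the
#'   nominal PP/FP/LP share of the cycle.
#' @param angle_amplitude Per-joint peak excursion in degrees, order
#'   `c("l_ankle","l_knee","l_hip","r_ankle","r_knee","r_hip")`.
#' @param angle_baseline Per-joint baseline angle in degrees, same order.
#' @param timing_jitter_sd SD of the per-trial phase-boundary jitter in
#'   seconds.
#' @param between_subject_sd SD (log scale) of the participant-level
#'   multiplicative amplitude factor.
#' @param within_subject_sd SD (log scale) of the trial-level multiplicative
#'   amplitude factor.
#' @param generative_weights 3 x 6 matrix (phases x joints) of nonnegative
#'   weights; the moment components are the per-phase weighted sum of scaled
#'   joint angles and angular velocities (see [simulate_trial()]).
#' @param noise_sd SD of the additive Gaussian noise on each moment
#'   component, in N.m.
#' @param seed Integer seed controlling all randomness.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_trial()], [simulate_dataset()],
#'   [ground_truth_relevance()]
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 2, trials_per_participant = 3)
#' length(simulate_dataset(cfg))
sim_config <- function(n_participants = 30,
                       trials_per_participant = 12,
                       sampling_rate_hz = 200,
                       n_samples = 240,
                       phase_fractions = c(0.5, 0.25, 0.25),
                       angle_amplitude = c(25, 50, 40, 25, 45, 35),
                       angle_baseline = c(-10, 20, 30, -10, 15, 25),
                       timing_jitter_sd = 0.02,
                       between_subject_sd = 0.10,
                       within_subject_sd = 0.03,
                       generative_weights = default_generative_weights(),
                       noise_sd = 0.2,
                       seed = 1L) {
  if (!is_count(n_participants) || !is_count(trials_per_participant)) {
    abort_config("n_participants and trials_per_participant must be positive integers")
  }
  if (!is.numeric(phase_fractions) || length(phase_fractions) != 3 ||
      any(phase_fractions <= 0) ||
      abs(sum(phase_fractions) - 1) > 1e-12) {
    abort_config("phase_fractions must be three positive values summing to 1")
  }
  if (length(angle_amplitude) != 6 || !all(is.finite(angle_amplitude))) {
    abort_config("angle_amplitude must be six finite values")
  }
  if (length(angle_baseline) != 6 || !all(is.finite(angle_baseline))) {
    abort_config("angle_baseline must be six finite values")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    abort_config("noise_sd must be a nonnegative scalar")
  }
  gw <- as.matrix(generative_weights)
  if (!all(dim(gw) == c(3, 6)) || any(!is.finite(gw)) || any(gw < 0)) {
    abort_config("generative_weights must be a nonnegative 3 x 6 matrix (phases x joints)")
  }
  if (!is_count(n_samples) || n_samples < N_NODES) {
    abort_config(sprintf("n_samples must be an integer >= %d", N_NODES))
  }
  if (sampling_rate_hz <= 0) abort_config("sampling_rate_hz must be positive")
  if (timing_jitter_sd < 0 || between_subject_sd < 0 || within_subject_sd < 0) {
    abort_config("jitter and subject-variation SDs must be nonnegative")
  }
  dimnames(gw) <- list(PHASE_NAMES, JOINT_NAMES)
  structure(
    list(
      n_participants = as.integer(n_participants),
      trials_per_participant = as.integer(trials_per_participant),
      sampling_rate_hz = sampling_rate_hz,
      n_samples = as.integer(n_samples),
      phase_fractions = phase_fractions,
      angle_amplitude = setNames(angle_amplitude, JOINT_NAMES),
      angle_baseline = setNames(angle_baseline, JOINT_NAMES),
      timing_jitter_sd = timing_jitter_sd,
      between_subject_sd = between_subject_sd,
      within_subject_sd = within_subject_sd,
      generative_weights = gw,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default per-phase generative weights
#'
#' The default angle-to-moment weight profile of the simulator: the
#' supporting (left) knee dominates the Preparation and Landing phases while
#' ankles and hips dominate the Flight phase, the qualitative contribution
#' pattern the explanation module is expected to recover.
#'
#' @return A 3 x 6 matrix (phases PP/FP/LP x joints).
#' @export
default_generative_weights <- function() {
  matrix(
    c(
      0.2, 1.0, 0.3, 0.1, 0.6, 0.2, # PP: supporting knee dominant
      0.9, 0.5, 0.9, 0.7, 0.4, 0.7, # FP: ankles and hips high
      0.5, 1.0, 0.5, 0.2, 0.5, 0.2  # LP: supporting knee dominant
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(PHASE_NAMES, JOINT_NAMES)
  )
}

# Raised-cosine bump spanning samples s0..s1 (inclusive) of a length-n
# series: zero outside, zero with zero slope at the phase boundaries, one at
# the phase midpoint. Band-limited well below 10 Hz for phase durations of
# the order of 0.3 s and longer.
phase_bump <- function(n, s0, s1) {
  out <- numeric(n)
  idx <- s0:s1
  u <- (idx - s0) / (s1 - s0)
  out[idx] <- 0.5 * (1 - cos(2 * pi * u))
  out
}

# Nominal (unjittered) phase boundaries for a trial of length n: the last
# sample of PP and of FP.
nominal_boundaries <- function(n, fractions) {
  b <- round(n * cumsum(fractions)[1:2])
  c(max(2, b[1]), min(n - 1, max(b[1] + 1, b[2])))
}

# Per-sample phase index (1 = PP, 2 = FP, 3 = LP) from boundaries.
phase_index <- function(n, boundaries) {
  rep.int(1:3, c(
    boundaries[1],
    boundaries[2] - boundaries[1],
    n - boundaries[2]
  ))
}

# Centered finite-difference time derivative (deg/s); one-sided at the ends.
finite_diff <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d
}

# The generative angle-to-moment mapping. Exposed internally so tests can
# compare against an independent re-evaluation:
#   scaled angle   a_j(t) = (theta_j(t) - baseline_j) / 10         [per 10 deg]
#   scaled velocity v_j(t) = dtheta_j/dt / 100                     [per 100 deg/s]
#   common terms   A(t) = sum_j W[p(t), j] a_j(t)
#                  V(t) = sum_j W[p(t), j] v_j(t)
#   component k    m_k(t) = MOMENT_MIX[k,1] A(t) + MOMENT_MIX[k,2] V(t) + noise
generative_moments <- function(angles, boundaries, config, noise) {
  n <- ncol(angles)
  p <- phase_index(n, boundaries)
  a_scaled <- (angles - config$angle_baseline) / 10
  v_scaled <- t(apply(angles, 1, finite_diff, fs = config$sampling_rate_hz)) / 100
  w <- t(config$generative_weights[p, , drop = FALSE]) # 6 x n
  A <- colSums(w * a_scaled)
  V <- colSums(w * v_scaled)
  m <- MOMENT_MIX[, "angle"] %o% A + MOMENT_MIX[, "velocity"] %o% V + noise
  rownames(m) <- c("mx", "my", "mz")
  m
}

#' Simulate one synthetic serve trial
#'
#' Generates one serve: six smooth joint-angle curves built from per-phase
#' raised-cosine excursions (band-limited well below the 10 Hz filter
#' cutoff), and three joint-moment components (sagittal, frontal,
#' transverse) equal to a per-phase weighted combination of scaled joint
#' angles and angular velocities plus additive Gaussian noise. Participant-
#' level amplitude factors are drawn from a stream keyed by
#' `(seed, participant_id)` only, trial-level factors, timing jitter and
#' noise from a stream keyed by `(seed, participant_id, trial_id)`, so the
#' same identifiers always reproduce the same trial.
#'
#' @param config A [sim_config()].
#' @param participant_id,trial_id Positive integer identifiers.
#'
#' @return A `serve_trial` object: list with `angles_raw` (6 x T, degrees,
#'   rows in canonical joint order), `moment_components_raw` (3 x T, N.m),
#'   `phase_boundaries` (last sample of PP and of FP), `sampling_rate_hz`,
#'   `participant_id`, `trial_id`.
#' @export
simulate_trial <- function(config, participant_id, trial_id) {
  stopifnot(inherits(config, "sim_config"))
  if (!is_count(participant_id) || !is_count(trial_id)) {
    abort_argument("participant_id and trial_id must be positive integers")
  }
  n <- config$n_samples
  fs <- config$sampling_rate_hz

  # participant-level amplitude factors: one draw per participant and per
  # joint (individual movement styles are joint-specific, so the six
  # excursions vary independently rather than through one shared scale)
  pfac <- with_seed(
    derive_seed(config$seed, 1L, participant_id),
    exp(rnorm(6, 0, config$between_subject_sd))
  )

  trial_draws <- with_seed(
    derive_seed(config$seed, 2L, participant_id, trial_id),
    list(
      tfac = exp(rnorm(6, 0, config$within_subject_sd)),
      jitter = rnorm(2, 0, config$timing_jitter_sd * fs),
      noise = matrix(rnorm(3 * n, 0, config$noise_sd), nrow = 3)
    )
  )

  b <- nominal_boundaries(n, config$phase_fractions)
  b1 <- min(max(2L, as.integer(round(b[1] + trial_draws$jitter[1]))), n - 2L)
  b2 <- min(max(b1 + 1L, as.integer(round(b[2] + trial_draws$jitter[2]))), n - 1L)
  boundaries <- c(b1, b2)

  seg <- list(c(1L, b1), c(b1 + 1L, b2), c(b2 + 1L, n))
  bumps <- vapply(
    seg, function(s) phase_bump(n, s[1], s[2]),
    numeric(n)
  ) # n x 3

  amp <- config$angle_amplitude * pfac * trial_draws$tfac
  angles <- config$angle_baseline +
    (amp * PHASE_SHAPE) %*% t(bumps) # 6 x n
  rownames(angles) <- JOINT_NAMES

  moments <- generative_moments(angles, boundaries, config, trial_draws$noise)

  structure(
    list(
      angles_raw = angles,
      moment_components_raw = moments,
      phase_boundaries = boundaries,
      sampling_rate_hz = fs,
      participant_id = as.integer(participant_id),
      trial_id = as.integer(trial_id)
    ),
    class = "serve_trial"
  )
}

#' Simulate a full synthetic dataset
#'
#' Runs [simulate_trial()] for every `(participant, trial)` pair. With the
#' default configuration (30 participants, 12 trials each) this yields the
#' emulated study size of 360 serves.
#'
#' @param config A [sim_config()].
#' @return A list of `serve_trial` objects of length
#'   `n_participants * trials_per_participant`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  trials <- vector("list", config$n_participants * config$trials_per_participant)
  k <- 1L
  for (p in seq_len(config$n_participants)) {
    for (tr in seq_len(config$trials_per_participant)) {
      trials[[k]] <- simulate_trial(config, p, tr)
      k <- k + 1L
    }
  }
  trials
}

#' Ground-truth per-phase relevance profile
#'
#' Returns the generative weight matrix with each phase's six-joint vector
#' normalized to maximum 1 — the reference pattern that relevance-recovery
#' tests compare LRP contribution curves against.
#'
#' @param config A [sim_config()].
#' @return A 3 x 6 matrix (phases x joints), each row with maximum 1.
#' @export
ground_truth_relevance <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gw <- config$generative_weights
  mx <- apply(gw, 1, max)
  if (any(mx == 0)) {
    abort_config("generative_weights has an all-zero phase; relevance ground truth undefined")
  }
  sweep(gw, 1, mx, "/")
}

#' @export
print.serve_trial <- function(x, ...) {
  cat(sprintf(
    "<serve_trial> participant %d, trial %d: %d samples @ %g Hz, phases PP 1-%d / FP %d-%d / LP %d-%d\n",
    x$participant_id, x$trial_id, ncol(x$angles_raw), x$sampling_rate_hz,
    x$phase_boundaries[1], x$phase_boundaries[1] + 1L, x$phase_boundaries[2],
    x$phase_boundaries[2] + 1L, ncol(x$angles_raw)
  ))
  invisible(x)
}

#' Write / read serve trials as CSV
#'
#' One CSV per trial with columns `time_index`, the six joint angles in
#' canonical order, and `mx, my, mz`, plus a `manifest.csv` listing
#' `participant_id, trial_id, file, phase_end_pp, phase_end_fp,
#' sampling_rate_hz`. Values are written at 12 significant digits.
#'
#' @param trials List of `serve_trial` objects.
#' @param dir Output directory (created if missing).
#' @return `write_dataset_csv` returns the manifest data frame invisibly;
#'   `read_dataset_csv` returns a list of `serve_trial` objects.
#' @export
write_dataset_csv <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(trials, function(tr) {
    file <- sprintf("trial_p%03d_t%03d.csv", tr$participant_id, tr$trial_id)
    df <- data.frame(
      time_index = seq_len(ncol(tr$angles_raw)) - 1L,
      t(tr$angles_raw),
      mx = tr$moment_components_raw[1, ],
      my = tr$moment_components_raw[2, ],
      mz = tr$moment_components_raw[3, ]
    )
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], format_sig)
    write.csv(df, file.path(dir, file), row.names = FALSE, quote = FALSE)
    data.frame(
      participant_id = tr$participant_id, trial_id = tr$trial_id,
      file = file,
      phase_end_pp = tr$phase_boundaries[1],
      phase_end_fp = tr$phase_boundaries[2],
      sampling_rate_hz = tr$sampling_rate_hz
    )
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    df <- read.csv(file.path(dir, manifest$file[i]))
    need <- c("time_index", JOINT_NAMES, "mx", "my", "mz")
    if (!all(need %in% names(df))) {
      abort_data(sprintf("trial CSV %s missing required columns", manifest$file[i]))
    }
    angles <- t(as.matrix(df[JOINT_NAMES]))
    rownames(angles) <- JOINT_NAMES
    moments <- t(as.matrix(df[c("mx", "my", "mz")]))
    structure(
      list(
        angles_raw = angles,
        moment_components_raw = moments,
        phase_boundaries = c(manifest$phase_end_pp[i], manifest$phase_end_fp[i]),
        sampling_rate_hz = manifest$sampling_rate_hz[i],
        participant_id = manifest$participant_id[i],
        trial_id = manifest$trial_id[i]
      ),
      class = "serve_trial"
    )
  })
}
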