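#' Default limb oscillation amplitudes
#'
#' Per-joint (x, y, z) oscillation amplitudes in meters for the 14 analysis
#' joints. Values are plausible magnitudes for natural walking: ankle and
#' wrist excursions dominate in the walking direction (z), with small
#' vertical components; the trunk barely oscillates. Not a biomechanical
#' model, just the signal family the Fourier feature set is built to capture.
#'
#' @return Named list mapping each analysis joint to `c(x, y, z)` amplitudes.
#' @export
default_joint_amplitudes <- function() {
  amp <- list(
    SpineBase = c(0, 0, 0),
    Neck      = c(0, 0.005, 0),
    ShoulderL = c(0, 0.005, 0.02),  ShoulderR = c(0, 0.005, 0.02),
    ElbowL    = c(0, 0.01, 0.06),   ElbowR    = c(0, 0.01, 0.06),
    WristL    = c(0, 0.02, 0.12),   WristR    = c(0, 0.02, 0.12),
    HipL      = c(0, 0.005, 0.02),  HipR      = c(0, 0.005, 0.02),
    KneeL     = c(0, 0.02, 0.10),   KneeR     = c(0, 0.02, 0.10),
    AnkleL    = c(0, 0.03, 0.18),   AnkleR    = c(0, 0.03, 0.18))
  amp
}

#' Synthetic gait parameters
#'
#' Parameter set of the synthetic walker: a body translating along the depth
#' axis of a 6 m footpath at walking speed, turning at the ends, with limbs
#' oscillating at the stride frequency (plus a weaker second harmonic) in
#' contralateral phase opposition, under additive Gaussian sensor noise that
#' is inflated tenfold while turning (skeleton tracking degrades during
#' turns).
#'
#' @param stride_freq Stride (full gait cycle) frequency in Hz; typical
#'   walking is 0.8-1.2 Hz. Default 1.
#' @param speed Walking speed in m/s. Default 1.
#' @param footpath_length Footpath length in m (default 6).
#' @param joint_amplitudes Per-joint oscillation amplitudes,
#'   see [default_joint_amplitudes()].
#' @param harmonic_ratio Amplitude fraction at twice the stride frequency
#'   (default 0.3).
#' @param noise_sd Sensor noise standard deviation in m (default 0.005).
#' @param turn_duration Turn duration at each footpath end in s (default 2).
#' @param duration Recording duration in s (default 60, one walking bout).
#' @param frame_rate Hz (default 30).
#' @param seed Integer seed for the record's noise.
#' @return A `gait_params` list.
#' @export
gait_params <- function(stride_freq = 1.0, speed = 1.0, footpath_length = 6,
                        joint_amplitudes = default_joint_amplitudes(),
                        harmonic_ratio = 0.3, noise_sd = 0.005,
                        turn_duration = 2, duration = 60, frame_rate = 30,
                        seed = 1L) {
  p <- list(stride_freq = stride_freq, speed = speed,
            footpath_length = footpath_length,
            joint_amplitudes = joint_amplitudes,
            harmonic_ratio = harmonic_ratio, noise_sd = noise_sd,
            turn_duration = turn_duration, duration = duration,
            frame_rate = frame_rate, seed = as.integer(seed))
  for (f in c("stride_freq", "speed", "footpath_length", "duration",
              "frame_rate"))
    if (!is.numeric(p[[f]]) || p[[f]] <= 0)
      stop(f, " must be positive", call. = FALSE)
  if (p$noise_sd < 0 || p$turn_duration < 0 || p$harmonic_ratio < 0)
    stop("noise_sd, turn_duration and harmonic_ratio must be >= 0",
         call. = FALSE)
  if (p$stride_freq >= p$frame_rate / 2)
    stop("stride_freq must be below the Nyquist frequency", call. = FALSE)
  missing_amp <- setdiff(analysis_joints(), names(p$joint_amplitudes))
  if (length(missing_amp))
    stop("joint_amplitudes missing: ", paste(missing_amp, collapse = ", "),
         call. = FALSE)
  structure(p, class = "gait_params")
}

#' Class-dependent gait modulation
#'
#' A stand-in for emotion effects on gait: affective state shifts cadence
#' (stride frequency) and scales arm and leg swing amplitudes.
#'
#' @param label Class label attached to generated records.
#' @param delta_freq Additive stride-frequency shift in Hz.
#' @param amp_scale_arms,amp_scale_legs Multiplicative amplitude factors for
#'   shoulder/elbow/wrist and hip/knee/ankle joints.
#' @return An `emotion_effect` list.
#' @export
emotion_effect <- function(label, delta_freq = 0, amp_scale_arms = 1,
                           amp_scale_legs = 1) {
  if (amp_scale_arms <= 0 || amp_scale_legs <= 0)
    stop("amplitude scales must be positive", call. = FALSE)
  structure(list(label = as.character(label), delta_freq = delta_freq,
                 amp_scale_arms = amp_scale_arms,
                 amp_scale_legs = amp_scale_legs),
            class = "emotion_effect")
}

# rest offsets of each joint relative to SpineBase (x lateral, y up, z), m
joint_offsets <- function() {
  list(
    SpineBase = c(0, 0, 0), SpineMid = c(0, 0.15, 0),
    SpineShoulder = c(0, 0.35, 0), Neck = c(0, 0.45, 0),
    Head = c(0, 0.60, 0),
    ShoulderL = c(-0.18, 0.40, 0), ShoulderR = c(0.18, 0.40, 0),
    ElbowL = c(-0.22, 0.15, 0), ElbowR = c(0.22, 0.15, 0),
    WristL = c(-0.24, -0.05, 0), WristR = c(0.24, -0.05, 0),
    HandL = c(-0.25, -0.12, 0), HandR = c(0.25, -0.12, 0),
    HandTipL = c(-0.25, -0.18, 0), HandTipR = c(0.25, -0.18, 0),
    ThumbL = c(-0.22, -0.13, 0), ThumbR = c(0.22, -0.13, 0),
    HipL = c(-0.09, -0.05, 0), HipR = c(0.09, -0.05, 0),
    KneeL = c(-0.10, -0.45, 0), KneeR = c(0.10, -0.45, 0),
    AnkleL = c(-0.10, -0.85, 0), AnkleR = c(0.10, -0.85, 0),
    FootL = c(-0.10, -0.90, 0.05), FootR = c(0.10, -0.90, 0.05))
}

# joints that are not modeled explicitly ride rigidly with a modeled parent
rider_parents <- c(
  Head = "Neck", SpineShoulder = "Neck", SpineMid = "SpineBase",
  HandL = "WristL", HandR = "WristR",
  HandTipL = "WristL", HandTipR = "WristR",
  ThumbL = "WristL", ThumbR = "WristR",
  FootL = "AnkleL", FootR = "AnkleR")

# base oscillation phase per analysis joint: left legs lead, right legs and
# ipsilateral-opposite arms are offset by pi (contralateral opposition)
joint_phases <- function() {
  c(SpineBase = 0, Neck = 0,
    ShoulderL = pi, ShoulderR = 0, ElbowL = pi, ElbowR = 0,
    WristL = pi, WristR = 0,
    HipL = 0, HipR = pi, KneeL = 0, KneeR = pi, AnkleL = 0, AnkleR = pi)
}

arm_joints <- c("ShoulderL", "ShoulderR", "ElbowL", "ElbowR",
                "WristL", "WristR")
leg_joints <- c("HipL", "HipR", "KneeL", "KneeR", "AnkleL", "AnkleR")

# piecewise footpath trajectory: straight passes joined by turn windows.
# Returns list(z = depth of SpineBase per frame, turning = logical per frame).
footpath_trajectory <- function(n_frames, speed, footpath_length,
                                turn_duration, frame_rate, z_near = 1.5) {
  n_pass <- max(2L, round(footpath_length / speed * frame_rate))
  n_turn <- round(turn_duration * frame_rate)
  z <- numeric(0)
  turning <- logical(0)
  pos <- z_near + footpath_length
  dir <- -1  # start at the far end walking toward the camera
  step <- speed / frame_rate
  while (length(z) < n_frames) {
    pass <- pos + dir * step * seq_len(n_pass)
    z <- c(z, pass)
    turning <- c(turning, rep(FALSE, n_pass))
    pos <- pass[n_pass]
    if (n_turn > 0L) {
      z <- c(z, rep(pos, n_turn))
      turning <- c(turning, rep(TRUE, n_turn))
    }
    dir <- -dir
  }
  list(z = z[seq_len(n_frames)], turning = turning[seq_len(n_frames)])
}

#' Simulate one gait record
#'
#' Generates a 25-joint skeleton recording: SpineBase translates along the
#' depth axis at walking speed, reversing at the footpath ends during turn
#' windows in which sensor noise is inflated tenfold; every analysis joint is
#' SpineBase plus a rest offset plus a stride-frequency sinusoid with a
#' second harmonic, left/right homologous joints in phase opposition; the
#' remaining joints ride rigidly with their nearest modeled joint. The
#' emotion effect shifts the stride frequency and scales arm/leg amplitudes.
#'
#' @param params A [gait_params()].
#' @param effect An [emotion_effect()]; defaults to an identity `"neutral"`
#'   effect.
#' @param subject_id,camera_id Metadata for the generated record.
#' @return A valid [gait_record]; the same `params$seed` reproduces the
#'   record exactly.
#' @export
simulate_record <- function(params, effect = emotion_effect("neutral"),
                            subject_id = "S01", camera_id = "K1") {
  stopifnot(inherits(params, "gait_params"), inherits(effect, "emotion_effect"))
  f <- params$stride_freq + effect$delta_freq
  if (f <= 0 || f >= params$frame_rate / 2)
    stop("effect-modified stride frequency out of (0, Nyquist)", call. = FALSE)
  set.seed(params$seed)
  n <- round(params$duration * params$frame_rate)
  t <- (seq_len(n) - 1L) / params$frame_rate
  traj <- footpath_trajectory(n, params$speed, params$footpath_length,
                              params$turn_duration, params$frame_rate)
  noise_sd <- ifelse(traj$turning, 10 * params$noise_sd, params$noise_sd)
  offsets <- joint_offsets()
  phases <- joint_phases()
  # SpineBase path: lateral sway, gentle vertical bounce at 2f, depth z
  base <- cbind(x = 0.02 * sin(2 * pi * f * t),
                y = 0.95 + 0.01 * sin(4 * pi * f * t),
                z = traj$z)
  pos <- list()
  for (j in analysis_joints()) {
    amp <- params$joint_amplitudes[[j]]
    if (j %in% arm_joints) amp <- amp * effect$amp_scale_arms
    if (j %in% leg_joints) amp <- amp * effect$amp_scale_legs
    osc <- sin(2 * pi * f * t + phases[[j]]) +
      params$harmonic_ratio * sin(4 * pi * f * t + 2 * phases[[j]] + pi / 4)
    pos[[j]] <- base +
      rep(offsets[[j]], each = n) +
      outer(osc, amp)
  }
  for (j in names(rider_parents)) {
    parent <- rider_parents[[j]]
    pos[[j]] <- pos[[parent]] +
      rep(offsets[[j]] - offsets[[parent]], each = n)
  }
  coords <- matrix(0, n, 75L,
                   dimnames = list(NULL, coord_columns(kinect_joints())))
  for (j in kinect_joints()) {
    noisy <- pos[[j]] + matrix(stats::rnorm(3L * n, sd = noise_sd), n, 3L)
    coords[, paste0(j, "_", c("x", "y", "z"))] <- noisy
  }
  gait_record(coords, subject_id = subject_id, condition = effect$label,
              camera_id = camera_id, frame_rate = params$frame_rate)
}

#' Simulate a labeled cohort
#'
#' Draws per-subject baseline gait parameters (stride frequency, speed and
#' oscillation amplitudes perturbed by a Gaussian relative deviation around
#' the base parameters), then generates one record per emotion effect per
#' subject — mirroring a within-subject design where every participant walks
#' once per condition.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param params_base A [gait_params()]; per-subject parameters scatter
#'   around it.
#' @param effects List of [emotion_effect()]s, one record per subject each.
#' @param between_subject_sd Relative (coefficient-of-variation) Gaussian
#'   spread of stride frequency, speed and amplitudes across subjects
#'   (default 0.05).
#' @param seed Cohort seed; drives subject draws and all record noise.
#' @return List of [gait_record]s of length `n_subjects * length(effects)`.
#' @export
simulate_cohort <- function(n_subjects, params_base = gait_params(),
                            effects = list(emotion_effect("neutral")),
                            between_subject_sd = 0.05, seed = 1L) {
  stopifnot(inherits(params_base, "gait_params"))
  if (n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  if (between_subject_sd < 0)
    stop("between_subject_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  records <- vector("list", n_subjects * length(effects))
  idx <- 0L
  for (s in seq_len(n_subjects)) {
    rel <- 1 + stats::rnorm(3L, sd = between_subject_sd)
    rel <- pmax(rel, 0.2)
    amps <- lapply(params_base$joint_amplitudes, function(a) a * rel[3L])
    record_seeds <- sample.int(.Machine$integer.max,
                               size = length(effects))
    for (e in seq_along(effects)) {
      p <- gait_params(
        stride_freq = params_base$stride_freq * rel[1L],
        speed = params_base$speed * rel[2L],
        footpath_length = params_base$footpath_length,
        joint_amplitudes = amps,
        harmonic_ratio = params_base$harmonic_ratio,
        noise_sd = params_base$noise_sd,
        turn_duration = params_base$turn_duration,
        duration = params_base$duration,
        frame_rate = params_base$frame_rate,
        seed = record_seeds[e])
      idx <- idx + 1L
      records[[idx]] <- simulate_record(p, effects[[e]],
                                        subject_id = sprintf("S%03d", s))
    }
  }
  records
}
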