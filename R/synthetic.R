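#' @title Specification constructors for synthetic gaze-shift data
#'
#' @description Small validated parameter containers used by the trace,
#' schedule and response generators. Defaults follow the study conditions
#' the package emulates: head movements of 10-30 degrees obeying a linear
#' main sequence (peak velocity = 13.22 + 1.27 x amplitude, in deg/s),
#' head sampling at 913.68 Hz, eye sampling at 120 Hz, comparison stimuli
#' at seven positions from -1.37 to +1.37 degrees in 0.46-degree steps
#' with eight repetitions per position.
#'
#' @name synthetic-specs
NULL

#' Evaluate expression with a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so
#' generator calls are reproducible without disturbing the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

#' @describeIn synthetic-specs Generating observer for 2AFC responses:
#'   `pha` is the true point of horizontal alignment (deg), `jnd` the true
#'   discrimination threshold (deg, > 0), `lapse_rate` a stimulus-independent
#'   error probability in \[0, 0.1\].
#' @param pha True point of horizontal alignment in degrees.
#' @param jnd True just-noticeable difference in degrees (> 0).
#' @param lapse_rate Lapse probability in \[0, 0.1\].
#' @export
observer_spec <- function(pha = 0, jnd = 0.8, lapse_rate = 0) {
  if (!is.numeric(jnd) || jnd <= 0) stop("'jnd' must be > 0")
  if (lapse_rate < 0 || lapse_rate > 0.1)
    stop("'lapse_rate' must be in [0, 0.1]")
  structure(list(pha = pha, jnd = jnd, lapse_rate = lapse_rate),
            class = "observer_spec")
}

#' @describeIn synthetic-specs Head-movement kinematics: amplitude (deg),
#'   main-sequence intercept (deg/s) and slope (deg/s per deg), Gaussian
#'   noise on the peak velocity (deg/s), additive position noise (deg RMS),
#'   sample rate (Hz) and direction sign (+1 rightward).
#' @param amplitude Movement amplitude in degrees (>= 0).
#' @param ms_intercept Main-sequence intercept in deg/s.
#' @param ms_slope Main-sequence slope in deg/s per degree.
#' @param velocity_noise_sd SD of Gaussian noise added to the peak
#'   velocity, deg/s.
#' @param position_noise_sd SD of additive Gaussian position noise, deg.
#' @param sample_rate Sampling rate in Hz.
#' @param direction +1 for rightward, -1 for leftward.
#' @export
head_movement_spec <- function(amplitude, ms_intercept = 13.22,
                               ms_slope = 1.27, velocity_noise_sd = 0,
                               position_noise_sd = 0.05,
                               sample_rate = 913.68, direction = 1) {
  if (amplitude < 0) stop("'amplitude' must be >= 0")
  if (sample_rate <= 0) stop("'sample_rate' must be > 0")
  if (!direction %in% c(-1, 1)) stop("'direction' must be +1 or -1")
  structure(list(amplitude = amplitude, ms_intercept = ms_intercept,
                 ms_slope = ms_slope, velocity_noise_sd = velocity_noise_sd,
                 position_noise_sd = position_noise_sd,
                 sample_rate = sample_rate, direction = direction),
            class = "head_movement_spec")
}

#' @describeIn synthetic-specs Comparison-stimulus schedule: unique
#'   positions (deg), repetitions per position, and whether the trial
#'   order is a seeded permutation.
#' @param comparison_positions Unique comparison offsets in degrees.
#' @param repetitions Repetitions per position (>= 1).
#' @param randomize Shuffle trial order (seeded)?
#' @param seed Integer seed for the shuffle.
#' @export
trial_schedule_spec <- function(
    comparison_positions = c(-1.37, -0.92, -0.46, 0, 0.46, 0.92, 1.37),
    repetitions = 8, randomize = TRUE, seed = 1L) {
  if (length(comparison_positions) == 0)
    stop("'comparison_positions' must be non-empty")
  if (anyDuplicated(comparison_positions))
    stop("'comparison_positions' must be unique")
  if (repetitions < 1) stop("'repetitions' must be >= 1")
  structure(list(comparison_positions = comparison_positions,
                 repetitions = repetitions, randomize = randomize,
                 seed = as.integer(seed)),
            class = "trial_schedule_spec")
}

#' @describeIn synthetic-specs Trial-level scenario: gaze-shift mode,
#'   target presentation, background, visual velocity gain (scene motion
#'   opposite the head, as a ratio of head velocity), and the fixation and
#'   target eccentricities (deg; fixation left of centre, target right).
#' @param gaze_mode `"unrestricted"` or `"sequential"`.
#' @param target_presentation `"stationary"` or `"flashed"`.
#' @param background `"grating"` or `"none"`.
#' @param visual_velocity_gain Gain ratio (>= 0; presets 1, 1.15, 1.3).
#' @param fixation_eccentricity Fixation-cross eccentricity, deg.
#' @param target_eccentricity Gaze-target eccentricity, deg.
#' @param n_secondary_saccades Secondary saccades injected during the head
#'   movement in unrestricted mode.
#' @export
gaze_shift_scenario <- function(gaze_mode = c("unrestricted", "sequential"),
                                target_presentation = c("stationary", "flashed"),
                                background = c("grating", "none"),
                                visual_velocity_gain = 1,
                                fixation_eccentricity = -10,
                                target_eccentricity = 10,
                                n_secondary_saccades =
                                  if (match.arg(gaze_mode) == "unrestricted") 2L else 0L) {
  gaze_mode <- match.arg(gaze_mode)
  target_presentation <- match.arg(target_presentation)
  background <- match.arg(background)
  if (visual_velocity_gain < 0) stop("'visual_velocity_gain' must be >= 0")
  structure(list(gaze_mode = gaze_mode,
                 target_presentation = target_presentation,
                 background = background,
                 visual_velocity_gain = visual_velocity_gain,
                 fixation_eccentricity = fixation_eccentricity,
                 target_eccentricity = target_eccentricity,
                 n_secondary_saccades = as.integer(n_secondary_saccades)),
            class = "gaze_shift_scenario")
}

#' Generate a synthetic head-yaw trace
#'
#' Synthesizes one head movement with a raised-cosine velocity profile:
#' v(t) = (Vp/2) * (1 - cos(2*pi*t/D)) over the movement interval, where
#' the peak velocity Vp follows the main-sequence line
#' `ms_intercept + ms_slope * amplitude` plus Gaussian noise, and the
#' movement duration is D = 2 * amplitude / Vp (the raised-cosine
#' displacement identity). Position is flat before onset and after offset;
#' additive Gaussian position noise is applied throughout.
#'
#' @param spec A [head_movement_spec()].
#' @param duration Total trace duration in seconds.
#' @param onset_time Movement onset in seconds from trace start.
#' @param seed Integer seed (noise draws), or `NULL`.
#' @param start_angle Yaw before movement onset, degrees.
#'
#' @return A [sampled_trace()] (`stream = "head"`). The generating ground
#'   truth (onset/offset times, amplitude, peak velocity) is attached as
#'   attribute `"truth"`.
#' @examples
#' tr <- generate_head_trace(head_movement_spec(20, position_noise_sd = 0),
#'                           duration = 2, onset_time = 0.4, seed = 1)
#' attr(tr, "truth")$peak_velocity  # 13.22 + 1.27 * 20 = 38.62
#' @export
generate_head_trace <- function(spec, duration, onset_time = 0.25,
                                seed = NULL, start_angle = 0) {
  stopifnot(inherits(spec, "head_movement_spec"))
  with_seed(seed, {
    n <- floor(duration * spec$sample_rate) + 1L
    times <- (seq_len(n) - 1L) / spec$sample_rate
    if (spec$amplitude <= 0) {
      ang <- rep(start_angle, n)
      truth <- list(onset_time = NA_real_, offset_time = NA_real_,
                    amplitude = 0, peak_velocity = 0)
    } else {
      vp <- spec$ms_intercept + spec$ms_slope * spec$amplitude +
        stats::rnorm(1L, 0, spec$velocity_noise_sd)
      vp <- max(vp, 0)
      if (vp <= 0) stop("implied peak velocity is non-positive")
      D <- 2 * spec$amplitude / vp
      if (onset_time < 0 || onset_time + D > duration)
        stop(sprintf(
          "movement (%.3f s from onset %.3f s) does not fit in a %.3f s trace",
          D, onset_time, duration))
      trel <- times - onset_time
      ang <- ifelse(
        trel <= 0, 0,
        ifelse(trel >= D, spec$amplitude,
               (vp / 2) * (trel - (D / (2 * pi)) * sin(2 * pi * trel / D))))
      ang <- start_angle + spec$direction * ang
      truth <- list(onset_time = onset_time, offset_time = onset_time + D,
                    amplitude = spec$amplitude, peak_velocity = vp)
    }
    if (spec$position_noise_sd > 0) {
      # band-limited tracker noise: Gaussian control points every 100 ms,
      # linearly interpolated. White noise at ~900 Hz would imply
      # per-sample velocities of tens of deg/s, which no head tracker
      # shows at rest; slow drift/tremor is the realistic error mode.
      k <- max(ceiling(duration / 0.1) + 1L, 2L)
      ctrl_t <- seq(0, duration, length.out = k)
      ctrl <- stats::rnorm(k, 0, spec$position_noise_sd)
      ang <- ang + stats::approx(ctrl_t, ctrl, xout = times)$y
    }
    out <- sampled_trace(times, ang, "head",
                         nominal_rate = spec$sample_rate)
    attr(out, "truth") <- truth
    out
  })
}

#' Generate a synthetic gaze-in-world trace
#'
#' Builds the eye component of a gaze shift on top of a head trace: a
#' step-like primary saccade from the fixation cross toward the target
#' shortly before the head-movement onset (typically undershooting), a
#' slow sub-criterion corrective glide that brings gaze onto the target by
#' head-movement onset, then gaze held on the target throughout the head
#' rotation (perfect vestibulo-ocular counter-rotation, so the
#' gaze-in-world signal stays flat). In unrestricted mode,
#' `scenario$n_secondary_saccades` small saccades of alternating sign are
#' injected during the head movement, which lowers the target-fixation
#' fraction.
#'
#' @param scenario A [gaze_shift_scenario()].
#' @param head_trace Head [sampled_trace()] produced by
#'   [generate_head_trace()] (its `"truth"` attribute supplies the
#'   head-movement interval; otherwise the interval is detected).
#' @param saccade_amplitude Signed primary-saccade amplitude in degrees;
#'   its sign must point from fixation toward the target.
#' @param seed Integer seed, or `NULL`.
#' @param eye_rate Eye sampling rate in Hz (must not exceed the head rate).
#' @param noise_sd Gaussian position noise SD, degrees.
#' @param saccade_lead Primary-saccade lead before head onset, seconds.
#' @param secondary_amplitude Amplitude of injected secondary saccades,
#'   degrees.
#'
#' @return A [sampled_trace()] (`stream = "gaze"`) with attribute
#'   `"truth"` listing the injected saccade times and amplitudes.
#' @export
generate_gaze_trace <- function(scenario, head_trace, saccade_amplitude,
                                seed = NULL, eye_rate = 120,
                                noise_sd = 0.1, saccade_lead = 0.15,
                                secondary_amplitude = 2) {
  stopifnot(inherits(scenario, "gaze_shift_scenario"))
  assert_trace(head_trace)
  if (eye_rate > head_trace$nominal_rate + 1e-9)
    stop("eye sample rate must not exceed the head sample rate")
  dir_target <- sign(scenario$target_eccentricity -
                       scenario$fixation_eccentricity)
  if (sign(saccade_amplitude) != dir_target)
    stop("saccade amplitude sign is inconsistent with the target direction")
  truth <- attr(head_trace, "truth")
  if (is.null(truth) || is.na(truth$onset_time)) {
    ev <- detect_head_movement(head_trace)
    truth <- list(onset_time = ev$onset_time, offset_time = ev$offset_time)
  }
  with_seed(seed, {
    t_end <- head_trace$times[length(head_trace$times)]
    n <- floor(t_end * eye_rate) + 1L
    times <- (seq_len(n) - 1L) / eye_rate
    fix <- scenario$fixation_eccentricity
    target <- scenario$target_eccentricity
    landing <- fix + saccade_amplitude

    # corrective glide: slow drift from the undershoot landing onto the
    # target, ideally finishing at head-movement onset. Per-sample steps
    # stay below the 0.1-degree saccade-offset criterion, so the glide is
    # fixational drift, not part of the saccade.
    undershoot <- abs(target - landing)
    glide_dur <- if (undershoot > 1e-12)
      undershoot / (0.08 * eye_rate) else 0

    # primary saccade: 3-sample ramp ending early enough for the saccade
    # to settle (>= 30 ms) before the glide begins
    sac_on <- max(truth$onset_time - max(saccade_lead, glide_dur + 0.1),
                  times[2])
    ramp_len <- 3L
    gaze <- rep(fix, n)
    i_on <- max(findInterval(sac_on, times), 1L)
    idx_ramp <- pmin(i_on + seq_len(ramp_len), n)
    gaze[idx_ramp] <- fix + saccade_amplitude * seq_len(ramp_len) / ramp_len
    if (max(idx_ramp) < n) gaze[(max(idx_ramp) + 1L):n] <- landing

    g0 <- g1 <- NA_real_
    if (glide_dur > 0 && !is.na(truth$onset_time)) {
      g0 <- max(truth$onset_time - glide_dur,
                times[max(idx_ramp)] + 0.04)
      g1 <- g0 + glide_dur
      in_glide <- times > g0 & times < g1
      gaze[in_glide] <- landing +
        (target - landing) * (times[in_glide] - g0) / (g1 - g0)
      gaze[times >= g1] <- target
    } else if (!is.na(truth$onset_time)) {
      gaze[times >= truth$onset_time] <- target
    }

    sec_times <- numeric(0)
    if (scenario$gaze_mode == "unrestricted" &&
        scenario$n_secondary_saccades > 0 && !is.na(truth$onset_time)) {
      k <- scenario$n_secondary_saccades
      # spaced inside the head-movement interval, leaving room to settle
      sec_times <- truth$onset_time +
        (truth$offset_time - truth$onset_time) * seq_len(k) / (k + 1)
      offset_state <- 0
      for (j in seq_len(k)) {
        jump <- secondary_amplitude * (if (j %% 2 == 1) 1 else -1)
        offset_state <- offset_state + jump
        i_j <- findInterval(sec_times[j], times)
        if (i_j < n) gaze[(i_j + 1L):n] <- target + offset_state
      }
    }
    if (noise_sd > 0) gaze <- gaze + stats::rnorm(n, 0, noise_sd)
    out <- sampled_trace(times, gaze, "gaze", nominal_rate = eye_rate)
    attr(out, "truth") <- list(
      primary_onset_time = sac_on, primary_amplitude = saccade_amplitude,
      landing = landing, glide_start = g0, glide_end = g1,
      secondary_times = sec_times,
      secondary_amplitude = secondary_amplitude)
    out
  })
}

#' Generate a balanced 2AFC trial schedule
#'
#' Fully crossed schedule of comparison positions: each position appears
#' exactly `repetitions` times; when `randomize` is set the order is a
#' seeded permutation.
#'
#' @param spec A [trial_schedule_spec()].
#' @return A data frame with columns `trial` and `comparison_deg`.
#' @examples
#' nrow(generate_trial_schedule(trial_schedule_spec()))  # 56
#' @export
generate_trial_schedule <- function(spec = trial_schedule_spec()) {
  stopifnot(inherits(spec, "trial_schedule_spec"))
  pos <- rep(spec$comparison_positions, times = spec$repetitions)
  if (spec$randomize)
    pos <- with_seed(spec$seed, sample(pos))
  data.frame(trial = seq_along(pos), comparison_deg = pos)
}

#' 2AFC observer response probability
#'
#' Probability of a "right" response for a comparison at `x` degrees under
#' a cumulative-Gaussian observer with lapses:
#' p = lapse/2 + (1 - lapse) * Phi((x - pha) / sigma), where sigma is
#' derived from the JND under the package's JND convention
#' (see [compute_jnd()]).
#'
#' @param x Comparison position(s), degrees.
#' @param observer An [observer_spec()].
#' @param jnd_convention `"sd"` (JND = sigma) or `"p75"`
#'   (JND = 0.6745 sigma).
#' @return Probability vector, same length as `x`.
#' @export
response_probability <- function(x, observer, jnd_convention = c("sd", "p75")) {
  stopifnot(inherits(observer, "observer_spec"))
  sigma <- jnd_to_sigma(observer$jnd, match.arg(jnd_convention))
  observer$lapse_rate / 2 +
    (1 - observer$lapse_rate) * stats::pnorm((x - observer$pha) / sigma)
}

#' Simulate 2AFC responses for a trial schedule
#'
#' Draws one Bernoulli response per trial from the cumulative-Gaussian
#' observer model (see [response_probability()]).
#'
#' @param schedule Data frame with a `comparison_deg` column
#'   (from [generate_trial_schedule()]).
#' @param observer An [observer_spec()].
#' @param seed Integer seed, or `NULL`.
#' @param jnd_convention Passed to [response_probability()].
#' @return `schedule` with an added `response` column (`"left"`/`"right"`).
#' @export
simulate_responses <- function(schedule, observer, seed = NULL,
                               jnd_convention = c("sd", "p75")) {
  stopifnot(is.data.frame(schedule), "comparison_deg" %in% names(schedule))
  p <- response_probability(schedule$comparison_deg, observer,
                            match.arg(jnd_convention))
  schedule$response <- with_seed(seed, {
    ifelse(stats::runif(nrow(schedule)) < p, "right", "left")
  })
  schedule
}

#' Background displacement under a visual velocity gain
#'
#' The grating background moves against the head, scaled by the gain: a
#' rightward head movement of amplitude A under gain g displaces the
#' background by g * A to the left. For example a 20 degree rightward head
#' movement under gain 1.15 shifts the grating 23 degrees to the left.
#'
#' @param head_amplitude Unsigned head-movement amplitude, degrees.
#' @param gain Visual velocity gain (>= 0).
#' @param direction Head-movement direction sign (+1 rightward).
#' @return Signed background displacement in degrees (opposite sign to the
#'   head movement).
#' @examples
#' apply_velocity_gain(20, 1.15, +1)  # -23
#' @export
apply_velocity_gain <- function(head_amplitude, gain, direction = 1) {
  if (any(gain < 0)) stop("'gain' must be >= 0")
  -direction * gain * head_amplitude
}
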