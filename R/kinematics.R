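#' Instantaneous angular velocity of a trace
#'
#' Time-based first differences:
#' v\[i\] = (angle\[i+1\] - angle\[i\]) / (time\[i+1\] - time\[i\]).
#' Using the recorded timestamps (not sample indices) keeps the estimate
#' correct under recorder jitter.
#'
#' @param trace A [sampled_trace()].
#' @return Numeric velocity series in deg/s, length `length(trace) - 1`;
#'   element i covers the interval starting at `trace$times[i]`.
#' @export
compute_velocity <- function(trace) {
  assert_trace(trace)
  dt <- diff(trace$times)
  if (any(dt == 0)) stop("duplicate timestamps in trace")
  diff(trace$angles) / dt
}

#' Forward moving-average smoothing of a velocity series
#'
#' Each output value is the mean of the `window` consecutively following
#' input values (the value at i and its window - 1 successors). Where
#' fewer than `window` samples remain at the tail, the available samples
#' are averaged (shrinking window), which avoids phantom onsets that
#' zero-padding would create.
#'
#' @param v Numeric velocity series, deg/s.
#' @param window Window length in samples (>= 1), default 10.
#' @return Smoothed series, same length as `v`.
#' @export
smooth_velocity <- function(v, window = 10L) {
  if (length(v) == 0) stop("empty velocity series")
  if (window < 1) stop("'window' must be >= 1")
  n <- length(v)
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  last <- pmin(i + window - 1L, n)
  (cs[last + 1L] - cs[i]) / (last - i + 1L)
}

#' Detect the head movement in a yaw trace
#'
#' Velocity-threshold event detection: velocity is computed by time-based
#' first differences and smoothed with a forward moving average
#' (default 10 samples). The movement peak is the maximum of the absolute
#' smoothed velocity; onset is the last sample before the peak where the
#' smoothed speed falls below `threshold` (default 3 deg/s), offset the
#' first such sample after the peak. Events whose smoothed speed never
#' exceeds the threshold, or whose amplitude is below `min_amplitude`
#' (default 10 degrees, half the nominal 20-degree gaze shift), are
#' flagged invalid with an exclusion reason rather than raising an error.
#'
#' When a trace contains several suprathreshold lobes, the event around
#' the global speed peak is returned and the number of additional lobes is
#' reported in `n_extra_lobes`.
#'
#' @param trace A head [sampled_trace()].
#' @param threshold Speed criterion for onset/offset, deg/s.
#' @param window Smoothing window in samples.
#' @param min_amplitude Minimum valid amplitude, degrees.
#' @return An object of class `head_movement_event`: onset/offset/peak
#'   times (s), peak velocity (deg/s, smoothed magnitude), unsigned
#'   `amplitude` and signed `displacement` (deg), `duration_ms`, `valid`,
#'   `exclusion_reason` (`"none"`, `"below_velocity_threshold"` or
#'   `"amplitude_below_10deg"`), and `n_extra_lobes`.
#' @export
detect_head_movement <- function(trace, threshold = 3, window = 10L,
                                 min_amplitude = 10) {
  assert_trace(trace)
  sv <- smooth_velocity(compute_velocity(trace), window)
  speed <- abs(sv)
  nv <- length(sv)
  peak_idx <- which.max(speed)

  if (speed[peak_idx] <= threshold) {
    return(new_head_event(valid = FALSE,
                          exclusion_reason = "below_velocity_threshold",
                          peak_velocity = speed[peak_idx],
                          peak_time = trace$times[peak_idx]))
  }
  below <- speed < threshold
  onset_idx <- {
    prior <- which(below[seq_len(peak_idx - 1L)])
    if (length(prior)) prior[length(prior)] else 1L
  }
  offset_idx <- {
    post <- which(below) # first below-threshold sample after the peak
    post <- post[post > peak_idx]
    if (length(post)) post[1L] else length(trace$times)
  }
  displacement <- trace$angles[offset_idx] - trace$angles[onset_idx]
  amplitude <- abs(displacement)

  # count suprathreshold lobes other than the one containing the peak
  runs <- rle(!below)
  n_lobes <- sum(runs$values)
  n_extra <- n_lobes - 1L

  valid <- amplitude >= min_amplitude
  new_head_event(
    onset_time = trace$times[onset_idx],
    offset_time = trace$times[offset_idx],
    peak_time = trace$times[peak_idx],
    peak_velocity = speed[peak_idx],
    amplitude = amplitude,
    displacement = displacement,
    duration_ms = 1000 * (trace$times[offset_idx] - trace$times[onset_idx]),
    valid = valid,
    exclusion_reason = if (valid) "none" else "amplitude_below_10deg",
    n_extra_lobes = n_extra)
}

new_head_event <- function(onset_time = NA_real_, offset_time = NA_real_,
                           peak_time = NA_real_, peak_velocity = NA_real_,
                           amplitude = NA_real_, displacement = NA_real_,
                           duration_ms = NA_real_, valid = FALSE,
                           exclusion_reason = "none",
                           n_extra_lobes = 0L) {
  structure(list(onset_time = onset_time, offset_time = offset_time,
                 peak_time = peak_time, peak_velocity = peak_velocity,
                 amplitude = amplitude, displacement = displacement,
                 duration_ms = duration_ms, valid = valid,
                 exclusion_reason = exclusion_reason,
                 n_extra_lobes = n_extra_lobes),
            class = "head_movement_event")
}

#' @export
print.head_movement_event <- function(x, ...) {
  if (x$valid) {
    cat(sprintf(paste0(
      "<head_movement_event> valid: %.2f deg in %.0f ms, ",
      "peak %.2f deg/s at %.3f s\n"),
      x$amplitude, x$duration_ms, x$peak_velocity, x$peak_time))
  } else {
    cat(sprintf("<head_movement_event> excluded (%s)\n",
                x$exclusion_reason))
  }
  invisible(x)
}

#' @export
as.data.frame.head_movement_event <- function(x, ...) {
  data.frame(onset_time = x$onset_time, offset_time = x$offset_time,
             peak_time = x$peak_time, peak_velocity = x$peak_velocity,
             amplitude = x$amplitude, displacement = x$displacement,
             duration_ms = x$duration_ms, valid = x$valid,
             exclusion_reason = x$exclusion_reason,
             n_extra_lobes = x$n_extra_lobes)
}

#' Simulated recovery of the head-movement main sequence
#'
#' End-to-end recovery study for the kinematics pipeline: generates
#' `n_events` seeded raised-cosine head movements with amplitudes uniform
#' on `amplitude_range` and peak velocities on the line
#' `ms_intercept + ms_slope x amplitude` plus Gaussian noise, runs each
#' trace through velocity computation, smoothing and threshold detection
#' (including the minimum-amplitude exclusion), and fits the main
#' sequence by OLS on the detected events.
#'
#' @param n_events Number of simulated movements.
#' @param seed Integer seed.
#' @param amplitude_range Amplitude bounds, degrees.
#' @param ms_intercept,ms_slope Generating main-sequence line
#'   (deg/s, deg/s per deg).
#' @param velocity_noise_sd SD of Gaussian noise on the generating peak
#'   velocity, deg/s.
#' @param sample_rate Head sampling rate, Hz.
#' @return A list with the `main_sequence_fit` (`fit`), its coefficient
#'   standard errors (`se`, from the OLS fit), the detected events data
#'   frame (`events`) and the number of excluded traces (`n_excluded`).
#' @export
main_sequence_recovery <- function(n_events = 500, seed = 1,
                                   amplitude_range = c(10, 30),
                                   ms_intercept = 13.22, ms_slope = 1.27,
                                   velocity_noise_sd = 3,
                                   sample_rate = 913.68) {
  amps <- with_seed(seed, stats::runif(n_events, amplitude_range[1],
                                       amplitude_range[2]))
  seeds <- with_seed(seed + 1L, sample.int(2147483646, n_events))
  events <- lapply(seq_len(n_events), function(i) {
    tr <- generate_head_trace(
      head_movement_spec(amps[i], ms_intercept = ms_intercept,
                         ms_slope = ms_slope,
                         velocity_noise_sd = velocity_noise_sd,
                         sample_rate = sample_rate),
      duration = 2.8, onset_time = 0.5, seed = seeds[i])
    as.data.frame(detect_head_movement(tr))
  })
  events <- do.call(rbind, events)
  fit <- fit_main_sequence(events)
  lmfit <- stats::lm(peak_velocity ~ amplitude,
                     data = events[events$valid, ])
  se <- summary(lmfit)$coefficients[, "Std. Error"]
  list(fit = fit, se = c(intercept = unname(se[1]), slope = unname(se[2])),
       events = events, n_excluded = sum(!events$valid))
}

#' Fit the head-movement main sequence
#'
#' Ordinary least squares of peak velocity on amplitude over the valid
#' events, the linear amplitude/peak-velocity relationship that
#' stereotyped gaze-shift kinematics follow.
#'
#' @param events A list of `head_movement_event` objects, or a data frame
#'   with columns `amplitude`, `peak_velocity` and `valid`.
#' @return Object of class `main_sequence_fit` with `slope` (deg/s per
#'   deg), `intercept` (deg/s), `n_events` and `residual_sd`.
#' @seealso [detect_head_movement()]
#' @export
fit_main_sequence <- function(events) {
  df <- if (is.data.frame(events)) events
        else do.call(rbind, lapply(events, as.data.frame))
  df <- df[df$valid, , drop = FALSE]
  if (nrow(df) < 2) stop("need at least 2 valid events")
  if (length(unique(df$amplitude)) < 2)
    stop("all amplitudes identical; main sequence is undefined")
  fit <- stats::lm(peak_velocity ~ amplitude, data = df)
  # suppress the "essentially perfect fit" note: exactly colinear events
  # are legitimate input here
  res_sd <- if (nrow(df) > 2) suppressWarnings(summary(fit)$sigma) else 0
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n_events = nrow(df), residual_sd = res_sd,
                 data = df[, c("amplitude", "peak_velocity")]),
            class = "main_sequence_fit")
}

#' @export
print.main_sequence_fit <- function(x, ...) {
  cat(sprintf(
    "<main_sequence_fit> peak velocity = %.2f + %.2f x amplitude (n = %d, residual SD %.2f deg/s)\n",
    x$intercept, x$slope, x$n_events, x$residual_sd))
  invisible(x)
}

#' @export
coef.main_sequence_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.main_sequence_fit <- function(object, amplitude, ...) {
  object$intercept + object$slope * amplitude
}

#' @export
plot.main_sequence_fit <- function(x, ...) {
  graphics::plot(x$data$amplitude, x$data$peak_velocity,
                 xlab = "amplitude (deg)", ylab = "peak velocity (deg/s)",
                 main = "Head-movement main sequence", ...)
  graphics::abline(x$intercept, x$slope, col = "red3", lwd = 2)
  invisible(x)
}
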