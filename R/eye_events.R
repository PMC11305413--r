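#' Detect saccades in a low-rate gaze trace
#'
#' Amplitude-difference saccade detection suited to 120 Hz eye tracking,
#' where classical velocity criteria are unreliable. The scan works on
#' amplitude changes between individual consecutive data points,
#' irrespective of the time elapsed between them:
#'
#' * onset: the data point immediately preceding the first consecutive
#'   difference of at least `onset_criterion` (1 degree);
#' * offset: the earliest data point recorded at least `min_latency`
#'   (30 ms) after the onset that deviates less than `offset_criterion`
#'   (0.1 degree) from its previous data point.
#'
#' Scanning resumes after each offset, so events are non-overlapping and
#' time-ordered. If the offset criterion is never met the event closes at
#' the final sample and is flagged `truncated`.
#'
#' @param trace A gaze [sampled_trace()].
#' @param onset_criterion Consecutive-sample difference that opens an
#'   event, degrees.
#' @param offset_criterion Consecutive-sample deviation below which the
#'   event closes, degrees.
#' @param min_latency Minimum onset-to-offset latency, seconds.
#' @return Data frame with one row per saccade: `onset_idx`, `offset_idx`,
#'   `onset_time`, `offset_time` (s), signed `amplitude`
#'   (offset minus onset position, deg) and `truncated`. Zero rows when
#'   no saccade is found or the trace is shorter than `min_latency`.
#' @export
detect_saccades <- function(trace, onset_criterion = 1,
                            offset_criterion = 0.1, min_latency = 0.030) {
  assert_trace(trace)
  x <- trace$angles
  tt <- trace$times
  n <- length(x)
  empty <- data.frame(onset_idx = integer(0), offset_idx = integer(0),
                      onset_time = numeric(0), offset_time = numeric(0),
                      amplitude = numeric(0), truncated = logical(0))
  if (tt[n] - tt[1] < min_latency) return(empty)

  d <- abs(diff(x))
  out <- list()
  i <- 1L
  while (i <= n - 1L) {
    if (d[i] >= onset_criterion) {
      onset <- i
      # candidate offsets: settled samples at least min_latency later
      j <- onset + 1L
      offset <- NA_integer_
      while (j <= n) {
        if (tt[j] - tt[onset] >= min_latency &&
            abs(x[j] - x[j - 1L]) < offset_criterion) {
          offset <- j
          break
        }
        j <- j + 1L
      }
      truncated <- is.na(offset)
      if (truncated) offset <- n
      out[[length(out) + 1L]] <- data.frame(
        onset_idx = onset, offset_idx = offset,
        onset_time = tt[onset], offset_time = tt[offset],
        amplitude = x[offset] - x[onset], truncated = truncated)
      i <- offset
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

#' Target-fixation fraction during a head movement
#'
#' Fraction of the head-movement interval during which gaze dwells on the
#' gaze-shift target: within `window` degrees of `target_position` and not
#' inside a detected saccade. Dwell time is accumulated from inter-sample
#' intervals, clipped to the head-movement interval. A low fixation
#' fraction means many eye movements were made during the head-movement
#' component of the gaze shift.
#'
#' @param gaze A gaze [sampled_trace()] covering the head-movement
#'   interval.
#' @param head_event A valid `head_movement_event`
#'   (see [detect_head_movement()]).
#' @param target_position Target eccentricity, degrees.
#' @param window Fixation tolerance around the target, degrees
#'   (default 1, matching the trial-control fixation window).
#' @param saccades Optional precomputed [detect_saccades()] table for
#'   `gaze`; detected on the fly when `NULL`.
#' @return Object of class `fixation_metric`: `fixation_fraction`
#'   (percent, in \[0, 100\]), `n_saccades_during`, and the `head_event`.
#' @export
fixation_duration <- function(gaze, head_event, target_position,
                              window = 1.0, saccades = NULL) {
  assert_trace(gaze)
  stopifnot(inherits(head_event, "head_movement_event"))
  if (!head_event$valid)
    stop("head_event is not a valid movement (", head_event$exclusion_reason, ")")
  t0 <- head_event$onset_time
  t1 <- head_event$offset_time
  if (!any(gaze$times >= t0 & gaze$times <= t1))
    stop("no gaze samples inside the head-movement interval")
  if (is.null(saccades)) saccades <- detect_saccades(gaze)

  n <- length(gaze$times)
  seg_start <- gaze$times[-n]
  seg_end <- gaze$times[-1L]
  lo <- pmax(seg_start, t0)
  hi <- pmin(seg_end, t1)
  dur <- pmax(hi - lo, 0)

  on_target <- abs(gaze$angles[-n] - target_position) <= window
  in_saccade <- rep(FALSE, n - 1L)
  if (nrow(saccades)) {
    for (k in seq_len(nrow(saccades))) {
      in_saccade <- in_saccade |
        (seg_start >= saccades$onset_time[k] &
           seg_start < saccades$offset_time[k])
    }
  }
  dwell <- sum(dur[on_target & !in_saccade])
  frac <- 100 * dwell / (t1 - t0)
  structure(list(
    fixation_fraction = min(max(frac, 0), 100),
    n_saccades_during = sum(saccades$onset_time >= t0 &
                              saccades$onset_time <= t1),
    head_event = head_event), class = "fixation_metric")
}

#' @export
print.fixation_metric <- function(x, ...) {
  cat(sprintf(
    "<fixation_metric> %.1f%% of the head movement on target (%d saccades during)\n",
    x$fixation_fraction, x$n_saccades_during))
  invisible(x)
}

#' Primary-saccade amplitude per trial
#'
#' For each trial, the amplitude of the primary saccade — the detected
#' saccade with the largest absolute amplitude. Trials without any
#' detected saccade are flagged missing and carry `NA`, so they can be
#' excluded from amplitude summaries.
#'
#' @param saccades Data frame of detected saccades with a `trial` column
#'   and an `amplitude` column (e.g. row-bound [detect_saccades()] output).
#' @param trials Vector of all trial identifiers; defaults to the trials
#'   present in `saccades`.
#' @return Data frame with `trial`, signed `primary_amplitude` (deg) and
#'   `missing`.
#' @export
saccade_amplitude_summary <- function(saccades,
                                      trials = sort(unique(saccades$trial))) {
  stopifnot(is.data.frame(saccades),
            all(c("trial", "amplitude") %in% names(saccades)))
  prim <- vapply(trials, function(tr) {
    a <- saccades$amplitude[saccades$trial == tr]
    if (length(a) == 0) NA_real_ else a[which.max(abs(a))]
  }, numeric(1))
  data.frame(trial = trials, primary_amplitude = prim,
             missing = is.na(prim))
}
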