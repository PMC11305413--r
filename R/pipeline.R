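#' Configuration for a full simulated experiment run
#'
#' Bundles every tunable constant of the pipeline. The detection and
#' fitting defaults are the analysis constants used throughout the
#' package: 3 deg/s velocity criterion, 10-degree minimum head-movement
#' amplitude, 10-sample smoothing window, 1-degree saccade onset and
#' 0.1-degree offset criteria, 30 ms minimum saccade latency, 1-degree
#' fixation window, and the +/- 1.37-degree comparison-stimulus range.
#'
#' @param experiment Preset 1 (eye-head gaze shifts, 2x2x2 conditions),
#'   2 (eye-only, 2x2) or 3 (velocity gains, 2 modes x 3 gains).
#' @param n_subjects Number of simulated participants.
#' @param seed Global seed; all per-subject/per-trial streams are derived
#'   from it deterministically.
#' @param out_dir Output directory for the result tables, or `NULL` to
#'   keep results in memory only.
#' @param simulate_traces Generate and analyse head/gaze traces per trial
#'   (slower); when `FALSE` only schedules, responses and fits are run.
#' @param velocity_threshold,min_head_amplitude,smooth_window Head
#'   detection constants (deg/s, deg, samples).
#' @param saccade_onset,saccade_offset,min_latency Saccade detection
#'   constants (deg, deg, s).
#' @param fixation_window Target-fixation tolerance, deg.
#' @param stimulus_range Inclusion half-range for the PHA, deg.
#' @param jnd_convention `"sd"` or `"p75"` (see [compute_jnd()]).
#' @param tails Tail convention for the gain-slope tests.
#' @param gains Visual velocity gains of the experiment-3 preset.
#' @param head_rate,eye_rate Sample rates, Hz.
#' @param repetitions Repetitions per comparison position.
#' @param comparison_positions Comparison offsets, deg.
#' @param true_gain_slope_unrestricted,true_gain_slope_sequential
#'   Generating PHA slope per unit gain for the two modes (deg).
#' @return A `run_config` list.
#' @export
run_config <- function(experiment = 1, n_subjects = 24, seed = 1,
                       out_dir = NULL, simulate_traces = TRUE,
                       velocity_threshold = 3, min_head_amplitude = 10,
                       smooth_window = 10L, saccade_onset = 1,
                       saccade_offset = 0.1, min_latency = 0.030,
                       fixation_window = 1, stimulus_range = 1.37,
                       jnd_convention = "sd", tails = "one",
                       gains = c(1, 1.15, 1.3),
                       head_rate = 913.68, eye_rate = 120,
                       repetitions = 8,
                       comparison_positions =
                         c(-1.37, -0.92, -0.46, 0, 0.46, 0.92, 1.37),
                       true_gain_slope_unrestricted = 0.5,
                       true_gain_slope_sequential = 0) {
  if (!experiment %in% 1:3) stop("'experiment' must be 1, 2 or 3")
  if (n_subjects < 2) stop("need at least 2 subjects")
  structure(as.list(environment()), class = "run_config")
}

# deterministic substream derivation with Lehmer-style mixing so that
# neighbouring (i, j) pairs land on well-separated streams; result stays
# below 2^31 (exact in double arithmetic: intermediates < 2^53)
derive_seed <- function(seed, i, j = 0L) {
  x <- (as.numeric(seed) %% 2147483647 + i * 40503 + j * 104729) %%
    2147483647
  x <- (x * 48271) %% 2147483647
  x <- ((x + 1) * 69621) %% 2147483647
  as.integer(x)
}

condition_grid <- function(config) {
  grid <- switch(as.character(config$experiment),
    "1" = expand.grid(gaze_mode = c("unrestricted", "sequential"),
                      target_presentation = c("stationary", "flashed"),
                      background = c("grating", "none"),
                      gain = 1, stringsAsFactors = FALSE),
    "2" = expand.grid(gaze_mode = "eye_only",
                      target_presentation = c("stationary", "flashed"),
                      background = c("grating", "none"),
                      gain = 1, stringsAsFactors = FALSE),
    "3" = expand.grid(gaze_mode = c("unrestricted", "sequential"),
                      target_presentation = "stationary",
                      background = "grating",
                      gain = config$gains, stringsAsFactors = FALSE))
  grid$condition <- seq_len(nrow(grid))
  grid
}

# generating observer for one subject x condition: small, plausible
# condition effects on PHA and JND around per-subject baselines
true_observer <- function(config, subj_base_pha, subj_base_jnd, cond) {
  pha <- subj_base_pha +
    0.12 * (cond$target_presentation == "stationary") +
    0.09 * (cond$background == "grating")
  if (config$experiment == 3) {
    slope <- if (cond$gaze_mode == "unrestricted")
      config$true_gain_slope_unrestricted
    else config$true_gain_slope_sequential
    pha <- pha + slope * (cond$gain - 1)
  }
  jnd <- subj_base_jnd * if (cond$target_presentation == "flashed") 1.25 else 1
  observer_spec(pha = pha, jnd = jnd)
}

#' Run a full simulated gaze-shift experiment
#'
#' Orchestrates simulate -> detect -> fit -> stats as one reproducible,
#' seeded run: per subject and condition it generates a balanced trial
#' schedule, simulates 2AFC responses from a generating observer,
#' optionally synthesizes and analyses head and gaze traces (head-movement
#' detection, saccade detection, fixation fraction, exclusion rules), fits
#' psychometric functions, and runs the experiment's inferential tests.
#' Re-running with the same config gives bit-identical outputs.
#'
#' @param config A [run_config()].
#' @return A `gazeshift_run` list: `trials`, `fits`, `events` (head
#'   events + fixation metrics, when traces are simulated), `stats`
#'   (rm-ANOVAs; for experiment 3 also gain slopes and slope tests),
#'   `excluded` (trial-exclusion summary) and `manifest`. When
#'   `config$out_dir` is set the tables are also written there as
#'   delimited text plus a JSON manifest.
#' @examples
#' \donttest{
#' run <- run_experiment(run_config(experiment = 3, n_subjects = 4,
#'                                  seed = 7, simulate_traces = FALSE))
#' run$stats$slope_test_unrestricted
#' }
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  grid <- condition_grid(config)
  base <- with_seed(derive_seed(config$seed, 0L), list(
    pha = stats::rnorm(config$n_subjects, 0, 0.15),
    jnd = exp(stats::rnorm(config$n_subjects, log(0.8), 0.15))))

  trials_all <- list(); fits_all <- list(); events_all <- list()
  n_excluded <- 0L; n_traced <- 0L
  for (s in seq_len(config$n_subjects)) {
    for (ci in seq_len(nrow(grid))) {
      cond <- grid[ci, ]
      sched <- generate_trial_schedule(trial_schedule_spec(
        comparison_positions = config$comparison_positions,
        repetitions = config$repetitions, randomize = TRUE,
        seed = derive_seed(config$seed, s, ci)))
      obs <- true_observer(config, base$pha[s], base$jnd[s], cond)
      tr <- simulate_responses(sched, obs,
                               seed = derive_seed(config$seed, s, ci + 100L),
                               jnd_convention = config$jnd_convention)
      tr$subject <- s
      tr$gaze_mode <- cond$gaze_mode
      tr$target_presentation <- cond$target_presentation
      tr$background <- cond$background
      tr$gain <- cond$gain
      tr$condition <- ci

      if (config$simulate_traces && cond$gaze_mode != "eye_only") {
        ev <- simulate_trial_traces(config, cond, s, ci, tr)
        events_all[[length(events_all) + 1L]] <- ev
        n_excluded <- n_excluded + sum(!ev$head_valid)
        n_traced <- n_traced + nrow(ev)
      }

      fit <- fit_psychometric(tabulate_responses(tr),
                              jnd_convention = config$jnd_convention,
                              stimulus_range = config$stimulus_range)
      fits_all[[length(fits_all) + 1L]] <- data.frame(
        subject = s, condition = ci, gaze_mode = cond$gaze_mode,
        target_presentation = cond$target_presentation,
        background = cond$background, gain = cond$gain,
        pha_deg = fit$pha, jnd_deg = fit$jnd,
        converged = fit$converged, included = fit$included)
      trials_all[[length(trials_all) + 1L]] <- tr
    }
  }
  trials <- do.call(rbind, trials_all)
  fits <- do.call(rbind, fits_all)
  events <- if (length(events_all)) do.call(rbind, events_all) else NULL

  stats_out <- run_stats(config, fits)
  manifest <- list(
    package = "gazeshift",
    version = as.character(utils::packageVersion("gazeshift")),
    experiment = config$experiment, n_subjects = config$n_subjects,
    seed = config$seed, n_conditions = nrow(grid),
    conditions = grid, n_trials = nrow(trials), n_fits = nrow(fits),
    n_traced_trials = n_traced, n_excluded_trials = n_excluded,
    exclusion_rate_pct = if (n_traced > 0)
      100 * n_excluded / n_traced else NA)

  out <- structure(list(trials = trials, fits = fits, events = events,
                        stats = stats_out, manifest = manifest),
                   class = "gazeshift_run")
  if (!is.null(config$out_dir)) write_run(out, config)
  out
}

# per-trial trace synthesis + detection for one subject x condition
simulate_trial_traces <- function(config, cond, s, ci, tr) {
  rows <- vector("list", nrow(tr))
  scen <- gaze_shift_scenario(
    gaze_mode = cond$gaze_mode,
    target_presentation = cond$target_presentation,
    background = cond$background, visual_velocity_gain = cond$gain)
  for (k in seq_len(nrow(tr))) {
    sd_k <- derive_seed(config$seed, s * 7L + ci, k + 200L)
    amp <- with_seed(sd_k, min(max(stats::rnorm(1, 18.8, 2.5), 5), 30))
    sac_amp <- with_seed(sd_k + 3L,
                         min(max(stats::rnorm(1, 18, 0.5), 16), 19.5))
    head <- generate_head_trace(
      head_movement_spec(amplitude = amp, sample_rate = config$head_rate),
      duration = 2.4, onset_time = 0.6, seed = sd_k + 1L)
    gaze <- generate_gaze_trace(
      scen, head, saccade_amplitude = sac_amp,
      seed = sd_k + 2L, eye_rate = config$eye_rate)
    ev <- detect_head_movement(head,
                               threshold = config$velocity_threshold,
                               window = config$smooth_window,
                               min_amplitude = config$min_head_amplitude)
    sac <- detect_saccades(gaze, onset_criterion = config$saccade_onset,
                           offset_criterion = config$saccade_offset,
                           min_latency = config$min_latency)
    fx <- if (ev$valid)
      fixation_duration(gaze, ev, target_position = 10,
                        window = config$fixation_window, saccades = sac)
    else NULL
    rows[[k]] <- data.frame(
      subject = s, condition = ci, trial = tr$trial[k],
      head_valid = ev$valid, head_exclusion = ev$exclusion_reason,
      head_amplitude = ev$amplitude, head_peak_velocity = ev$peak_velocity,
      head_duration_ms = ev$duration_ms,
      n_saccades = nrow(sac),
      primary_saccade_amplitude = if (nrow(sac))
        sac$amplitude[which.max(abs(sac$amplitude))] else NA_real_,
      fixation_fraction = if (!is.null(fx)) fx$fixation_fraction
      else NA_real_)
  }
  do.call(rbind, rows)
}

run_stats <- function(config, fits) {
  out <- list()
  ok <- fits[fits$converged, , drop = FALSE]
  if (config$experiment %in% 1:2) {
    facs <- c("target_presentation", "background")
    if (config$experiment == 1) facs <- c(facs, "gaze_mode")
    complete <- stats::aggregate(converged ~ subject, fits, all)
    keep <- complete$subject[complete$converged]
    sub <- ok[ok$subject %in% keep, , drop = FALSE]
    if (length(unique(sub$subject)) >= 2) {
      out$anova_pha <- rm_anova(sub, "pha_deg", "subject", facs)
      out$anova_jnd <- rm_anova(sub, "jnd_deg", "subject", facs)
    }
  } else {
    for (mode in c("unrestricted", "sequential")) {
      m <- ok[ok$gaze_mode == mode, c("subject", "gain", "pha_deg")]
      names(m)[3] <- "pha"
      full <- table(m$subject)
      m <- m[m$subject %in% names(full)[full == 3], , drop = FALSE]
      if (length(unique(m$subject)) >= 2) {
        sl <- fit_gain_slopes(m)
        out[[paste0("slopes_", mode)]] <- sl
        out[[paste0("slope_test_", mode)]] <-
          slopes_vs_zero(sl, tails = config$tails)
      }
    }
    complete <- stats::aggregate(converged ~ subject, fits, all)
    keep <- complete$subject[complete$converged]
    sub <- ok[ok$subject %in% keep, , drop = FALSE]
    if (length(unique(sub$subject)) >= 2) {
      sub$gain <- factor(sub$gain)
      out$anova_pha <- rm_anova(sub, "pha_deg", "subject",
                                c("gaze_mode", "gain"))
    }
  }
  out
}

write_run <- function(run, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  write_trials(run$trials, p("trials.csv"))
  utils::write.csv(run$fits, p("fits.csv"), row.names = FALSE)
  if (!is.null(run$events))
    utils::write.csv(run$events, p("events.csv"), row.names = FALSE)
  if (!is.null(run$stats$anova_pha))
    utils::write.csv(as.data.frame(run$stats$anova_pha),
                     p("anova_pha.csv"), row.names = FALSE)
  jsonlite::write_json(run$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

#' @export
print.gazeshift_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<gazeshift_run> experiment %d: %d subjects x %d conditions, %d trials (seed %s)\n",
    m$experiment, m$n_subjects, m$n_conditions, m$n_trials, m$seed))
  if (m$n_traced_trials > 0)
    cat(sprintf("  traces analysed: %d trials, %.2f%% excluded\n",
                m$n_traced_trials, m$exclusion_rate_pct))
  cat(sprintf("  psychometric fits: %d (%d converged, %d included)\n",
              nrow(x$fits), sum(x$fits$converged), sum(x$fits$included)))
  invisible(x)
}
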