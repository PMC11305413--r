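# Independent brute-force oracles, written directly from the detection
# rules and classical formulas. Deliberately loop-based and naive; they
# share no code path with the package implementation.

# Head-movement scan: first-difference velocity, forward moving average
# with shrinking tail, peak of absolute smoothed speed, then a backward /
# forward scan for the last / first sample below the speed criterion.
oracle_head_event <- function(times, angles, threshold = 3, window = 10,
                              min_amplitude = 10) {
  n <- length(angles)
  v <- numeric(n - 1)
  for (i in 1:(n - 1))
    v[i] <- (angles[i + 1] - angles[i]) / (times[i + 1] - times[i])
  sv <- numeric(n - 1)
  for (i in 1:(n - 1)) {
    j <- min(i + window - 1, n - 1)
    sv[i] <- mean(v[i:j])
  }
  peak <- 1
  for (i in seq_along(sv)) if (abs(sv[i]) > abs(sv[peak])) peak <- i
  if (abs(sv[peak]) <= threshold)
    return(list(valid = FALSE, reason = "below_velocity_threshold",
                onset = NA, offset = NA, peak = peak))
  onset <- 1
  if (peak > 1)
    for (i in 1:(peak - 1)) if (abs(sv[i]) < threshold) onset <- i
  offset <- n
  if (peak < length(sv)) {
    for (i in (peak + 1):length(sv)) {
      if (abs(sv[i]) < threshold) { offset <- i; break }
    }
  }
  amp <- abs(angles[offset] - angles[onset])
  list(valid = amp >= min_amplitude,
       reason = if (amp >= min_amplitude) "none" else "amplitude_below_10deg",
       onset = onset, offset = offset, peak = peak, amplitude = amp)
}

# Saccade scan: consecutive-sample differences; onset is the sample before
# the first difference of at least 1 degree; offset the earliest sample at
# least 30 ms later deviating under 0.1 degree from its predecessor.
oracle_saccades <- function(times, angles, onset_crit = 1,
                            offset_crit = 0.1, latency = 0.030) {
  n <- length(angles)
  res <- NULL
  if (times[n] - times[1] < latency)
    return(data.frame(onset_idx = integer(0), offset_idx = integer(0)))
  i <- 1
  while (i <= n - 1) {
    if (abs(angles[i + 1] - angles[i]) >= onset_crit) {
      on <- i
      off <- NA
      for (j in (on + 1):n) {
        if (times[j] - times[on] >= latency &&
            abs(angles[j] - angles[j - 1]) < offset_crit) { off <- j; break }
      }
      if (is.na(off)) off <- n
      res <- rbind(res, data.frame(onset_idx = on, offset_idx = off))
      i <- off
    } else {
      i <- i + 1
    }
  }
  if (is.null(res)) data.frame(onset_idx = integer(0), offset_idx = integer(0))
  else res
}

# Dense grid-search maximum likelihood for the cumulative-Gaussian
# psychometric model.
oracle_grid_mle <- function(tab, mu_grid = seq(-2, 2, length.out = 200),
                            sigma_grid = seq(0.1, 3, length.out = 200)) {
  best <- list(ll = -Inf, mu = NA, sigma = NA)
  for (mu in mu_grid) {
    for (sg in sigma_grid) {
      p <- pnorm((tab$position - mu) / sg)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      ll <- sum(tab$n_right * log(p) +
                  (tab$n_total - tab$n_right) * log(1 - p))
      if (ll > best$ll) best <- list(ll = ll, mu = mu, sigma = sg)
    }
  }
  best
}

# Longhand repeated-measures ANOVA by inclusion-exclusion over effect
# means: for a set of classification columns, the effect term of each
# observation is the alternating-sign sum of its cell means over all
# subsets, and the sum of squares is the sum of squared effect terms.
# F(effect) = MS(effect) / MS(effect x subject).
oracle_rm_anova <- function(d, dv, subject, factors) {
  y <- d[[dv]]
  m <- function(cols) {
    if (length(cols) == 0) return(rep(mean(y), length(y)))
    key <- do.call(paste, c(d[cols], list(sep = "\r")))
    ave(y, key, FUN = mean)
  }
  eterm <- function(cols) {
    tot <- rep(0, length(y))
    for (k in 0:length(cols)) {
      for (u in combn_list(cols, k)) {
        tot <- tot + (-1)^(length(cols) - k) * m(u)
      }
    }
    tot
  }
  ss <- function(cols) sum(eterm(cols)^2)
  nsub <- length(unique(d[[subject]]))
  out <- NULL
  for (k in 1:length(factors)) {
    for (eff in combn_list(factors, k)) {
      df_eff <- prod(vapply(eff, function(f)
        length(unique(d[[f]])) - 1, numeric(1)))
      ss_eff <- ss(eff)
      ss_err <- ss(c(eff, subject))
      df_err <- df_eff * (nsub - 1)
      Fv <- (ss_eff / df_eff) / (ss_err / df_err)
      out <- rbind(out, data.frame(
        effect = paste(eff, collapse = ":"),
        ss_eff = ss_eff, ss_err = ss_err, df_num = df_eff,
        df_den = df_err, F = Fv,
        p = pf(Fv, df_eff, df_err, lower.tail = FALSE),
        eta = ss_eff / (ss_eff + ss_err)))
    }
  }
  out
}

combn_list <- function(x, k) {
  if (k == 0) return(list(character(0)))
  combn(x, k, simplify = FALSE)
}

# random single-movement head trace for detector equivalence checks
random_head_trace <- function(seed) {
  set.seed(seed)
  rate <- sample(c(120, 250, 913.68), 1)
  dur <- runif(1, 0.8, if (rate > 500) 3 else 8)
  n_target <- floor(dur * rate) + 1
  if (n_target > 1e4) dur <- (1e4 - 1) / rate
  amp <- runif(1, 0, 30)
  kind <- sample(1:3, 1)
  if (kind == 1) { # generated movement, band-limited noise
    spec <- head_movement_spec(amp, sample_rate = rate,
                               position_noise_sd = runif(1, 0, 0.05))
    vp <- 13.22 + 1.27 * amp
    onset <- runif(1, 0.05, max(dur - 2 * amp / max(vp, 1e-6) - 0.05, 0.06))
    tr <- try(generate_head_trace(spec, dur, onset, seed = seed), silent = TRUE)
    if (inherits(tr, "try-error"))
      tr <- generate_head_trace(head_movement_spec(0, sample_rate = rate),
                                dur, 0, seed = seed)
  } else if (kind == 2) { # smooth multi-lobe wiggle
    n <- floor(dur * rate) + 1
    tt <- (seq_len(n) - 1) / rate
    ang <- amp * sin(2 * pi * runif(1, 0.2, 1.2) * tt) *
      exp(-((tt - dur / 2) / (dur / 3))^2)
    tr <- sampled_trace(tt, ang, "head", nominal_rate = rate)
  } else { # slow drift only
    n <- floor(dur * rate) + 1
    tt <- (seq_len(n) - 1) / rate
    ang <- cumsum(rnorm(n, 0, 0.3 / rate)) * rate / 50
    tr <- sampled_trace(tt, ang, "head", nominal_rate = rate)
  }
  tr
}

# random gaze trace with step-like jumps for saccade-detector equivalence
random_gaze_trace <- function(seed) {
  set.seed(seed)
  n <- sample(50:2000, 1)
  tt <- (seq_len(n) - 1) / 120
  ang <- rnorm(n, 0, runif(1, 0, 0.15))
  for (k in seq_len(sample(0:5, 1))) {
    at <- sample(2:n, 1)
    ang[at:n] <- ang[at:n] + runif(1, -20, 20)
  }
  sampled_trace(tt, ang, "gaze", nominal_rate = 120)
}
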