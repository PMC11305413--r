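# Velocity computation, smoothing and head-movement detection

test_that("first-difference velocity is exact for linear and constant traces", {
  tt <- sort(c(0, cumsum(runif(99, 0.5, 2)) / 100))
  ramp <- sampled_trace(tt, 5 + 10 * tt, "head")
  expect_equal(compute_velocity(ramp), rep(10, 99), tolerance = 1e-10)

  flat <- sampled_trace(tt, rep(2, 100), "head")
  expect_equal(compute_velocity(flat), rep(0, 99))

  dup <- structure(list(times = c(0, 1, 1, 2), angles = c(0, 1, 2, 3),
                        stream = "head", nominal_rate = 1),
                   class = "sampled_trace")
  expect_error(compute_velocity(dup), "duplicate")
})

test_that("raised-cosine movement peak speed matches closed form at 913 Hz", {
  tr <- generate_head_trace(head_movement_spec(20, position_noise_sd = 0),
                            duration = 2, onset_time = 0.4)
  vp <- attr(tr, "truth")$peak_velocity
  expect_equal(max(abs(compute_velocity(tr))), vp, tolerance = 0.01 * vp)
})

test_that("forward moving average matches its definition", {
  expect_equal(smooth_velocity(rep(4, 50), 10), rep(4, 50))

  v <- rep(0, 40); v[25] <- 10
  s <- smooth_velocity(v, 10)
  expect_equal(which(s == 1), 16:25)  # ten values of 1 ending at the impulse
  expect_true(all(s[-(16:25)] == 0))

  # shrinking tail: mean of the remaining samples
  v2 <- 1:20
  s2 <- smooth_velocity(v2, 10)
  expect_equal(s2[20], 20)
  expect_equal(s2[15], mean(15:20))

  # variance reduction by the window length on white noise
  set.seed(7)
  w <- rnorm(20000)
  sw <- smooth_velocity(w, 10)
  expect_equal(var(sw[1:19000]), var(w) / 10, tolerance = 0.05)

  expect_error(smooth_velocity(numeric(0)), "empty")
})

test_that("head-movement detection applies the velocity and amplitude rules", {
  tt <- (0:999) / 913.68
  flat <- sampled_trace(tt, rep(1, 1000), "head")
  ev <- detect_head_movement(flat)
  expect_false(ev$valid)
  expect_equal(ev$exclusion_reason, "below_velocity_threshold")

  small <- generate_head_trace(head_movement_spec(8, position_noise_sd = 0),
                               duration = 1.5, onset_time = 0.3)
  ev8 <- detect_head_movement(small)
  expect_false(ev8$valid)
  expect_equal(ev8$exclusion_reason, "amplitude_below_10deg")

  tr <- generate_head_trace(head_movement_spec(20, position_noise_sd = 0),
                            duration = 2, onset_time = 0.4)
  ev20 <- detect_head_movement(tr)
  expect_true(ev20$valid)
  expect_equal(ev20$exclusion_reason, "none")
  expect_lt(abs(ev20$amplitude - 20), 0.5)
  expect_true(ev20$onset_time < ev20$peak_time)
  expect_true(ev20$peak_time < ev20$offset_time)

  # exact agreement with the brute-force scan
  orc <- oracle_head_event(tr$times, tr$angles)
  expect_equal(ev20$onset_time, tr$times[orc$onset])
  expect_equal(ev20$offset_time, tr$times[orc$offset])
  expect_equal(ev20$peak_time, tr$times[orc$peak])
})

test_that("detector equals the brute-force oracle on random traces", {
  for (seed in 1:60) {
    tr <- random_head_trace(seed)
    ev <- detect_head_movement(tr)
    orc <- oracle_head_event(tr$times, tr$angles)
    expect_equal(ev$valid, orc$valid, info = paste("seed", seed))
    expect_equal(ev$exclusion_reason, orc$reason, info = paste("seed", seed))
    if (orc$valid) {
      expect_equal(ev$onset_time, tr$times[orc$onset],
                   info = paste("seed", seed))
      expect_equal(ev$offset_time, tr$times[orc$offset],
                   info = paste("seed", seed))
    }
    # exclusion totality: valid or exactly one reason
    expect_true(ev$valid || ev$exclusion_reason %in%
                  c("below_velocity_threshold", "amplitude_below_10deg"))
    expect_true(!ev$valid || ev$exclusion_reason == "none")
  }
})

test_that("detected amplitude shrinkage stays within the subthreshold bound", {
  # for a noiseless raised-cosine movement the onset/offset sit where the
  # smoothed speed crosses 3 deg/s, so at most the displacement accrued
  # below that speed (plus a discretization margin) is lost at each end
  for (amp in c(12, 20, 28)) {
    tr <- generate_head_trace(head_movement_spec(amp, position_noise_sd = 0),
                              duration = 3, onset_time = 0.5)
    truth <- attr(tr, "truth")
    vp <- truth$peak_velocity
    D <- 2 * amp / vp
    # time at which the profile reaches the 3 deg/s criterion
    t3 <- (D / (2 * pi)) * acos(1 - 2 * 3 / vp)
    x3 <- (vp / 2) * (t3 - (D / (2 * pi)) * sin(2 * pi * t3 / D))
    margin <- 2 * (10 / 913.68) * 3  # window length x criterion speed
    ev <- detect_head_movement(tr)
    expect_lte(ev$amplitude, amp + 1e-9)
    expect_gte(ev$amplitude, amp - 2 * x3 - margin)
  }
})

test_that("raising the velocity threshold never lengthens the event", {
  for (seed in c(2, 5, 9)) {
    tr <- generate_head_trace(
      head_movement_spec(20, position_noise_sd = 0.03), 2.5, 0.5,
      seed = seed)
    durs <- vapply(c(1, 2, 3, 5, 8), function(th) {
      ev <- detect_head_movement(tr, threshold = th)
      if (ev$valid) ev$duration_ms else 0
    }, numeric(1))
    expect_true(all(diff(durs) <= 1e-9))
  }
})

test_that("main-sequence fit recovers exact and noisy lines", {
  amps <- c(10, 15, 20, 25, 30)
  exact <- data.frame(amplitude = amps,
                      peak_velocity = 13.22 + 1.27 * amps, valid = TRUE)
  fit <- fit_main_sequence(exact)
  expect_equal(fit$slope, 1.27, tolerance = 1e-10)
  expect_equal(fit$intercept, 13.22, tolerance = 1e-10)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-8)

  two <- data.frame(amplitude = c(10, 30),
                    peak_velocity = c(20, 50), valid = TRUE)
  f2 <- fit_main_sequence(two)
  expect_equal(f2$slope, 1.5)
  expect_equal(f2$intercept, 5)
  expect_equal(predict(f2, 20), 35)

  set.seed(21)
  n <- 120
  a <- runif(n, 10, 30)
  v <- 13.22 + 1.27 * a + rnorm(n, 0, 3)
  fn <- fit_main_sequence(data.frame(amplitude = a, peak_velocity = v,
                                     valid = TRUE))
  se <- 3 / (sqrt(n) * sd(a))
  expect_lt(abs(fn$slope - 1.27), 3 * se)

  expect_error(fit_main_sequence(exact[1, , drop = FALSE]), "at least 2")
  same <- data.frame(amplitude = c(20, 20), peak_velocity = c(30, 40),
                     valid = TRUE)
  expect_error(fit_main_sequence(same), "identical")

  # invalid events are excluded from the fit
  mixed <- rbind(exact, data.frame(amplitude = 5, peak_velocity = 200,
                                   valid = FALSE))
  expect_equal(fit_main_sequence(mixed)$slope, 1.27, tolerance = 1e-10)
})

test_that("noise-free generated movements land on the generating line", {
  # main-sequence fidelity of the full generate -> detect path
  amps <- seq(12, 30, by = 3)
  det <- lapply(amps, function(a) {
    tr <- generate_head_trace(head_movement_spec(a, position_noise_sd = 0),
                              duration = 4, onset_time = 0.5)
    as.data.frame(detect_head_movement(tr))
  })
  det <- do.call(rbind, det)
  expect_true(all(det$valid))
  expect_true(all(abs(det$peak_velocity -
                        (13.22 + 1.27 * amps)) < 0.5))
})
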