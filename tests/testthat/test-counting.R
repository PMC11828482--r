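test_that("drift correction inverts a known integer translation", {
  set.seed(4)
  base <- matrix(0, 40, 40)
  base[15:20, 18:24] <- 100
  base <- base + matrix(runif(1600, 0, 1), 40, 40)
  frames <- array(0, c(3, 40, 40))
  frames[1, , ] <- base
  frames[2, , ] <- base
  ## shift frame 3 by (3, -2): content moves down 3 rows, left 2 cols
  shifted <- matrix(0, 40, 40)
  shifted[4:40, 1:38] <- base[1:37, 3:40]
  frames[3, , ] <- shifted
  mv <- az_movie(frames, 0.05, 71, 1)
  out <- correct_drift(mv)
  expect_equal(unname(out$shifts[3, ]), c(-3, 2), tolerance = 0.15)
  expect_equal(unname(out$shifts[1, ]), c(0, 0), tolerance = 0.1)
})

test_that("linear drift is recovered within 0.2 px and statics stay put", {
  set.seed(8)
  cfg0 <- bleach_sim_config(n_az = 4, channels_per_az = 20,
                            unitary_intensity = 100, conversion_rate = 1,
                            bleach_rate = 0.001, blink_off_rate = 0,
                            blink_on_rate = 0, noise_sd = 1,
                            n_frames = 60, uv_onset_frame = 11,
                            drift_per_frame = c(0.05, 0), seed = 2)
  out <- simulate_bleach_movie(cfg0)
  corr <- correct_drift(out$movie)
  ## only frames with converted signal carry registration information;
  ## shifts are relative to the temporal-median reference
  post <- 11:60
  true_dy <- -0.05 * (post - 1)
  est <- corr$shifts[post, 1] - stats::median(corr$shifts[post, 1])
  ref <- true_dy - stats::median(true_dy)
  expect_lt(max(abs(est - ref)), 0.2)

  cfg1 <- bleach_sim_config(n_az = 4, channels_per_az = 20,
                            conversion_rate = 1, bleach_rate = 0.001,
                            blink_off_rate = 0, blink_on_rate = 0,
                            noise_sd = 1, n_frames = 30, uv_onset_frame = 11,
                            seed = 2)
  corr0 <- correct_drift(simulate_bleach_movie(cfg1)$movie)
  expect_lt(max(abs(corr0$shifts[11:30, ])), 0.1)
})

test_that("ROI extraction subtracts background and respects borders", {
  frames <- array(7, c(10, 21, 21))     # uniform value = annulus mean
  mv <- az_movie(frames, 0.05, 71, 1)
  tr <- extract_roi_trace(mv, c(11, 11))
  expect_equal(tr$intensity, rep(0, 10))

  frames2 <- array(0, c(5, 21, 21))
  frames2[, 11, 11] <- 42
  tr2 <- extract_roi_trace(az_movie(frames2, 0.05, 71, 1), c(11, 11))
  expect_equal(tr2$intensity, rep(42, 5))

  expect_error(extract_roi_trace(mv, c(2, 11)), "outside")
})

test_that("noiseless staircases segment exactly and count exactly", {
  tr <- make_staircase(c(0, 300, 200, 100, 0), seg_len = 40, uv_onset = 41)
  sm <- detect_steps(tr)
  expect_equal(sm$change_points, c(41, 81, 121, 161))
  expect_equal(sm$segment_levels, c(0, 300, 200, 100, 0))
  expect_equal(sm$step_amplitudes[-1], rep(-100, 3))
  un <- estimate_unitary_intensity(sm, tr)
  expect_equal(un$unitary, 100)
  est <- count_channels(tr, sm, un$unitary, n_unitary_events = un$n_events)
  expect_identical(est$n_channels, 3)
})

test_that("flat noisy traces yield zero change points at the default penalty", {
  set.seed(11)
  for (i in 1:5) {
    tr <- bleach_trace(rnorm(400, 50, 8), uv_onset_frame = 10)
    expect_length(detect_steps(tr)$change_points, 0)
  }
})

test_that("non-positive penalty is rejected and short traces error", {
  tr <- make_staircase(c(100, 0), 30, uv_onset = 5)
  expect_error(detect_steps(tr, penalty = 0), "penalty")
  short <- bleach_trace(rnorm(25), uv_onset_frame = 20)
  expect_error(detect_steps(short), "20 frames")
})

test_that("step detection at SNR 5 finds 10 steps within +/-1 most of the time", {
  hits <- 0L
  n_cases <- 60L
  for (i in seq_len(n_cases)) {
    set.seed(3000 + i)
    u <- 100
    bounds <- sort(sample(seq(20, 1180, by = 4), 10))
    levels <- seq(10, 0) * u
    x <- rep(levels, diff(c(0, bounds, 1200))) + rnorm(1200, 0, u / 5)
    sm <- detect_steps(bleach_trace(x, uv_onset_frame = 5))
    if (abs(length(sm$change_points) - 10) <= 1) hits <- hits + 1L
  }
  expect_gte(hits / n_cases, 0.8)
})

test_that("unitary estimation isolates the smallest amplitude mode", {
  ## late amplitudes u, u, 2u, u with u = 50 -> unitary 50 from 3 events
  tr <- make_staircase(c(250, 200, 150, 50, 0), c(200, 30, 30, 30, 30),
                       uv_onset = 2)
  sm <- detect_steps(tr)
  un <- estimate_unitary_intensity(sm, tr)
  expect_equal(un$unitary, 50)
  expect_equal(un$n_events, 3L)

  ## all amplitudes identical -> that amplitude, regardless of count
  tr2 <- make_staircase(c(300, 225, 150, 75, 0), c(200, 30, 30, 30, 30),
                        uv_onset = 2)
  un2 <- estimate_unitary_intensity(detect_steps(tr2), tr2)
  expect_equal(un2$unitary, 75)

  ## no late steps -> unavailable with reason
  tr3 <- make_staircase(c(100, 0, 0, 0), 40, uv_onset = 2)
  un3 <- estimate_unitary_intensity(detect_steps(tr3), tr3)
  expect_true(is.na(un3$unitary))
  expect_match(un3$qc, "no single-molecule events")
})

test_that("counting is the peak/unitary ratio with sensible QC", {
  tr <- make_staircase(c(0, 500, 450, 50, 0), 30, uv_onset = 31)
  sm <- detect_steps(tr)
  est <- count_channels(tr, sm, 50)
  expect_equal(est$peak_intensity, 500)
  expect_equal(est$n_channels, 10)
  expect_error(count_channels(tr, sm, 0), "unitary")

  flat <- bleach_trace(rep(0, 200), uv_onset_frame = 20)
  smf <- detect_steps(flat)
  estf <- count_channels(flat, smf, 50)
  expect_equal(estf$n_channels, 0)
  expect_false(estf$qc_pass)
  expect_true("no signal" %in% estf$qc_flags)
})

test_that("scaling a trace leaves the channel count unchanged", {
  set.seed(42)
  tr <- make_staircase(c(0, 400, 300, 200, 100, 0), 50, noise_sd = 10,
                       uv_onset = 51)
  for (c0 in c(0.1, 3, 1e4)) {
    tr_s <- bleach_trace(tr$intensity * c0, tr$times,
                         uv_onset_frame = tr$uv_onset_frame)
    e1 <- count_channels_trace(tr)
    e2 <- count_channels_trace(tr_s)
    expect_equal(e2$unitary_intensity, e1$unitary_intensity * c0,
                 tolerance = 1e-9)
    expect_equal(e2$n_channels, e1$n_channels, tolerance = 1e-9)
  }
})

test_that("counting error degrades monotonically with noise", {
  mae_at <- function(noise_sd) {
    errs <- vapply(1:25, function(i) {
      set.seed(500 + i)
      k <- sample(4:12, 1)
      bounds <- sort(sample(seq(300, 1150, by = 6), k))
      levels <- c(0, seq(k, 0) * 100)
      x <- rep(levels, diff(c(0, 250, bounds, 1200)))
      if (noise_sd > 0) x <- x + rnorm(1200, 0, noise_sd)
      est <- count_channels_trace(bleach_trace(x, uv_onset_frame = 250))
      if (is.na(est$n_channels)) return(NA_real_)
      abs(est$n_channels - k)
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }
  maes <- vapply(c(0, 5, 10, 20), mae_at, numeric(1))
  expect_true(all(diff(maes) >= -0.05))
  expect_equal(maes[1], 0)
})

test_that("aggregation summarises per animal and genotype with QC", {
  mk <- function(n, qc = TRUE) structure(
    list(peak_intensity = n * 50, unitary_intensity = 50, n_channels = n,
         n_unitary_events = 5L, qc_pass = qc, qc_flags = character(0)),
    class = "channel_count_estimate")
  est <- c(lapply(rep(c(9, 10, 11), 10), mk), list(mk(99, qc = FALSE)))
  labels <- data.frame(animal = "a1", genotype = "wt")[rep(1, 31), ]
  agg <- aggregate_counts(est, labels)
  expect_equal(agg$per_animal$mean, 10)
  expect_equal(agg$per_animal$n_excluded, 1)
  expect_equal(agg$per_animal$flag, "")
  expect_equal(agg$per_genotype$mean, 10)

  est2 <- lapply(rep(10, 10), mk)
  labels2 <- data.frame(animal = "a2", genotype = "wt")[rep(1, 10), ]
  agg2 <- aggregate_counts(est2, labels2)
  expect_equal(agg2$per_animal$flag, "below minimum AZ count")
})
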