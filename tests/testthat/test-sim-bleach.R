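test_that("config validation names the offending field", {
  expect_error(bleach_sim_config(conversion_rate = 1.2), "conversion_rate")
  expect_error(bleach_sim_config(unitary_intensity = 0), "unitary_intensity")
  expect_error(bleach_sim_config(n_frames = 255, uv_onset_frame = 250),
               "n_frames")
  expect_error(bleach_sim_config(channels_per_az = 2.5), "channels_per_az")
})

test_that("noiseless instant-conversion trace is a clean staircase to zero", {
  cfg <- bleach_sim_config(n_az = 1, channels_per_az = 3,
                           unitary_intensity = 100, conversion_rate = 1,
                           bleach_rate = 0.02, blink_off_rate = 0,
                           blink_on_rate = 0, noise_sd = 0,
                           n_frames = 1500, uv_onset_frame = 100, seed = 5)
  sim <- simulate_bleach_traces(cfg)
  x <- sim$traces[[1]]$intensity
  expect_true(all(x[1:99] == 0))
  expect_equal(x[100], 300)             # all converted at UV onset
  expect_true(all(diff(x[100:1500]) <= 0))  # non-increasing once converted
  expect_true(all(x %in% c(0, 100, 200, 300)))
  expect_equal(x[length(x)], 0)         # fully bleached by the end
  drops <- diff(x[100:1500])
  expect_equal(sum(-drops[drops < 0]) / 100, 3)  # integrated steps = count
})

test_that("identical seed and config reproduce outputs exactly", {
  cfg <- bleach_sim_config(n_az = 3, channels_per_az = 5, n_frames = 400,
                           uv_onset_frame = 50, seed = 21)
  s1 <- simulate_bleach_traces(cfg)
  s2 <- simulate_bleach_traces(cfg)
  expect_identical(s1, s2)
  m1 <- simulate_bleach_movie(cfg)
  m2 <- simulate_bleach_movie(cfg)
  expect_identical(m1$movie$frames, m2$movie$frames)
  expect_identical(m1$truth, m2$truth)
})

test_that("survival after conversion follows the closed-form bleach law", {
  ## one AZ with many fluorophores; instant conversion, no blinking
  cfg <- bleach_sim_config(n_az = 1, channels_per_az = 2000,
                           unitary_intensity = 1, conversion_rate = 1,
                           bleach_rate = 0.01, blink_off_rate = 0,
                           blink_on_rate = 0, noise_sd = 0,
                           n_frames = 2000, uv_onset_frame = 10, seed = 3)
  sim <- simulate_bleach_traces(cfg)
  x <- sim$traces[[1]]$intensity     # = survivors per frame
  fr <- c(50, 100, 200, 400)
  surv_sim <- x[10 + fr] / 2000
  surv_theory <- (1 - 0.01)^fr
  tol <- 4 * sqrt(surv_theory * (1 - surv_theory) / 2000)
  expect_true(all(abs(surv_sim - surv_theory) <= tol))
  ## independent Monte-Carlo tally from geometric bleach-time draws
  set.seed(99)
  bleach_frames <- rgeom(20000, 0.01) + 1
  surv_mc <- vapply(fr, function(f) mean(bleach_frames > f), numeric(1))
  expect_true(all(abs(surv_mc - surv_theory) <=
                    4 * sqrt(surv_theory * (1 - surv_theory) / 20000)))
})

test_that("movie rendering places spots at truth positions with background", {
  cfg <- bleach_sim_config(n_az = 4, channels_per_az = 8,
                           unitary_intensity = 200, background_level = 20,
                           noise_sd = 2, n_frames = 300, uv_onset_frame = 40,
                           conversion_rate = 0.5, bleach_rate = 0.005,
                           seed = 13)
  out <- simulate_bleach_movie(cfg)
  expect_s3_class(out$movie, "az_movie")
  expect_equal(nrow(out$truth), 4)
  tr <- extract_roi_trace(out$movie, c(out$truth$row[1], out$truth$col[1]))
  ## pre-onset: background-subtracted trace stays near zero
  pre <- tr$intensity[1:39]
  expect_lt(abs(mean(pre)), 3 * 2 * sqrt(25))
  ## post-onset: signal appears
  expect_gt(max(tr$intensity), 8 * 200 * 0.5)
})
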