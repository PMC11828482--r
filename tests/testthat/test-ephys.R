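test_that("the Gaussian low-pass honors its frequency-domain contract", {
  fs <- 50000
  t <- (0:49999) / fs
  ## DC gain
  flat <- gaussian_lowpass(az_sweep(rep(2, 5000), fs), 360)
  expect_lt(max(abs(flat$current - 2)), 1e-6)
  ## -3 dB at the cutoff
  sine <- az_sweep(sin(2 * pi * 360 * t), fs)
  f <- gaussian_lowpass(sine, 360)
  att_db <- 20 * log10(max(abs(f$current[10000:40000])))
  expect_lt(abs(att_db - (-3)), 0.1)
  ## smoothing strictly reduces white-noise variance
  set.seed(1)
  wn <- az_sweep(rnorm(20000), fs)
  expect_lt(var(gaussian_lowpass(wn, 360)$current), var(wn$current))
  ## zero phase: cross-correlation peak at zero lag
  set.seed(2)
  x <- az_sweep(rnorm(8192), fs)
  y <- gaussian_lowpass(x, 360)
  cc <- stats::ccf(y$current, x$current, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(gaussian_lowpass(x, 25000), "Nyquist")
})

test_that("EPSC measurement recovers amplitude, width and charge", {
  cfg <- tevc_sim_config(noise_sd = 0, mepsc_rate = 0, epsc_amplitude = 100,
                         seed = 1)
  tw <- simulate_tevc_sweeps(cfg, stim_protocol(0.05, 0.3))
  m <- measure_epsc(tw$sweeps[[1]], 0.05)
  expect_equal(m$amplitude, 100, tolerance = 0.5 / 100)
  expect_gt(m$half_width, 0)

  flat <- az_sweep(rep(-5, 5000), 50000)
  mf <- measure_epsc(flat, 0.05)
  expect_equal(mf$flag, "no event")
  expect_equal(mf$amplitude, 0)

  rect <- az_sweep(c(rep(0, 500), rep(-10, 500), rep(0, 500)), 50000)
  mr <- measure_epsc(rect, 0.01, response_window = 0.02)
  expect_equal(mr$charge, 0.1, tolerance = 1e-3)
  expect_equal(mr$half_width, 10, tolerance = 0.01)
  expect_error(measure_epsc(rect, 0.02, response_window = 0.02), "window")
})

test_that("burst charge integrates below-baseline area only", {
  fs <- 50000
  flat <- az_sweep(rep(-1, fs * 0.4), fs)
  expect_equal(burst_charge(flat, c(0.1, 0.3)), 0)

  rect <- az_sweep(c(rep(0, fs * 0.1), rep(-50, fs * 0.2), rep(0, fs * 0.1)), fs)
  expect_equal(burst_charge(rect, c(0.1, 0.3)), 10, tolerance = 1e-3)

  ## summating 60 Hz burst against the analytic kernel-sum integral
  cfg <- tevc_sim_config(noise_sd = 0, mepsc_rate = 0, epsc_amplitude = 50,
                         seed = 1)
  stims <- seq(0.1, by = 1 / 60, length.out = 12)
  tw <- simulate_tevc_sweeps(cfg, stim_protocol(stims, 0.6))
  bc <- burst_charge(tw$sweeps[[1]], c(0.1, 0.45))
  amps <- true_epsc_amplitudes(cfg, stims)
  rt <- cfg$rise_tau / 1000; dt <- cfg$decay_tau / 1000
  tpk <- log(dt / rt) * rt * dt / (dt - rt)
  kernel_integral <- (dt - rt) / (exp(-tpk / dt) - exp(-tpk / rt))
  expect_equal(bc, sum(amps * kernel_integral), tolerance = 0.02)
})

test_that("both PPR schemes are computed and diverge as documented", {
  p1 <- compute_ppr(100, 80, ipi_ms = 10)
  expect_equal(p1$ppr_scheme_a, 0.8)
  expect_equal(p1$ppr_scheme_b, 0.8)

  p2 <- compute_ppr(c(100, 50), c(50, 50))
  expect_equal(p2$ppr_scheme_a, 0.75)
  expect_equal(p2$ppr_scheme_b, 100 / 150)

  ## schemes coincide exactly whenever all first amplitudes are equal
  set.seed(4)
  a2 <- runif(20, 40, 120)
  p3 <- compute_ppr(rep(80, 20), a2)
  expect_equal(p3$ppr_scheme_a, p3$ppr_scheme_b, tolerance = 1e-12)

  expect_warning(p4 <- compute_ppr(c(100, 0), c(80, 10)), "zero first")
  expect_equal(p4$n_sweeps, 1L)
})

test_that("PPR CoV per IPI matches hand arithmetic", {
  df <- data.frame(ipi = c(10, 10, 10, 25, 25), ppr = c(1, 1, 1, 0.9, 1.1))
  cv <- ppr_cov(df)
  expect_equal(cv$cov_percent[cv$ipi == 10], 0)
  expect_equal(cv$cov_percent[cv$ipi == 25], 100 * sd(c(0.9, 1.1)) / 1,
               tolerance = 1e-9)
  expect_error(ppr_cov(data.frame(ipi = 10, ppr = 1)), ">= 2 animals")
})

test_that("depression fitting is exact on noiseless data and flags degeneracy", {
  t <- 0:59
  f <- fit_depression(0.8 + 0.2 * exp(-t / 5), t)
  expect_equal(f$tau, 5, tolerance = 0.01)
  expect_equal(f$plateau_fraction, 0.8, tolerance = 0.005)

  fc <- fit_depression(rep(2, 30), 0:29)
  expect_equal(fc$flag, "degenerate")
  expect_equal(fc$plateau_fraction, 1)

  ## amplitude rescaling leaves tau and plateau fraction unchanged
  set.seed(5)
  a <- (0.8 + 0.2 * exp(-t / 5)) * exp(rnorm(60, 0, 0.03))
  f1 <- fit_depression(a, t)
  f2 <- fit_depression(1000 * a, t)
  expect_equal(f2$tau, f1$tau, tolerance = 1e-6)
  expect_equal(f2$plateau_fraction, f1$plateau_fraction, tolerance = 1e-6)
})

test_that("mean quantal content is the ratio of mean amplitudes", {
  q <- mean_quantal_content(rep(100, 5), rep(1, 5))
  expect_equal(q$mqc, 100)
  expect_equal(mean_quantal_content(c(3, 5), c(3, 5))$mqc, 1)
  expect_error(mean_quantal_content(numeric(0), 1), "non-empty")
  ## simulated recording: mEPSC truth feeds the denominator
  cfg <- tevc_sim_config(mepsc_rate = 4, noise_sd = 0.2, seed = 6)
  tw <- simulate_tevc_sweeps(cfg, stim_protocol(numeric(0), 50))
  expect_gt(nrow(tw$mepscs), 100)
  mq <- mean_quantal_content(rep(cfg$epsc_amplitude, 50),
                             tw$mepscs$amplitude_nA)
  expect_equal(mq$mqc, cfg$epsc_amplitude / cfg$mepsc_amplitude,
               tolerance = 0.1)
})

test_that("TEVC simulation matches its own stated amplitude model", {
  cfg <- tevc_sim_config(noise_sd = 0, mepsc_rate = 0, epsc_amplitude = 100,
                         seed = 1)
  ## single stimulus: trough is exactly -amplitude
  tw <- simulate_tevc_sweeps(cfg, stim_protocol(0.05, 0.3))
  expect_equal(min(tw$sweeps[[1]]$current), -100, tolerance = 1e-3)

  ## twin pulses at unit PPR and long IPI: equal amplitudes
  tw2 <- simulate_tevc_sweeps(cfg, stim_protocol(c(0.05, 0.15), 0.4))
  m1 <- measure_epsc(tw2$sweeps[[1]], 0.05)
  m2 <- measure_epsc(tw2$sweeps[[1]], 0.15)
  expect_equal(m2$amplitude / m1$amplitude, 1, tolerance = 1e-3)

  ## per-IPI PPR lookup
  cfg_p <- tevc_sim_config(noise_sd = 0, mepsc_rate = 0,
                           ppr_true = c("10" = 0.7, "100" = 1.05), seed = 1)
  a <- true_epsc_amplitudes(cfg_p, c(0, 0.010))
  expect_equal(a[2] / a[1], 0.7)
  b <- true_epsc_amplitudes(cfg_p, c(0, 0.100))
  expect_equal(b[2] / b[1], 1.05)

  ## 1 Hz train equals the closed-form depression recursion
  times <- seq(0, 29)
  amps <- true_epsc_amplitudes(cfg, times)
  want <- oracle_depression_closed_form(100, cfg$depression_plateau,
                                        cfg$depression_tau, times)
  expect_equal(amps, want, tolerance = 1e-12)

  expect_error(stim_protocol(c(0.1, 0.05), 1), "increasing")
  expect_error(az_sweep(rep(0, 100), 1000, stimulus_times = 0.2),
               "sweep end")
})

test_that("sweep text round-trip preserves the data", {
  cfg <- tevc_sim_config(seed = 2)
  tw <- simulate_tevc_sweeps(cfg, stim_protocol(0.02, 0.1))
  p <- file.path(tempdir(), "sweep.tsv")
  write_sweep(tw$sweeps[[1]], p)
  back <- read_sweep(p)
  expect_equal(back$sampling_rate, 50000)
  expect_equal(back$current, tw$sweeps[[1]]$current, tolerance = 1e-6)
})
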