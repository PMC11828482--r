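#!/usr/bin/env Rscript
## Stage 5: evoked-transmission metrics from simulated voltage-clamp
## sweeps — offline Gaussian filtering, per-stimulus EPSC measures,
## paired-pulse ratios under both averaging schemes, the coefficient of
## variation across simulated animals, single-exponential depression
## fits, burst charge transfer, and mean quantal content.

source("analysis/00_common.R")

tcfg <- tevc_setup()
ipis <- c(10, 15, 20, 25, 30, 50, 100)

## --- paired pulses over IPIs, 3 simulated animals x 5 sweeps ---------
ppr_rows <- list(); cov_rows <- list()
for (animal in 1:3) {
  ## per-animal biological variability in paired-pulse behavior
  set.seed(RUN_SEED + 100L + animal)
  acfg <- tevc_sim_config(ppr_true = exp(rnorm(1, 0, 0.08)),
                          seed = RUN_SEED + 100L + animal)
  for (ipi in ipis) {
    prot <- stim_protocol(c(0.05, 0.05 + ipi / 1000), 0.25 + ipi / 1000)
    tw <- simulate_tevc_sweeps(acfg, prot, n_sweeps = 5)
    a1 <- a2 <- numeric(5)
    for (s in 1:5) {
      f <- gaussian_lowpass(tw$sweeps[[s]], 360)
      a1[s] <- measure_epsc(f, 0.05,
                            response_window = min(ipi / 1000, 0.02))$amplitude
      a2[s] <- measure_epsc(f, 0.05 + ipi / 1000)$amplitude
    }
    pr <- compute_ppr(a1, a2, ipi_ms = ipi)
    ppr_rows[[length(ppr_rows) + 1L]] <- data.frame(
      animal = animal, ipi_ms = ipi,
      ppr_scheme_a = pr$ppr_scheme_a, ppr_scheme_b = pr$ppr_scheme_b)
    cov_rows[[length(cov_rows) + 1L]] <- data.frame(
      ipi = ipi, ppr = pr$ppr_scheme_a)
  }
}
ppr_tab <- do.call(rbind, ppr_rows)
write.csv(ppr_tab, "results/ppr.csv", row.names = FALSE)
cv <- ppr_cov(do.call(rbind, cov_rows))
write.csv(cv, "results/ppr_cov.csv", row.names = FALSE)
cat(sprintf("PPR (true 1.0): scheme A mean %.3f, scheme B mean %.3f; CoV across animals %.1f-%.1f%%\n",
            mean(ppr_tab$ppr_scheme_a), mean(ppr_tab$ppr_scheme_b),
            min(cv$cov_percent), max(cv$cov_percent)))

## --- 1 Hz depression train, per-animal fits -------------------------
tt <- 0:59
fits <- t(vapply(1:5, function(animal) {
  set.seed(RUN_SEED + 200L + animal)
  amps <- true_epsc_amplitudes(tcfg, tt) * exp(rnorm(60, 0, 0.05))
  f <- fit_depression(amps, tt)
  c(tau = f$tau, plateau = f$plateau_fraction)
}, numeric(2)))
write.csv(data.frame(animal = 1:5, fits), "results/depression_fits.csv",
          row.names = FALSE)
cat(sprintf("depression: mean tau %.2f s (true %g), mean plateau %.3f (true %g)\n",
            mean(fits[, "tau"]), tcfg$depression_tau,
            mean(fits[, "plateau"]), tcfg$depression_plateau))

## --- burst charge at 60 Hz ------------------------------------------
stims <- seq(0.1, by = 1 / 60, length.out = 12)
tw <- simulate_tevc_sweeps(tevc_sim_config(noise_sd = 0, mepsc_rate = 0,
                                           seed = RUN_SEED),
                           stim_protocol(stims, 0.6))
bc <- burst_charge(tw$sweeps[[1]], c(0.1, 0.45))
cat(sprintf("60 Hz burst (200 ms, 12 stimuli): charge transfer %.2f nC\n", bc))

## --- mean quantal content -------------------------------------------
mtw <- simulate_tevc_sweeps(tevc_sim_config(mepsc_rate = 4, seed = RUN_SEED),
                            stim_protocol(numeric(0), 60))
mq <- mean_quantal_content(rep(tcfg$epsc_amplitude, 50),
                           mtw$mepscs$amplitude_nA)
write.csv(data.frame(mean_epsc = mq$mean_epsc, mean_mepsc = mq$mean_mepsc,
                     mqc = mq$mqc, burst_charge_nC = bc),
          "results/ephys_summary.csv", row.names = FALSE)
cat(sprintf("mean quantal content: %.1f nA / %.3f nA = %.1f (generator: %g/%g = %.1f)\n",
            mq$mean_epsc, mq$mean_mepsc, mq$mqc,
            tcfg$epsc_amplitude, tcfg$mepsc_amplitude,
            tcfg$epsc_amplitude / tcfg$mepsc_amplitude))
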