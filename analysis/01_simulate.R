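#!/usr/bin/env Rscript
## Stage 1: generate the seeded synthetic datasets and write their
## ground-truth sidecars. Later stages regenerate the same data from the
## shared seeds in 00_common.R, so nothing binary needs to persist.

source("analysis/00_common.R")
dir.create("results/simulated", showWarnings = FALSE, recursive = TRUE)

bl <- bleach_cohort()
write.csv(bl$sim$truth, "results/simulated/bleach_truth.csv", row.names = FALSE)
write.csv(bl$sim$events, "results/simulated/bleach_events.csv", row.names = FALSE)
cat(sprintf("bleach cohort: %d traces of %d frames at %g Hz; true counts %d..%d; %d fluorophores converted\n",
            length(bl$sim$traces), bl$cfg$n_frames, bl$cfg$frame_rate,
            min(bl$sim$truth$true_channels), max(bl$sim$truth$true_channels),
            sum(!is.na(bl$sim$events$conversion_frame))))

for (cond in c("control", "half")) {
  sc <- synapse_condition(cond)
  write.csv(sc$sim$truth, sprintf("results/simulated/synapse_%s_truth.csv", cond),
            row.names = FALSE)
  cls <- table(sc$sim$truth$content_class[sc$sim$truth$type == "cac"])
  cat(sprintf("synapse %s: %d AZs, ring %g nm, content: %s\n", cond,
              sum(sc$sim$truth$type == "cac"), sc$cfg$ring_radius,
              paste(names(cls), cls, sep = "=", collapse = ", ")))
}

tcfg <- tevc_setup()
train_times <- seq(0, 59)
write.csv(data.frame(time_s = train_times,
                     true_amplitude_nA = true_epsc_amplitudes(tcfg, train_times)),
          "results/simulated/tevc_train_truth.csv", row.names = FALSE)
cat(sprintf("TEVC model: amplitude %g nA, depression plateau %g, tau %g s\n",
            tcfg$epsc_amplitude, tcfg$depression_plateau, tcfg$depression_tau))
cat("truth sidecars written to results/simulated/\n")
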