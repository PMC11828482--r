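## Shared constants for the analysis drivers. Each stage regenerates its
## synthetic inputs from these seeds (generation is fast and exactly
## reproducible), so all persistent outputs stay plain text.

library(azquant)

RUN_SEED <- 20240601L
dir.create("results", showWarnings = FALSE)

bleach_cohort <- function() {
  set.seed(RUN_SEED)
  true_counts <- sample(4:16, 60, replace = TRUE)
  cfg <- bleach_sim_config(n_az = 60, channels_per_az = true_counts,
                           unitary_intensity = 100, noise_sd = 10,
                           n_frames = 2500L, uv_onset_frame = 250L,
                           seed = RUN_SEED)
  list(cfg = cfg, sim = simulate_bleach_traces(cfg))
}

synapse_condition <- function(cond = c("control", "half", "noiseless",
                                       "confocal")) {
  cond <- match.arg(cond)
  cfg <- switch(cond,
    control = synapse_sim_config(stack_shape = c(9L, 288L, 288L),
                                 n_boutons = 9L, az_per_bouton = 4L,
                                 cac_intensity_A = 100, seed = RUN_SEED + 1L),
    half = synapse_sim_config(stack_shape = c(9L, 288L, 288L),
                              n_boutons = 9L, az_per_bouton = 4L,
                              cac_intensity_A = 50, seed = RUN_SEED + 2L),
    noiseless = synapse_sim_config(psf_sigma = c(0, 0, 0), noise_sd = 0,
                                   intensity_cv = 0, seed = RUN_SEED + 5L),
    ## confocal-like sampling: the coarser PSF blurs the channel cluster
    ## and its scaffold ring into overlapping blobs, the regime in which
    ## their colocalization is normally quantified (nanoscopy resolves
    ## the ring and is used for distances, not for Pearson/Manders)
    confocal = synapse_sim_config(stack_shape = c(7L, 96L, 96L),
                                  voxel_size = c(300, 90, 90),
                                  psf_sigma = c(250, 110, 110),
                                  n_boutons = 2L, az_per_bouton = 4L,
                                  seed = RUN_SEED + 3L))
  list(cfg = cfg, sim = simulate_synapse_stack(cfg))
}

tevc_setup <- function() tevc_sim_config(seed = RUN_SEED)
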