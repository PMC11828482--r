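#!/usr/bin/env Rscript
## Stage 4: active-zone geometry, masked intensity and isoform content.
## Detects cac and brp puncta, measures the in-plane distance from each
## channel cluster to its nearest same-section scaffold punctum, compares
## masked cac intensity between the control and half-intensity
## conditions, and classifies per-AZ isoform content.

source("analysis/00_common.R")

## --- ring geometry --------------------------------------------------
geo <- list()
for (cond in c("noiseless", "control")) {
  sc <- synapse_condition(cond)
  vs <- sc$cfg$voxel_size
  ch <- sc$sim$stack$channels
  cac <- detect_puncta(ch$cac_a + ch$cac_b, vs, channel_label = "cac")
  brp <- detect_puncta(ch$brp, vs, channel_label = "brp")
  dd <- nearest_brp_distance(cac, brp)
  dd$condition <- cond
  geo[[cond]] <- dd
  cat(sprintf("%s: %d cac vs %d brp puncta; median nearest distance %.1f nm (%d excluded, ring truth %g nm)\n",
              cond, nrow(cac), nrow(brp), median(dd$distance_nm),
              attr(dd, "n_excluded"), sc$cfg$ring_radius))
}
write.csv(do.call(rbind, geo), "results/cac_brp_distances.csv", row.names = FALSE)

## --- masked intensity, two conditions, normalized to control --------
per_az <- list()
for (cond in c("control", "half")) {
  sc <- synapse_condition(cond)
  mi <- masked_intensity(sc$sim$stack$channels$cac_a,
                         sc$sim$stack$channels$brp, dilation_radius = 3)
  per_az[[cond]] <- data.frame(group = cond,
                               value = mi$per_az$mean_intensity)
}
tab <- normalize_to_control(do.call(rbind, per_az), "control")
write.csv(tab, "results/az_intensity_normalized.csv", row.names = FALSE)
means <- tapply(tab$normalized, tab$group, mean)
cat(sprintf("normalized masked cac intensity: control %.3f, half %.3f (generator ratio 0.5)\n",
            means["control"], means["half"]))

## --- isoform content classification ---------------------------------
sc <- synapse_condition("control")
content <- az_content_from_stack(sc$sim$stack)
write.csv(content$per_az, "results/az_content.csv", row.names = FALSE)
truth_cls <- table(sc$sim$truth$content_class[sc$sim$truth$type == "cac"])
cat(sprintf("content over %d AZ components: both %.1f%%, B-only %.1f%% (truth: %s)\n",
            content$n_az, 100 * content$fractions[["both"]],
            100 * content$fractions[["B_only"]],
            paste(names(truth_cls), truth_cls, sep = "=", collapse = ", ")))
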