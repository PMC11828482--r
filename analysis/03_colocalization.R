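#!/usr/bin/env Rscript
## Stage 3: masked colocalization of the channel-cluster signal with the
## scaffold staining. The membrane (HRP) channel defines the analysis
## mask; Costes thresholds are found on the channel pair inside it and
## Pearson/Manders coefficients reported.

source("analysis/00_common.R")

sc <- synapse_condition("confocal")
ch <- sc$sim$stack$channels
hrp_mask <- build_mask(ch$hrp)
res <- coloc_within_mask(ch$cac_a + ch$cac_b, ch$brp, hrp_mask,
                         max_candidates = 512L)
cat(sprintf("confocal-like stack: Pearson r = %.3f, M1 = %.3f, M2 = %.3f over %d masked voxels\n",
            res$pearson_r, res$m1, res$m2, res$n_voxels))
cat(sprintf("Costes thresholds %.2f / %.2f (regression slope %.3f)\n",
            res$threshold_a, res$threshold_b, res$regression_slope))
write.csv(res, "results/colocalization.csv", row.names = FALSE)
cat("colocalization table written to results/colocalization.csv\n")
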