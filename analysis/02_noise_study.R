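#!/usr/bin/env Rscript
# Noise propagation (Simulation i): bias (ME) and precision (CoV) of the
# tensor-model estimates from perfectly powder-averaged data over a grid
# of microscopic anisotropies at fixed MD, plus the two-point stick
# design at the sensitivity optimum.
#
# Findings: with the five-b ladder to 14.5 ms/um^2 at SNR 50 (12 averages
# per point), D_L and MD carry sub-percent bias across uFA 0.6-0.99 while
# D_T is increasingly overestimated as uFA -> 1; a two-point acquisition
# at bD_L = 2.284 achieves CoV(D_L) ~ 10% at SNR 50.

library(pamrs)
dir.create("results", showWarnings = FALSE)
seed <- 1L

ns <- run_noise_study(SNR = 50, b_max = 14.5, MD = 0.17,
                      n_realizations = 1e4, seed = seed)
print(ns, row.names = FALSE, digits = 3)
write.csv(ns, "results/noise_study_mufa_grid.csv", row.names = FALSE)
cat(sprintf("worst |ME| over grid: D_L %.2f%%, MD %.2f%%\n",
            max(abs(ns$ME_D_L)), max(abs(ns$ME_MD))))

covs <- do.call(rbind, lapply(c(25, 50, 100), function(snr) {
  tp <- run_two_point_noise_study(SNR = snr, n_realizations = 1e4,
                                  seed = seed + snr)
  data.frame(SNR = snr, CoV_D_L = tp$CoV, ME_D_L = tp$ME)
}))
print(covs, row.names = FALSE, digits = 3)
write.csv(covs, "results/two_point_cov.csv", row.names = FALSE)
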