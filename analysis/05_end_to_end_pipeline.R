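#!/usr/bin/env Rscript
# End-to-end demonstration on synthetic acquisitions: generate
# directional datasets for the two scenario presets (aligned CC-like and
# dispersed PWM-like substrates), run the full analysis pipeline, and
# compare the two regions.
#
# Findings: powder averaging returns the same microscopic D_L for both
# substrates despite very different orientational order, while the
# macroscopic tensor separates them cleanly through FA and the angular
# spread theta; a two-sample t-test flags the macro-anisotropy metrics
# but not the microscopic ones, mirroring how the two real regions
# differ only macroscopically.

library(pamrs)
dir.create("results", showWarnings = FALSE)
seed <- 1L
n_subjects <- 5

run_region <- function(preset_name) {
  pre <- scenario_preset(preset_name)
  sc <- preset_scheme(pre, seed = 0)
  lapply(seq_len(n_subjects), function(s) {
    ds <- generate_dataset(pre, sc, seed = seed + 100 * s +
                             (preset_name == "PWM"))
    suppressWarnings(run_full_pipeline(ds))
  })
}

cc <- run_region("CC")
pwm <- run_region("PWM")

metrics <- function(runs) data.frame(
  D_L = vapply(runs, function(r) r$fit_tensor$D_L, 1),
  D_T = vapply(runs, function(r) r$fit_tensor$D_T, 1),
  MD = vapply(runs, function(r) r$fit_tensor$MD, 1),
  uFA = vapply(runs, function(r) r$fit_tensor$uFA, 1),
  D_L_stick = vapply(runs, function(r) r$fit_stick$D_L, 1),
  FA_macro = vapply(runs, function(r) r$macro$FA, 1),
  theta = vapply(runs, function(r) r$theta_deg, 1))

mcc <- metrics(cc)
mpwm <- metrics(pwm)
summ <- data.frame(metric = names(mcc),
                   CC_mean = colMeans(mcc), CC_sd = apply(mcc, 2, sd),
                   PWM_mean = colMeans(mpwm), PWM_sd = apply(mpwm, 2, sd))
cmp <- region_compare(mcc, mpwm)
summ$p <- cmp$p[match(summ$metric, cmp$metric)]
print(summ, row.names = FALSE, digits = 3)
write.csv(summ, "results/region_summary.csv", row.names = FALSE)

# asymptote diagnostic for one dispersed-region subject
write.csv(pwm[[1]]$asymptote, "results/asymptote_diagnostic.csv",
          row.names = FALSE)
cat(sprintf("\nPWM subject 1: stick D_L = %.3f um^2/ms, theta = %.1f deg\n",
            pwm[[1]]$fit_stick$D_L, pwm[[1]]$theta_deg))
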