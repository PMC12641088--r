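#!/usr/bin/env Rscript
# Stage 6 — Patlak quantification of dynamic time-activity curves.
#
# Simulates dynamic acquisitions (120 frames at 1 s) for a range of
# influx constants, recovers (K1, V0) from the linear portion of the
# Patlak plot, and demonstrates the area-weighted aggregation of ROI
# values into the 24 arterial territories.

suppressPackageStartupMessages(library(temporient))
dir.create("results", showWarnings = FALSE)
seed <- 1L

cases <- expand.grid(k1 = c(0.3, 0.5, 0.7), noise = c(0, 0.01, 0.03))
fits <- do.call(rbind, lapply(seq_len(nrow(cases)), function(i) {
  curve <- gen_tac(k1 = cases$k1[i], v0 = 0.2, noise_sd = cases$noise[i],
                   seed = seed + i)
  f <- patlak_fit(curve)
  data.frame(k1_true = cases$k1[i], noise = cases$noise[i],
             k1_hat = f$k1, v0_hat = f$v0, r2 = f$r2,
             frames = paste(f$fit_window, collapse = "-"))
}))
write.csv(fits, "results/patlak_fits.csv", row.names = FALSE)
cat("Patlak recovery across influx constants and noise levels:\n")
print(cbind(fits[1:5], k1_err = round(fits$k1_hat - fits$k1_true, 4)),
      row.names = FALSE)

# ROI -> territory aggregation on the bundled synthetic template
template <- toy_roi_template()
set.seed(seed)
roi_values <- setNames(rnorm(nrow(template), 50, 6), template$roi_id)
agg <- aggregate_territories(roi_values, template, participant_id = "demo",
                             global_normalize = TRUE)
write_cbf_table(agg, "results/patlak_territories.csv")
cat(sprintf("\naggregated %d ROIs into 24 territories (globally normalized; mean %.3f)\n",
            nrow(template), mean(agg$cbf_ml_100g_min)))
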