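#!/usr/bin/env Rscript

# Generate all synthetic datasets for the analysis workflow.
#
# Every downstream script reads its input from results/data/, so the whole
# workflow is reproducible from this script's seed alone. Generator defaults
# mirror the experimental designs: gel densitometry sampled over 5-1200 s with
# 5% multiplicative noise, a seven-point 2-fold BLI dilution series
# (200 -> 3.125 nM) with 500 s phases and 0.5% additive noise, a bimodal
# chromatogram on an 8-24 mL column, and 10-90 degC melt curves at 1% noise.

suppressPackageStartupMessages(library(inteinkit))

seed <- 20240901
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

## splice time course (gel densitometry) ------------------------------------
gel <- generate_pts_gel(k1 = 0.05, k2 = 0.01, k3 = 0.1,
                        active_fraction = 0.30, noise_sd = 0.05, seed = seed)
tc <- gel$timecourse
write_table_csv(
  data.frame(time_s = tc$times,
             A = tc$intensities[, "A"],
             BI = tc$intensities[, "BI"],
             P = tc$intensities[, "P"]),
  "results/data/gel_densitometry.csv")

## biphasic BLI sensorgrams --------------------------------------------------
bli_rates <- list(ka = 1e5, kd = 1e-2, kf = 1e-2, ku = 1e-3)
sg <- generate_sensorgrams(bli_rates, noise_sd = 0.005, seed = seed + 1)
long <- do.call(rbind, lapply(sg$sensorgrams, function(tr) {
  data.frame(conc_M = attr(tr, "conc"), time_s = tr$time,
             response = tr$response, phase = tr$phase)
}))
write_table_csv(long, "results/data/sensorgrams.csv")

## SEC chromatogram (aggregate + monomer) ------------------------------------
chrom <- generate_chromatogram(
  data.frame(center = c(8.6, 15.5), width = c(0.35, 0.8), area = c(71, 29)),
  V0 = 8, Vt = 24, noise_sd = 0.05, seed = seed + 2)
write_table_csv(data.frame(volume_mL = chrom$volume,
                           absorbance_mAU = chrom$absorbance),
                "results/data/chromatogram.csv")

## thermal-shift melt curves (3 replicates, post-peak quench) ----------------
melts <- lapply(1:3, function(i) {
  m <- generate_melt_curve(T_M = 61.4, b = 0.25, quench_onset = 75,
                           quench_slope = 0.03, noise_sd = 0.01,
                           seed = seed + 2 + i)
  data.frame(replicate = i, temperature_C = m$temperature,
             fluorescence = m$fluorescence)
})
write_table_csv(do.call(rbind, melts), "results/data/melt_curves.csv")

## ground truth for later comparison -----------------------------------------
write_report(
  list(gel = gel$truth, bli = sg$truth[c("ka", "kd", "kf", "ku")],
       sec = list(aggregate_percent = 71, monomer_percent = 29),
       melt = list(T_M = 61.4, b = 0.25)),
  "results/data/truth.json", seed = seed,
  inputs = "synthetic generators, this script")

cat("wrote synthetic datasets to results/data/ (seed ", seed, ")\n", sep = "")
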