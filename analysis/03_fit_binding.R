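#!/usr/bin/env Rscript

# Analyze the synthetic BLI dilution series with the two-step
# conformational-change model N + C <-> N.C <-> NC.
#
# Each sensorgram's association and dissociation phases are fitted with
# biexponentials; the exponents' linear dependence on analyte concentration
# yields (ka, kd, kf, ku), which are then refined by a global fit that
# constrains every trace to share one rate set. Equilibrium and macroscopic
# constants follow algebraically.

suppressPackageStartupMessages(library(inteinkit))

long <- read_table_auto("results/data/sensorgrams.csv",
                        required = c("conc_M", "time_s", "response"),
                        numeric_cols = c("conc_M", "time_s", "response"))
sensorgrams <- lapply(split(long, long$conc_M), function(d) {
  d <- d[order(d$time_s), ]
  tr <- data.frame(time = d$time_s, response = d$response, phase = d$phase)
  attr(tr, "conc") <- d$conc_M[1]
  tr
})
# analyze in descending concentration order, as acquired
sensorgrams <- rev(sensorgrams)

rates <- analyze_sensorgrams(sensorgrams, t0 = 500, refine = TRUE)
mac <- macroscopic_rates(equilibrium_constants(rates))

write_table_csv(
  data.frame(quantity = c("ka_per_M_s", "kd_per_s", "kf_per_s", "ku_per_s",
                          "Ka1_per_M", "Ka2", "Ka_per_M", "Kd_M",
                          "kon_per_M_s", "koff_per_s"),
             value = c(rates$ka, rates$kd, rates$kf, rates$ku,
                       mac$Ka1, mac$Ka2, mac$Ka, mac$Kd,
                       mac$kon, mac$koff)),
  "results/binding_constants.csv")

cat(sprintf("ka = %.3g /(M s), kd = %.3g /s, kf = %.3g /s, ku = %.3g /s\n",
            rates$ka, rates$kd, rates$kf, rates$ku))
cat(sprintf("overall Kd = %.3g M (kon = %.3g /(M s), koff = %.3g /s)\n",
            mac$Kd, mac$kon, mac$koff))
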