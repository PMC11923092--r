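#!/usr/bin/env Rscript

# Fit splice-product formation kinetics from the synthetic gel densitometry.
#
# Two models are fitted to the mass-normalized, fraction-scaled band
# intensities: the single-exponential product model P(t) = P_max (1 - e^{-kt})
# that summarizes the overall reaction, and the three-state scheme
# A <-> BI -> P that resolves association (k1), dissociation (k2) and
# splicing chemistry (k3).

suppressPackageStartupMessages(library(inteinkit))

raw <- read_table_auto("results/data/gel_densitometry.csv",
                       required = c("time_s", "A", "BI", "P"))
tc <- pts_timecourse(raw$time_s,
                     as.matrix(raw[, c("A", "BI", "P")]),
                     masses = c(A = 58.2, BI = 128.3, P = 70.1))
tc <- scale_to_limiting_total(tc)

overall <- fit_single_exponential(tc)
three <- fit_three_state(tc, inactive_offset = TRUE)

write_table_csv(
  data.frame(model = c("single_exponential", "three_state"),
             k_total_per_s = c(overall$k_total, NA),
             t_half_s = c(overall$t_half_s, NA),
             P_max = c(overall$P_max, three$P_max),
             k1_per_s = c(NA, three$k1),
             k2_per_s = c(NA, three$k2),
             k3_per_s = c(NA, three$k3)),
  "results/splice_kinetics.csv")

cat(sprintf("overall: k = %.4f /s (t1/2 = %.1f s), plateau = %.3f\n",
            overall$k_total, overall$t_half_s, overall$P_max))
cat(sprintf("three-state: k1 = %.4f, k2 = %.4f, k3 = %.4f /s, P_max = %.3f\n",
            three$k1, three$k2, three$k3, three$P_max))
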