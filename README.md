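# inteinkit

Quantitative analysis of split-intein assembly: protein trans-splicing
kinetics, biphasic biosensor binding, size-exclusion hydrodynamics, thermal
stability, and sequence charge–hydrophobicity profiles — with synthetic-data
generators that make every estimator testable by round-trip against known
ground truth.

## The scientific problem

Split inteins are protein domains split into an N-fragment and a C-fragment
that associate, fold, and splice themselves out while ligating their flanking
polypeptides (protein trans-splicing). Engineering them requires connecting
four kinds of measurement into one kinetic picture:

* **Splicing time courses** (gel densitometry of precursor A, branched
  intermediate BI, product P) fitted with
  `P(t) = P_max (1 − e^(−k_total · t))` or with the full three-state scheme
  `A ⇌(k1,k2) BI →(k3) P`, which has a closed-form solution with
  eigen-exponents `a, b = (p ± √(p² − 4·k1·k3)) / 2`, `p = k1 + k2 + k3`.
* **Binding kinetics** from biolayer interferometry (BLI), where biphasic
  sensorgrams are described by the two-step conformational-change model
  `N + C ⇌(ka,kd) N·C ⇌(kf,ku) NC`. The biexponential phase exponents depend
  linearly on analyte concentration (`σ1 + σ2 = ka·C + kd + kf + ku`,
  `σ1·σ2 = ka·C·(kf + ku) + kd·ku`), which identifies all four rates; the
  equilibrium constant follows as `Kd = 1 / (Ka1 (1 + Ka2))` with
  `Ka1 = ka/kd`, `Ka2 = kf/ku`.
* **Solution behavior** from SEC: `Kav = (Ve − V0)/(Vt − V0)`, a Stokes-radius
  calibration linear in `√(−log10 Kav)`, and aggregate/monomer quantification
  by trapezoidal peak integration.
* **Stability and sequence**: melt curves fitted with
  `Y = Ymin + (Ymax − Ymin)/(1 + 10^((T_M − T)·b))` after truncation at the
  fluorescence maximum, and the charge–hydrophobicity plane with boundary
  `R* = 2.785·H − 1.151`.

A mass-action ODE layer (`deSolve`) links the measured binding and splicing
rates in one simulation, `N + C ⇌ N·C ⇌ NC → SP`, and verifies that simulated
equilibrium occupancy reproduces the closed-form Kd.

## Worked example

Overall splice rates convert directly to half-lives:

```r
library(inteinkit)
half_life(0.1387)   # 4.997456 -> 5.0 s
half_life(0.0913)   # 7.591974 -> 7.6 s
```

Simulate a noisy gel time course from known truth and recover the kinetics:

```r
gel <- generate_pts_gel(k1 = 0.05, k2 = 0.01, k3 = 0.1,
                        active_fraction = 0.30, noise_sd = 0.05,
                        seed = 20240901)
tc  <- scale_to_limiting_total(gel$timecourse)
fit_single_exponential(tc)
#> k_total = 0.0260 /s, t_half = 26.7 s, P_max = 0.300
fit_three_state(tc, inactive_offset = TRUE)
#> k1 = 0.0522 /s, k2 = 0.0207 /s, k3 = 0.0973 /s, P_max = 0.297
```

Analyze a synthetic BLI dilution series (200 → 3.125 nM, 0.5% noise) with the
two-step model:

```r
rates <- list(ka = 1e5, kd = 1e-2, kf = 1e-2, ku = 1e-3)
sim <- generate_sensorgrams(rates, noise_sd = 0.005, seed = 20240902)
est <- analyze_sensorgrams(sim$sensorgrams, t0 = 500)
unlist(est[c("ka", "kd", "kf", "ku")])
#>      ka      kd      kf      ku
#> 9.87e4  9.97e-3  1.00e-2  1.00e-3      (all within 1.3% of truth)
macroscopic_rates(equilibrium_constants(est))[c("Kd", "kon", "koff")]
#> Kd = 9.18e-9 M, kon = 4.94e4 /(M s), koff = 4.99e-4 /s
```

The full analysis workflow lives in `analysis/` as numbered scripts
(`01_simulate.R` … `05_sec_stability_sequence.R`), each a thin driver over the
package functions; run them in order from the package root and they write
their tables under `results/`.

## License

MIT. See `LICENSE`.
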