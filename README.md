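# dose4d

Simulation of 4DCT dose-accumulation uncertainty under heterogeneous
respiratory motion, for medical physicists studying lung SBRT plan
robustness.

A treatment plan for a moving lung tumor is usually evaluated on a
traditional ten-phase 4DCT, which represents breathing as one uniform
cycle. Real breathing varies cycle to cycle, so the accumulated dose
computed from the ten traditional phases (D⁴ᴰ) can diverge from the dose
accumulated over the patient's entire breathing session (Dᵗʳᵘᵉ). `dose4d`
simulates that divergence end to end and implements a
probability-density-based robust ITV strategy that mitigates it:

* **Motion**: per-cycle model `Z(t) = A(cos⁴(πt/P) − 1/2)` with Gaussian
  amplitude `A ~ N(μ_A, σ_A)` and period `P ~ N(μ_P, σ_P)`, plus
  fiducial-like 30-Hz noisy traces; zero-phase low-pass filtering, cycle
  segmentation, ten-phase midpoint sampling.
* **Phantom**: 1-mm voxel grid with spherical GTVs (2/3/4 cm) at integer SI
  offsets −15..15 mm (93 sample images), phase mapping `⌊(i+15)/3⌋`, ITV as
  the union of phase GTVs.
* **Dose**: a parametric plan-dose surrogate (minimum ITV dose =
  prescription, ITV surface on a 70/80/90% isodose of the maximum, Gaussian
  penumbra) standing in for the clinical VMAT dose.
* **Accumulation & evaluation**: rigid sub-volume mean `D(e) = (1/I) Σ
  d(xᵢ(e))`, DVH metrics `D_x`, and the per-curve worst-case discrepancy

  `ΔD̄ₓ = Σⱼ maxₖ |D⁴ᴰₓ,ⱼ,ₖ − Dᵗʳᵘᵉₓ,ⱼ| / (J · Dᵗʳᵘᵉₓ,ⱼ) × 100%`,

  with linear trend fits and paired t / Wilcoxon comparisons of standard vs
  robust plans.

Because the dose engine is an analytic surrogate rather than an optimized
VMAT plan, discrepancy *magnitudes* are smaller than clinical ones; the
package reproduces the qualitative structure (directions, orderings,
significance) of the divergence and its mitigation.

## Worked example

```r
library(dose4d)

## one heterogeneous breathing session
params <- motion_params(15, 0.25, 4, 0.2, seed = 42)
simulate_trace(params)
#> Breathing trace: 5001 samples, 100.0 s at dt = 0.02 s, range [-11.28, 11.28] mm

## amplitude sweep: 4 scenarios x 3 replicate curves
bank <- generate_scenario_bank(table1_scenarios()[1:4, ], replicates = 3,
                               base_seed = 20190108)
res <- run_sweep(bank)
res$summary[, c("mean_excursion_mm", "delta_d95", "delta_d99")]
#>   mean_excursion_mm delta_d95 delta_d99
#> 1                 5     0.942      1.22
#> 2                10     1.731      1.70
#> 3                15     3.213      5.23
#> 4                20     7.973     11.71
fit_trend(res$summary$mean_excursion_mm, res$summary$delta_d99,
          "mean amplitude (mm)")
#> Trend vs mean amplitude (mm): slope 0.6998, intercept -3.787, R^2 0.872

## robust strategy for a ~10-mm, cv ~0.22 patient (five fractions)
tab <- table3_patients()
rob <- run_patient_robust(tab[tab$patient == 2, ], base_seed = 20190308)
rob$coverage_interval
#> lo hi
#> -6  6
rob$comparison
#> Paired comparison over 5 fractions: mean difference +0.125, paired-t p = 0.02338, Wilcoxon p = 0.05906
```

Reading the output: the worst-case D₉₉ discrepancy `delta_d99` grows with
the mean breathing amplitude (1.2% → 11.7% across 5–20 mm here), i.e. the
ten-phase evaluation becomes less trustworthy the larger and more variable
the motion. For the patient-like case, 80% of the per-cycle extreme tumor
positions require phase images out to ±6 mm — one image beyond the
traditional −5..5 set — and re-planning on the extended ITV raises the true
accumulated D₉₉ in every fraction (mean +0.13% of prescription, paired-t
p = 0.02).

A YAML-configured command-line front end (`inst/cli/dose4d`) exposes the
same pipeline as `simulate` / `evaluate` / `robust` subcommands via
`cmd_simulate()`, `cmd_evaluate()` and `cmd_robust()`.

## Package layout

* `R/motion.R`, `R/tables.R` — motion model, scenario bank, printed
  parameter tables
* `R/trace_processing.R` — filtering, segmentation, phase sampling,
  position pdfs, coverage intervals
* `R/phantom.R` — voxel grid, sphere masks, phase mapping, ITV, sample bank
* `R/dose_engine.R`, `src/edt.cpp` — plan-dose surrogate and the exact
  Euclidean distance transform behind it
* `R/accumulation.R` — rigid dose accumulation and DVH metrics
* `R/evaluation.R` — discrepancy records, ΔD̄ₓ, sweeps, trend fits, paired
  comparisons, the patient robust study
* `R/workflow.R` — run configurations, orchestration commands, manifests
* `vignettes/motion-dose-discrepancy.Rmd` — the methods vignette
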