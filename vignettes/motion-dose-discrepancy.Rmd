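---
title: "Simulating 4DCT dose-accumulation uncertainty under heterogeneous breathing"
author: "dose4d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating 4DCT dose-accumulation uncertainty under heterogeneous breathing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A lung-SBRT plan is evaluated on a traditional ten-phase 4DCT, which freezes
the patient's breathing into the phases of (effectively) a single cycle. Real
breathing is heterogeneous: amplitude and period vary from cycle to cycle,
so the tumor visits positions the planning 4DCT never sampled. The
accumulated dose computed from the ten traditional phases (`D4D`) can then
diverge from the dose actually accumulated over the entire breathing session
(`Dtrue`). `dose4d` simulates this divergence end to end — breathing-trace
generation, phase-based sorting, a digital spherical-tumor phantom, a
parametric plan-dose surrogate, rigid dose accumulation, and DVH evaluation
— and implements a probability-density-based robust ITV strategy that
mitigates it.

## Motion model

Each breathing cycle follows

$$Z(t) = A\left(\cos^4\!\left(\frac{\pi t}{P}\right) - \tfrac12\right),
  \qquad t \in [0, P),$$

with the peak-to-peak amplitude $A \sim N(\mu_A, \sigma_A)$ and the period
$P \sim N(\mu_P, \sigma_P)$ redrawn independently for every cycle;
$\sigma_A = \mathrm{cv}_A\,\mu_A$ and $\sigma_P = \mathrm{cv}_P\,\mu_P$.
Every cycle starts and ends at its peak $+A/2$, so concatenated cycles join
with a jump of at most $|A_k - A_{k+1}|/2$. A session lasts 100 s (a typical
4DCT acquisition). Positive $Z$ is superior; motion is SI-only (no
hysteresis, no baseline drift, no RL/PA components).

Numerical choices:

* Gaussian draws at or below 0.5 mm (amplitude) or 0.5 s (period) are
  **redrawn**, not clipped, to avoid a point mass at the floor. For
  cv $\le$ 0.35 the induced mean bias is below 1% of the mean.
* Simulated traces are sampled at 0.02 s; fiducial-like patient traces at
  30 Hz with additive Gaussian measurement noise (0.5 mm by default).
* A cycle cut by the end of the session stays in the trace but is excluded
  from cycle-wise statistics.
* Scenario banks derive the replicate seed as
  `base_seed + 1000*row + replicate`, so a whole bank reproduces
  bit-identically from one integer.

The generator emulates the cycle-to-cycle variability of real breathing and
the sampling/noise characteristics of fluoroscopic fiducial tracking. It
does not emulate baseline drift, hysteresis loops, coughs/swallows, or
correlated amplitude-period dynamics; conclusions drawn from passing tests
therefore concern heterogeneity of the modelled kind, not every failure
mode of clinical traces.

## Phase sorting and cycle segmentation

Measured traces are low-pass filtered (4th-order Butterworth, 1 Hz default,
applied forward and backward so the filter is zero-phase and extremum
timestamps do not shift). The filter pads the signal by odd reflection over
10/cutoff seconds before filtering; without padding the forward-backward
pass leaves millimetre-scale edge transients that destroy the boundary
peaks. Extrema are detected, forced to alternate, and pruned with a
prominence threshold of 20% of the displacement IQR (plateaus resolve to
their first sample).

For phase sampling, a span of the trace is divided into ten equal time
intervals and the displacement is taken at each interval midpoint (linear
interpolation between samples). The clinical literature is ambiguous about
whether the ten intervals span a half breathing cycle (one neighboring
peak-valley pair) or a full peak-to-peak cycle; both are implemented
(`phase_sample_cycles(mode = "full_cycle")`, the common clinical
convention and the package default, vs `"half_cycle"`), and the
per-cycle traditional accumulation uses the full-cycle convention.

## Position pdfs and the robust strategy

Two empirical position distributions are available:

* `empirical_position_pdf()` — the **occupancy** histogram of the trace in
  1-mm bins (ties rounded away from zero). Note that the $\cos^4$ waveform
  dwells roughly three times longer near its valley than near its peak, so
  this distribution is strongly asymmetric even for symmetric motion
  parameters.
* `cycle_extreme_pdf()` — the distribution of **per-cycle extreme
  positions** (each cycle's peak and valley displacement).

The robust strategy extends the traditional phase-position set with every
integer position in the 80% equal-tail coverage interval of the pdf,
rebuilds the ITV and re-plans. It uses the *extreme-position* pdf: phase
images are added to cover the positions breathing cycles actually reach,
and an interval of the occupancy pdf would be dominated by valley dwell
(its equal-tail interval is asymmetric and, for a ~10-mm patient with
cv ~0.22, never reaches the +6 mm extension that covering the cycles
requires). For such a patient the extreme-position interval is (-6, +6),
extending the traditional -5..5 set by one image on each side.

## Phantom and dose surrogate

The phantom is a 1-mm isotropic voxel grid (default 120^3) holding
spherical GTVs of 2, 3 or 4 cm diameter at integer SI offsets -15..15 mm
(93 sample images in total; a voxel belongs to a sphere iff its center
does). Offset $i$ maps to phase $\lfloor (i+15)/3 \rfloor$ with $i = 15$
assigned to phase 9. The clinical CT background is not reproduced: the
dose stand-in below depends only on geometry, so tissue heterogeneity
would not change anything it computes.

The traditional ITV is the union of the phase GTVs of a homogeneous
planning curve with the scenario's mean amplitude (patient plans use the
first — planning — fraction's amplitude, since planning precedes
treatment). For a ~10-mm amplitude these positions span SI = -5..5 mm.

The plan-dose surrogate reproduces the dosimetric structure of the VMAT
plans it stands in for, parametrically: with $s$ the signed distance to the
ITV surface (negative inside) and $L$ the isodose level,

$$D(s \le 0) = D_{max}\left(L + (1-L)\,\min(1, -s/c)\right), \qquad
  D(s > 0) = R_x\, e^{-s^2/2\sigma^2},$$

where $R_x$ is the prescription (60 Gy in 5 fractions), $D_{max} = R_x/L$
(so the ITV surface lies on the $L$ = 70/80/90% isodose of the maximum),
$c$ = 5 mm is the depth at which the interior plateau is reached and
$\sigma$ = 3 mm scales the exterior Gaussian penumbra (generic lung-SBRT
values, both configurable; the exterior 80%-to-20% fall-off distance is
$(\sqrt{2\ln 5} - \sqrt{2\ln 1.25})\,\sigma \approx 1.13\sigma$). The
signed distance is computed from exact Euclidean distance transforms of
the ITV mask and its complement, with the surface passing through the
centers of the outermost mask voxel layer: boundary voxels sit at $s = 0$
(dose exactly $R_x$, making the minimum ITV dose the prescription and the
min/max ratio exactly $L$) and the first exterior ring at one voxel pitch.

Because this field is an analytic surrogate rather than an optimized VMAT
dose, all downstream discrepancy numbers reproduce the qualitative
structure of the clinical study — directions, orderings, significance —
not its printed dosimetric magnitudes, which are several-fold larger.

## Accumulation and evaluation

Rigid accumulation follows the sub-volume mean

$$D(e) = \frac{1}{I}\sum_{i=1}^I d(x_i(e)),$$

with displacements rounded to the integer-mm sample bank (configurable;
linear interpolation along SI when rounding is off) and clamped to
$\pm 15$ mm with a warning. `D4D` uses the ten phase samples of one cycle
($I = 10$); `Dtrue` resamples the whole trace at 0.4 s ($I \approx 250$
per 100-s session). The resampler takes interval midpoints — the same
midpoint rule as the phase sorting — so homogeneous breathing with
$P = 10\,\Delta t$ gives matching samplings and the null case reflects
only incommensurate periods.

$D_x$ is the dose at rank $\lceil x/100 \cdot N \rceil$ of the
descending-sorted voxel doses (no interpolation; the conservative lower
value), reported as percent of prescription. The headline statistic is the
per-curve worst case averaged over curves,

$$\overline{\Delta D_x} = \sum_{j=1}^{J}
  \frac{\max_k |D^{4D}_{x,j,k} - D^{true}_{x,j}|}{J\,D^{true}_{x,j}}
  \times 100\%,$$

whose ratio form makes it invariant to the dose scale. Both the paired
t-test and the Wilcoxon signed-rank test are reported for the
standard-vs-robust comparison; over 5 fractions the two-sided Wilcoxon
cannot fall below 0.0625, so the t-test carries the significance call.

## Problem sizes

The packaged tests run the sweep at 5 replicates per scenario over the
8 scenarios that form the amplitude, amplitude-cv and period sweeps, the
patient studies at 5 fractions each, and distribution-recovery checks at
2000 cycles; these sizes give stable orderings while keeping a full test
run under half a minute on one core. The full study conditions (10
replicates for each of the 10 scenario rows, 100 curves in total) are the
generator defaults.

## A full run

```{r}
library(dose4d)

bank <- generate_scenario_bank(table1_scenarios(), replicates = 10,
                               base_seed = 20190108)
res <- run_sweep(bank)
res$summary

tab <- table3_patients()
rob <- run_patient_robust(tab[tab$patient == 3, ], base_seed = 20190408)
rob$comparison
```

## Known limitations

* Rigid SI-only motion: no deformation, no interplay between MLC motion
  and breathing, no RL/PA components, no baseline drift.
* The parametric dose field has an exactly flat interior plateau and an
  exactly uniform surface dose; real plans carry dose heterogeneity that
  makes DVH quantiles respond more smoothly, so desk-scale discrepancies
  are smaller than clinical ones.
* Position pdfs are binned at the 1-mm resolution of the phantom bank;
  sub-millimetre coverage distinctions are not representable.
* The paired tests treat the five fractions as independent replicates, as
  the clinical analysis does.
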