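---
title: "Methods: single-cell MAR estimation and drug-sensitivity classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell MAR estimation and drug-sensitivity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmrMAR)
```

# The measurement model

A serial SMR weighs each flowing object once per sensor. We model the
buoyant mass of a cell as **linear in time** over the ~20-minute
observation window,

$$m(t) = m_0 + \mathrm{MAR}\cdot t,$$

because the window is short relative to a doubling time; exponential and
linear growth are indistinguishable at this scale, and the assay's readout
is the slope of a linear least-squares fit. The measured signal at sensor
$k$ is the instantaneous mass times a global calibration scale plus i.i.d.
Gaussian noise with standard deviation `mass_noise_sd` (default 50 fg, the
single-measurement precision the instrument class achieves). MAR is
reported in pg/h — times are kept in seconds internally and converted to
hours only at fit time — and MAR per mass (1/h) divides each cell's MAR by
the **mean of its own measured masses**. The mean (rather than the first
measurement or the fitted intercept) is symmetric in the points and needs
no extrapolation; for the short window the three differ by well under a
percent of mass.

`fit_mar` rejects traces whose times are all identical, returns residual
SD 0 for two-point traces (an exact fit has no residual degrees of
freedom), and flags records with non-positive mean mass as invalid; those
are excluded from summaries and tests.

# What the simulator emulates — and what it does not

`simulate_run` generates the statistical structure the analysis assumes:

* `n_sensors = 10` sensors, transit times per delay channel drawn from a
  Gaussian with mean 105 s and SD 8 s (inside the 1.5–2 min cadence of
  real devices), truncated at 3 SD so transits stay physical;
* cell masses $\mathcal{N}(50, 10^2)$ pg and MARs $\mathcal{N}(5, 2^2)$
  pg/h, values typical of myeloma-line measurements; negative mass draws
  are **resampled**, not clamped, so the distribution shape is preserved;
* spiked polystyrene beads with nominal buoyant mass 12.6 pg — an 8 µm
  sphere at 1.05 g/cm³ in medium of 1.003 g/cm³ (`bead_buoyant_mass`) —
  a 1% bead-to-bead mass CV (manufacturing tolerance), and exactly zero
  MAR;
* Poisson-like arrivals at `arrival_rate = 0.5` objects/min with a spacing
  floor (below);
* a condition-level treatment modelled as an additive downward shift of
  every true MAR (`drug_effect`, pg/h); 0 is the resistant model.

The instrument does not report an in-run arrival rate; 0.5/min is chosen
so that consecutive objects are usually minutes apart, which is what makes
event linking solvable at all — on a device run at much higher throughput
the matching problem is harder than anything this generator produces.

The generator deliberately omits resonator physics (peak fitting,
frequency modes), flow irregularities, cell clumps and doublets, detection
artifacts correlated across sensors, and any biology beyond the MAR shift
(no death dynamics, no mass-dependent drug response). Passing tests
therefore demonstrate that the **analysis** is correct under its stated
assumptions, not that those assumptions hold on any particular instrument
or sample.

# Event linking

Detections at adjacent sensors are linked by minimum-cost bipartite
assignment. For an upstream event $a$ and downstream event $b$ with delay
$\Delta t$ and signal difference $\Delta s$:

* pairs with $\Delta t$ outside `transit_window` (default: mean transit
  ± 4 SD) are forbidden;
* otherwise
  $c(a,b) = w_t\,\lvert\Delta t - \text{mid}\rvert/\text{halfwidth} +
  w_m\,\lvert\Delta s\rvert/\text{tol}$ with $w_t = w_m = 1$ — two
  symmetric, dimensionless residuals;
* every event may instead stay unlinked at `unmatched_cost = 4`, so a pair
  must beat the cost (8) of leaving both events unlinked.

`mass_tolerance` defaults to 0.25 pg, a few times the noise on a signal
difference ($\sqrt2 \times 50$ fg), so that true pairs cost $\ll 1$ while
pairs of different cells (masses pg apart) are effectively forbidden. The
rectangular problem is squared by dummy augmentation and solved exactly
with an internal $O(n^3)$ Jonker–Volgenant shortest-augmenting-path solver;
the test suite verifies its optimum against exhaustive enumeration on
hundreds of random instances. Determinism: events are sorted by time then
event id before the cost matrix is built, so cost ties break toward
earlier events and lexicographically smaller ids. Matchings between
consecutive sensors are chained transitively; a missing link terminates
the trace and chains are never re-joined across a gap — we prefer losing
the tail of a trace to risking a spurious long-gap link. Single-event
chains are reported as unlinked, and `filter_traces` (default
`min_points = 4` in the pipeline) drops short fragments before fitting.

**Well-posedness of the zero-noise oracle.** The matching tests demand
exact recovery of ground truth when mass noise is zero. Two design choices
make that meaningful: (i) the arrival-spacing floor is 6 transit-time SDs
— with transits truncated at 3 SD, an adjacent-arrival swap then strictly
increases the time cost at the first sensor pair, and spacing drift across
later channels is overwhelmingly unlikely to close a gap that large at the
default arrival rate; (ii) beads carry a realistic 1% mass CV, because
*exactly* identical bead masses would make bead–bead swaps undetectable in
principle (the time cost alone cannot always distinguish them). The
recovery invariant is validated over 100 fixed simulation seeds.

# Calibration

Bead traces are gated by mean raw signal in a closed interval (boundary
values count as beads; beads are tight in mass, cells broad, so the gate
placement is uncritical). The scale is the single global scalar
`nominal / mean(all bead signals)`, which makes the grand mean of
calibrated bead masses equal the nominal mass exactly — per-sensor gains
and drifts are out of scope. Because the scale is estimated from a finite
bead sample, it carries a relative error of roughly
`bead_mass_cv / sqrt(n_beads)`; exact end-to-end recovery tests therefore
use `bead_mass_cv = 0`. The nominal bead buoyant mass is a required input
(with `bead_buoyant_mass()` computing a physical default from sphere
volume × density contrast), since the buoyant mass of an 8 µm bead depends
on the medium. The pooled SD of calibrated bead signals about each bead's
mean estimates the measurement noise; the mean per-bead OLS slope checks
the zero-MAR baseline.

# Classification and statistics

`fit_lda` is Fisher's two-class discriminant with pooled within-class
covariance and equal priors, on the features `(mean mass, MAR)` — the
plane in which the assay's scatter plots are drawn; a flag switches to
`(mean mass, MAR/mass)`. When the pooled covariance is near-singular
(e.g. a constant feature) a ridge of $10^{-6}\,\mathrm{tr}(S)/2$ is added
with a warning. The weight sign is fixed so treated cells project low,
which pins the ROC orientation and prevents AUC < 0.5 flips; scores are
negated before ROC computation so higher = more treated-like. AUC uses the
Mann–Whitney pair-counting form with ties counting ½, and the emitted ROC
point set integrates (trapezoid) to exactly that number — an identity the
tests assert on random score sets. The ROC/AUC is computed on the same
cells the discriminant was fitted to, as the assay does; with two features
this in-sample optimism is mild but visible at small cohorts (null AUC
≈ 0.52 at 500 cells/arm and ≈ 0.56 at 60 cells/arm, rather than exactly
0.5).

Condition-level shifts are tested with Welch's unequal-variance *t*-test
(via `stats::t.test`) on MAR per mass, two-sided, with Welch–Satterthwaite
degrees of freedom; when both groups have zero variance, equal means give
$p = 1$ by convention and unequal means are rejected as degenerate.
P-values are Bonferroni corrected with an explicit, user-supplied family
size `m` (the number of treatment comparisons in the analysis; the
pipeline defaults to counting its own manifest), and a sample is called
**sensitive** when the corrected $p$ beats the family-wise `alpha` —
equivalently raw $p <$ `alpha/m`, e.g. 0.05/9 ≈ 0.0056.

# Reproducibility and problem sizes

Every stochastic stage takes an explicit seed; the pipeline derives
condition $i$'s seed as `seed + i` and records it in the output manifest,
so a rerun is bit-identical. The validation suite runs at the assay's own
scale — 60 cells per arm, 10 sensors, 50 fg noise — using 100 seeds for
exact-recovery checks, 200 random instances for assignment optimality,
1000 simulated null pairs for type-I calibration (bounded by `alpha/m`
within binomial error) and a 6-point drug-effect grid for the monotone
dose–response of the median AUC. Statistical-calibration checks draw
per-cell (mass, MAR) records directly from the population model rather
than re-running the sensor simulation, since the quantity under test is
the downstream statistics.

# Known limitations

* A broken link shortens a trace rather than bridging it, so heavy dropout
  biases traces short; `min_points` trades retention against fit variance.
* The single global calibration scalar ignores per-sensor gain variation.
* The drug model is a pure location shift of MAR; real responses also
  change spread, mass, and the shape of the MAR distribution.
* LDA assumes shared within-class covariance; strongly heteroscedastic
  treated populations would favour a quadratic or rank-based classifier.
* The matcher is single-hypothesis: it will not recover crossings of
  near-identical objects at high arrival rates, and it does not model
  doublets.
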