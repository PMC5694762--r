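# ssmrMAR

Single-cell mass accumulation rate (MAR) analysis for serial suspended
microchannel resonator (sSMR) drug-sensitivity assays.

## The problem

An sSMR device is an array of 10–12 microfluidic mass sensors connected in
series by delay channels. A live cell flowing through the array is weighed
once per sensor, roughly every 1.5–2 minutes, with ~50 fg precision —
three orders of magnitude below a cell's buoyant mass (tens of pg). The
slope of the linear least-squares fit of buoyant mass against time is the
cell's **mass accumulation rate**:

```
MAR = Σ(tᵢ − t̄)(mᵢ − m̄) / Σ(tᵢ − t̄)²        [pg/h, t in hours]
```

Cells that respond to a drug stop accumulating mass within hours — long
before bulk viability assays show anything — so the distribution of
single-cell MAR (and MAR normalized by each cell's own mass, 1/h) separates
drug-sensitive from drug-resistant populations. This package implements the
complete analysis for that assay, aimed at anyone building or using serial
mass sensors for functional drug-response profiling:

1. **`smr_sim`-style simulator** (`simulate_run`): synthetic per-sensor
   detection events with ground truth — growing cells, spiked zero-MAR
   polystyrene beads, Gaussian transit and mass noise — so the whole
   pipeline is testable without instrument data.
2. **Trace building** (`match_adjacent`, `build_traces`): events at adjacent
   sensors are linked by a gated minimum-cost bipartite assignment
   (Hungarian-type solver), chained across the array into per-cell
   mass-vs-time traces.
3. **Bead calibration** (`gate_beads`, `fit_calibration`,
   `apply_calibration`): spiked beads of known buoyant mass provide the
   absolute-mass scale, a zero-MAR baseline, and a noise estimate.
4. **MAR estimation** (`fit_mar`, `fit_mars`, `summarize_condition`):
   per-cell MAR, MAR/mass, negative-MAR fraction.
5. **Sensitivity classification** (`fit_lda`, `roc_auc`, `welch_test`,
   `bonferroni`, `call_sensitivity`): Fisher LDA projects each cell's
   (mass, MAR) onto the axis best separating control from treated; ROC/AUC
   (Mann–Whitney pair counting) scores single-cell separability (0.5 =
   indistinguishable, 1 = perfect); Welch's *t*-test on MAR/mass with
   Bonferroni correction calls the sample *sensitive* or *resistant*.

## Worked example

Simulate one patient-like sample: a control arm and a bortezomib arm whose
true MAR distribution is shifted down by 8 pg/h, 60 cells plus 10 beads per
arm, 10 sensors, 50 fg noise, Bonferroni family of 9 comparisons.

```r
library(ssmrMAR)

cfg <- run_config(
  population = population_config(n_cells = 60, n_beads = 10),
  conditions = list(
    list(sample_id = "P1", condition_label = "control",
         drug_effect = 0, is_control = TRUE),
    list(sample_id = "P1", condition_label = "bortezomib",
         drug_effect = 8)),
  family_size = 9, seed = 42)
res <- run_pipeline(cfg)

print(res$summaries$control)
#> Condition 'control': 60 cells
#>   mean MAR/mass 0.1093 1/h; negative-MAR fraction 0.000
#>   mass median 51.1 pg (IQR 44.1-56.2)
print(res$summaries$bortezomib)
#> Condition 'bortezomib': 60 cells
#>   mean MAR/mass -0.0659 1/h; negative-MAR fraction 0.917
#>   mass median 46.8 pg (IQR 41.4-55.1)
print(res$conditions$control$calibration)
#> sSMR bead calibration: scale 0.999239 pg/unit from 10 beads
#>   bead slope -0.007899 pg/h (expect ~0); noise SD 47.3 fg
```

Under treatment the mean MAR/mass flips from +0.11/h to −0.066/h and 92% of
cells are losing mass, while the mass distribution barely moves. The
classifier output for the pair:

```r
r <- res$results$bortezomib
#> AUC 1.000 | t -19.92 (df 118.0) | p_raw 1.48e-39 | p_corr 1.33e-38 | call sensitive
```

An AUC of 1 means every treated cell projects below every control cell on
the LDA axis; the Bonferroni-corrected Welch *p* is far below the 0.05
family-wise level (equivalently, raw *p* < 0.05/9 ≈ 0.0056), so the sample
is called **sensitive**. Rerunning with `drug_effect = 0` gives AUC ≈ 0.5
and a *resistant* call. `run_pipeline(cfg, out_dir = "out")` additionally
writes every intermediate table (events, traces, calibration, MAR records)
plus `results.json` and a reproducibility manifest; a command-line wrapper
with `run` and `simulate` subcommands is installed at
`inst/scripts/run_ssmr.R`.

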