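# tgflsci

Analysis of renal **tubuloglomerular feedback (TGF)** hemodynamics from
high-resolution **laser speckle contrast imaging (LSCI)**, with a fully
synthetic data module so every stage is testable without animal recordings.

## The scientific problem

Each nephron autoregulates its blood flow. The TGF mechanism — macula densa
sensing of distal tubular NaCl driving afferent arteriolar constriction —
produces slow flow oscillations (0.015–0.04 Hz) in the stellate "star
vessels" of the renal cortex, alongside a faster myogenic component
(~0.1 Hz). LSCI images dozens of these microvessels at once: moving blood
cells blur the laser speckle, so the *temporal contrast*
K = σ/μ of each pixel across a 25-frame kernel at 50 Hz encodes flow, and
BFI = 1/K² is a per-pixel blood-flow index, subsampled to 1 Hz.

The package implements the full chain for two-period (control vs. drug)
experiments:

1. **Registration** — track a dark myograph-wire fiducial by phase
   correlation and align every frame to frame 1 (breathing motion removal).
2. **Speckle core** — temporal contrast → BFI → 1 Hz flow stacks and
   time-averaged flow maps.
3. **Segmentation** — threshold + morphology labeling of star vessels,
   with optional seed points; per-vessel flow time series extraction.
4. **Time–frequency** — **superlet** spectra: at each frequency f, the
   squared geometric mean of Morlet responses with cycle counts
   c₁, 2c₁, …, oc₁ — P(t,f) = [∏ᵢ Rᵢ(t,f)]^(2/o) — resolving slow,
   drifting TGF oscillations better than any single-resolution transform;
   plus a single/none/multiple TGF peak taxonomy.
5. **Metrics** — per vessel and period: mean **BFI**; **Sigma**, the SD of
   the 0.015–0.04 Hz band-filtered series (oscillation amplitude); and
   **AUC**, the band power integral minus a 0.04–0.05 Hz median baseline.
6. **Statistics** — linear mixed-effects comparison
   `metric ~ period + (1 | animal)` with Satterthwaite F tests at
   p < 0.001, plus paired t-tests and box-plot summaries.
7. **Synthetic data** — generators for flow series (TGF + myogenic +
   noise, optional chirp), star-vessel flow maps, dynamic speckle stacks
   (gamma intensities with CV = 1/√BFI, wire fiducial, breathing motion),
   and multi-animal cohorts with furosemide (+11.3 % flow, oscillation
   abolished) and phlorizin (−6.42 % flow, oscillation attenuated)
   presets — each paired with its ground truth.

## Worked example

Simulate a furosemide experiment (3 animals × 20 vessels, 15-min periods),
compute the three metrics, and test the oscillation-amplitude change:

```r
library(tgflsci)

coh <- gen_cohort(
  cohort_design(n_animals = 3, vessels_per_animal = 20, drug = "furosemide",
                base_params = flow_series_params(duration_s = 900)),
  seed = 7)
metrics <- compute_metrics(coh)
metrics
#> # A tibble: 120 × 6
#>    animal_id vessel_id period  bfi_mean sigma      auc
#>        <int>     <int> <chr>      <dbl> <dbl>    <dbl>
#>  1         1         1 control     71.4 1.79   1.21
#>  2         1         1 drug        79.4 0.431 -0.0168
#>  3         1         2 control     71.4 1.50   0.925
#>  4         1         2 drug        79.6 0.436  0.0255
#> # ℹ 116 more rows

compare_periods_lme(metrics, "sigma")
#> <tgf_comparison> sigma: period effect -1.702 (F = 253.4, p = 3.7e-31) *significant at p < 0.001*
#>   60 vessels, 3 animals; linear mixed-effects (Satterthwaite F)
```

The period effect −1.70 is the drop in Sigma (band-filtered flow SD, in
arbitrary BFI units) from control to drug: the TGF oscillation is gone,
exactly the furosemide signature. Mean BFI rises ~11 % in the same cohort
(`compare_periods_lme(metrics, "bfi_mean")`), and the AUC collapses to the
noise floor, as the box summary shows:

```r
summarize_boxstats(metrics)
#> # A tibble: 6 × 6
#>   metric   period      q25   median     q75     n
#> 1 auc      control  0.833   1.57     3.30      60
#> 2 auc      drug    -0.0223  0.00697  0.0260    60
#> 3 bfi_mean control 54.0    56.5     71.4       60
#> 4 bfi_mean drug    60.1    62.9     79.5       60
#> 5 sigma    control  1.44    2.00     2.83      60
#> 6 sigma    drug     0.412   0.443    0.480     60
```

`plot_carpet()`, `plot_metric_box()` and `plot_metric_scatter3d()` render
the standard figures; `run_pipeline(pipeline_config(...), out_dir)`
orchestrates everything (optionally including an imaging-side
stack-to-series demonstration) and writes CSV/JSON results, figures, and a
reproducibility manifest. A thin CLI lives in `inst/scripts/tgf-lsci.R`.

## The methods vignette

`vignettes/tgf-lsci-methods.Rmd` documents the models, parameter
conventions (Morlet/superlet settings, cone of influence, filter
contracts), the synthetic generators' scope, and known limitations.
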