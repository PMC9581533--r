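# macroflim

Label-free phenotyping of dermal macrophages from two-photon excited
fluorescence lifetime imaging (TPE-FLIM) data.

M1 (inflammation-promoting) and M2 (anti-inflammatory) macrophages run
different metabolic programs, and the balance of free vs bound NAD(P)H
shifts their autofluorescence decay: M1 cells have short lifetimes and a
dominant short component, M2 cells longer lifetimes. `macroflim` turns
that contrast into a tested analysis pipeline for researchers working
with TCSPC/FLIM data of skin:

* **Synthetic data** — a bundled reference table of per-class decay
  parameter distributions (mean ± SD of τ1, τ2, τm, a1/a2, intensity) for
  macrophages and the other autofluorescent dermal cells, with per-class
  counts assembling a 399-cell reference set; simulators for TCSPC decay
  histograms (Gaussian IRF, 80 MHz periodic excitation with analytic
  wrap-around, Poisson noise) and small FLIM image cubes.
* **Decay fitting** — bi-exponential model
  `I(t) = a1·exp(-t/τ1) + a2·exp(-t/τ2)` fitted by Poisson maximum
  likelihood with IRF shift and offset, multi-start initialisation,
  Pearson reduced χ², spatial binning (49-pixel windows) and intensity
  thresholding for image cubes.
* **FLIM features** — the 8-value classifier vector (τ1, τ2, a1, a2,
  τm = (a1τ1+a2τ2)/(a1+a2), τ2/τ1, a1/a2, (a1−a2)/(a1+a2)), intensity
  normalisation, and per-pixel 2D segmentation by class parameter boxes.
* **Phasor analysis** — first-harmonic phasor transform, analytic phasor
  of a fitted decay (chord geometry on the universal semicircle),
  relative-intensity masking.
* **Classification & evaluation** — a from-scratch CART decision tree
  with entropy impurity (max depth 9, min samples split 2), verified
  prediction-for-prediction against a reference CART implementation;
  repeated random 50/50 split evaluation with one-vs-rest
  sensitivity/specificity, ROC curves, fivefold cross-validation, and
  Kolmogorov–Smirnov distribution comparison.

## Worked example

```r
library(macroflim)

## the 399-cell synthetic reference set drawn from the bundled table
cells <- simulate_reference_cells(seed = 1)
feats <- cells_to_features(cells)          # 8 features + 0/1/2 labels

## the published evaluation protocol: 1,000 random 50/50 splits
rep <- repeated_split_eval(feats$X, feats$y, n_repeats = 1000, seed = 1001)
rep
#> Repeated 50/50 split evaluation (1000 repeats, 0 re-draws):
#>   class 0: sensitivity 0.892 +- 0.056, specificity 0.961 +- 0.016
#>   class 1: sensitivity 0.501 +- 0.098, specificity 0.859 +- 0.045
#>   class 2: sensitivity 0.736 +- 0.067, specificity 0.712 +- 0.058
```

Class 0 is M1, class 1 is M2, class 2 is every other dermal cell; each
row is the mean ± SD over the 1,000 test halves of the one-vs-rest
sensitivity and specificity read off the confusion matrix. M1 cells are
nearly always recovered (their lifetimes are the shortest and their
amplitude ratio the highest in the set); M2 recovery is limited by the
overlap of the published M2, dendritic-cell, neutrophil and mast-cell
parameter ranges — see the methods vignette for why independent
marginal sampling makes this overlap worse than in the real data.

```r
## simulate one in vivo M1-like decay and fit it back
h <- simulate_decay(list(tau1 = 196, tau2 = 1698, a1 = 5/6),
                    total_photons = 1e5, seed = 7)
fit <- fit_biexponential(h)
fit
#> Bi-exponential fit: tau1 = 194 ps, tau2 = 1697 ps, a1 = 0.835,
#>   a1/a2 = 5.07, chi2_red = 1.049

phasor_from_fit(fit)
#> Phasor point (harmonic 1): g = 0.7298, s = 0.3481
```

The fit recovers the ground truth (τ1 = 196 ps, τ2 = 1698 ps,
a1/a2 = 5) within about 1% at 10^5 photons, with a reduced χ² near 1, and
the phasor point lies on the chord between the two component lifetimes on
the universal semicircle.

A YAML-configurable end-to-end run (all tasks, CV, ROC) is
`run_classification_protocol(pipeline_config(seed = 1))`, and
`inst/cli/macroflim.R` exposes the pipeline as shell subcommands
(`simulate`, `fit`, `features`, `phasor`, `train`, `evaluate`,
`report`).

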