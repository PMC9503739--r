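# ramanclass

Statistical classification of surface-enhanced Raman (SERS) spectra of
genomic DNA into healthy (0) and tumoral (1).  SERS maps of DNA droplets
dried on silver-coated silicon nanowires yield thousands of spectra
(1680 channels over 50.6–3288.5 cm⁻¹) whose band structure — most
visibly around 1550 cm⁻¹ — differs between healthy and tumoral DNA.
`ramanclass` provides the full analysis pipeline for such data, for
spectroscopists and biostatisticians who want a tested, reusable
implementation rather than ad-hoc scripts:

* **Preprocessing** — Savitzky–Golay smoothing (order 5, 91-point window,
  raw values kept at the edges) and per-class outlier rejection by a
  decision surface: a spectrum is discarded if it leaves the channel-wise
  band mean ± 3·SD at any channel.
* **The "local" classifier** — column-center the training matrix
  (y<sub>ij</sub> = x<sub>ij</sub> − x̄<sub>·j</sub>), take the leading
  *m* principal components (thin SVD; default *m* = 4), fit the logistic
  model logit Pr(W = 1 | z) = β₀ + Σ βᵢzᵢ, and call tumoral when the
  fitted probability is ≥ λ.
* **The "global" classifier** — squared ℓ2 distances d_h, d_t of a test
  spectrum to the healthy and tumoral training mean spectra, with the
  τ-weighted decision g = 1{τ·d_t ≤ (1 − τ)·d_h}.
* **Tuning and evaluation** — stratified 10-fold cross-validation over a
  threshold grid; the optimum maximizes the fold-averaged Youden index
  J = sensitivity + specificity − 1; ROC/AUC by trapezoidal integration
  of the sweep; Cohen's κ = 2(TP·TN − FP·FN) / [(TP+FP)(FP+TN) +
  (TP+FN)(FN+TN)]; and joint-classifier agreement tables with NPV, PPV,
  joint accuracy and disagreement rates.
* **Synthetic data** — a generator of Raman-like two-class spectra
  (Lorentzian bands, correlated noise, gross artifacts) so the whole
  pipeline is testable without any measured data set.

Spectra live in a `SpectraSet`, a `SummarizedExperiment` subclass
(channels × spectra, labels in `colData`), so the usual Bioconductor
subsetting and accessors apply.

## Worked example

```r
library(ramanclass)

cfg <- syntheticConfig(nPerClass = 500, seed = 11)   # 1000 x 1680 spectra
raw <- simulateSpectra(cfg)
raw
#> SpectraSet with 1000 spectra x 1680 channels
#>   Raman shift: 50.6 .. 3288.5 cm^-1
#>   labels: 500 healthy (0), 500 tumoral (1)
#>   simulated artifacts: 160 flagged

pp <- preprocessSpectra(raw)        # smooth, then 3-sigma filter per class
round(100 * pp$report$discardFraction, 1)
#> [1] 8.4

res <- evaluateJoint(pp$spectra, seed = 7)   # 10-fold CV, grids 0..1 by 0.01
res$local$optimalParameter; res$local$auc
#> [1] 0.01
#> [1] 1
res$global$optimalParameter; res$global$auc
#> [1] 0.38
#> [1] 1
round(res$kappa, 2)
#>  local global
#>      1      1
round(res$local$confusion, 1)
#>   TP   FP   FN   TN
#> 49.6  0.0  0.0 50.4
```

Reading the output: 8.4 % of spectra left their class envelope and were
discarded (the injected artifact rate is 15 %, but smoothing repairs the
single-channel spikes, so only the baseline-shift artifacts and a few
false alarms are removed).  Both classifiers then separate the two
classes perfectly — the default synthetic class effect (a 1550 cm⁻¹ band
gap of 500 a.u. against correlated noise of sd 40 a.u.) is deliberately
clear-cut; it exercises the machinery, not the difficulty of measured
data.  On measured spectra the same statistics land well below 1 (κ in
the 0.6 range), and the joint tables (`res$joint`) become informative:
NPV/PPV of unanimous calls, the joint accuracy among concordant
predictions, and the disagreement rate.

`writeReport(res, "results")` serializes everything to `results.json`
plus a markdown report.  A thin command-line wrapper with `simulate`,
`preprocess` and `evaluate` subcommands is installed at
`system.file("scripts", "raman-pipeline.R", package = "ramanclass")`.

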