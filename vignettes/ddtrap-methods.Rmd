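---
title: "ddtrap: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ddtrap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddtrap)
```

## The assay in computational terms

The droplet digital TRAP (ddTRAP) assay measures telomerase enzyme activity
by letting telomerase in a cell lysate extend a synthetic substrate
oligonucleotide, partitioning the extension products into ~20,000 emulsion
droplets of ~0.85 nl, PCR-amplifying to endpoint, and counting which
droplets fluoresce. Because a droplet can hold more than one template, the
positive-droplet fraction $\hat p$ understates the template count; the
digital-PCR correction inverts the Poisson zero-class,

$$\hat\lambda = -\ln(1 - \hat p), \qquad
  \text{copies/}\mu\text{l} = \frac{\hat\lambda}{v},$$

with $v$ the droplet volume in microliters. Telomerase activity is defined
operationally as extended substrate molecules per microliter of PCR, scaled
to total products by the PCR volume (x20 for a 20 ul reaction) and
normalized per cell equivalent via the lysis-extension-PCR dilution chain
(canonically 50,000 cells / 40 ul = 1250 cells/ul; 1 ul into a 50 ul
extension = 25 cells/ul; 2 ul into the PCR = 50 cell equivalents).

`ddtrap` implements this chain end to end — thresholding, counting, Poisson
correction with confidence intervals, no-template-control (NTC-LB)
background subtraction at the concentration level, per-cell normalization —
together with a droplet-level simulator that stands in for the instrument,
and the downstream analyses the assay is validated with: replicate CV
tables, limiting-dilution linearity, single-cell positivity, 4PL IC50
fitting and paired time-course comparison.

## The synthetic-data generator

The simulator emulates, stage by stage, the stochastic path from cells to
read droplets:

1. **Per-cell products.** A cell population is a zero-inflated negative
   binomial: a cell is inactive with probability $1 - f$ (preset
   `hela_single_cell`: $f = 0.73$); active cells draw products from a
   gamma-mixed Poisson with mean $\mu$ (57.8 for the single-cell HeLa
   preset) and gamma shape $r$. The zero-inflated NB was chosen because it
   captures both the sizeable inactive class and biological overdispersion
   with two interpretable knobs.
2. **Lysis/extension thinning.** Which cells' material enters the extension
   is a binomial thinning at the volume ratio (1/40 canonically);
   single-step (one-step lysis-extension) wells carry everything in.
3. **Extension kinetics.** Yield saturates as $y(t) = 1 - e^{-kt}$, with
   $k$ solved once so that a 40-minute extension recovers 75% of the
   2-hour yield ($k \approx 0.0333\,\text{min}^{-1}$). Molecule counts are
   scaled by $y(t)/y(40)$, exactly 1 at the standard duration. The full
   time-course shape is emulated qualitatively; absolute time-course values
   are not a target.
4. **PCR aliquot and background.** The extension-to-PCR aliquot is another
   binomial thinning (2/50 canonically). Each PCR — sample or NTC — also
   receives an independent Poisson background, mean
   `background_mean_per_ul` x `pcr_volume_ul` (1.5 molecules/ul x 20 ul =
   30 molecules by default), representing trace contamination introduced
   during sample preparation.
5. **Emulsion capture and partitioning.** With 20,000 droplets of 0.85 nl,
   the emulsion holds 17 ul of the 20 ul PCR, so each molecule enters a
   droplet with probability $20{,}000 \times 0.85\,\text{nl} / 20\,\mu\text{l}
   = 0.85$ (a binomial thinning), and captured molecules are assigned
   multinomially to droplets. This capture step is what makes the
   concentration estimator unbiased in molecules per microliter *of the
   PCR*; forcing every molecule into the smaller emulsion volume would
   inflate every concentration by 20/17. Partitioning itself conserves
   molecules exactly.
6. **Amplitude rendering and the reader.** Occupied droplets draw endpoint
   fluorescence from a positive Gaussian band (or an intermediate "rain"
   band with configurable probability), empty droplets from a negative
   band, and a uniform random subset of 17,000 of the 20,000 droplets is
   retained, emulating incomplete droplet recovery by the reader. Band
   positions are arbitrary instrument-scale values; only separability
   matters.

Reproducibility: each plate takes one master seed; each well's randomness
comes from a child seed derived by a fixed counter scheme, so identical
seeds reproduce plates bit-for-bit.

### Preset parameter choices

* `hela_single_cell`: $f = 0.73$, $\mu = 57.8$ products per active cell —
  the single-cell positivity fraction and positive-cell mean of the assay's
  validation data.
* `hela_bulk`: $f = 0.73$, $\mu = 21.74$, so the population mean is
  $0.73 \times 21.74 = 15.87$ products per cell equivalent, which puts a
  100-cell-equivalent reaction at ~1,590 total products — the scale of the
  published replicate-dilution tables.
* **Dispersion** $r = 8$ (active-cell CV $1/\sqrt8 \approx 35\%$) for all
  presets. The reported standard error of the single-cell mean would, taken
  alone, imply an inter-cell SD comparable to the mean (gamma shape near
  1). But a shape-1 law places roughly a quarter of *active* cells below
  the plate's detection limit (the 3-SD positivity threshold over NTC wells
  corresponds to roughly 15-30 molecules), which is incompatible with the
  simultaneously reported 73% detection rate being the active fraction.
  The two observations cannot both hold under a gamma/NB active-cell law;
  the generator resolves the tension in favor of near-complete
  detectability of active cells ($r = 8$ leaves <1.5% of active cells
  below the limit), so that simulated cohorts recover both preset
  parameters. Users modeling wider activity distributions can lower
  `dispersion` per `cell_model()`.
* **Background** is Poisson per well with mean 1.5 molecules/ul of PCR (the
  published cross-experiment average); the cross-experiment SD is larger
  than Poisson, but within one simulated plate Poisson is the natural
  minimal model.
* **Droplet volume 0.85 nl** is the manufacturer's nominal droplet volume
  for this emulsion chemistry; it is a parameter everywhere because every
  copies/ul figure scales by it. 20,000 generated / 17,000 read droplets
  mirror the reported average read count; the generated count is otherwise
  free.

### What the simulator does not model

No per-cycle PCR efficiency, primer-dimer artifacts or droplet coalescence:
endpoint positivity is deterministic given occupancy, apart from the
optional rain band. Single-cell picking failures are not modeled — the
inactive fraction is treated as biological zeros. Consequently, passing
tests show that the *analysis chain* recovers what the generator encodes;
they cannot certify instrument-specific effects (rain structure, baseline
drift) that real exports may contain.

## Quantification choices

* **Threshold.** Default: pooled control-well mean + 7 SD. Under a Gaussian
  negative band this puts the per-droplet false-positive rate far below
  1/17,000. NTC wells do contain genuine template (the background), so the
  pooled SD is slightly inflated by their few positive droplets; with
  well-separated bands this moves the threshold harmlessly within the
  between-band gap. A `k_sigma` variant derives the statistic from the
  target well's lower mode by iterative 3-SD trimming, and `fixed` passes a
  value through. Ties at the threshold count as negative, stated explicitly
  because instrument exports are discrete-valued.
* **Confidence intervals.** The 95% CI is a Wilson score interval on
  $\hat p$, each bound mapped through $-\ln(1-\cdot)/v$ — chosen for good
  small-count behavior (it never collapses to a zero-width interval at
  $\hat p = 0$). A Clopper-Pearson exact mode is available behind
  `ci_method`. Coverage at $\lambda = 0.1$ is verified at 93-97% in the
  test suite.
* **Saturation.** When every droplet is positive the estimator is
  undefined; the package raises an error instructing dilution rather than
  reporting a floor-of-infinity value.
* **Background subtraction order.** NTC subtraction happens at the
  molecules/ul level, *before* the x20 volume scaling (the two orders are
  equivalent up to the shared constant; the concentration-level order is
  normative here). Negative corrected concentrations are floored at zero
  with the floor flagged and the unfloored value kept in a diagnostic
  column.
* **Positivity.** A sample is "detectably above background" when its raw
  concentration exceeds mean + 3 SD of the plate's NTC wells. With fewer
  than two NTC wells the SD is undefined and the call falls back to
  comparing the sample's CI lower bound to the NTC mean, with a notice.
  The rule and its parameters are recorded in every output because the
  positive fraction of a marginal cohort depends on them. NTC replication
  matters more generally: with only 2-3 NTC wells the background mean
  carries an appreciable standard error that propagates into every
  corrected value (~±4 molecules of total products at the default
  background), and the 3-SD threshold itself becomes volatile; plates
  aimed at single-cell work benefit from 6-8 NTC wells, and the package's
  own validation runs use 8.

## Downstream analyses

* **CV tables** use the sample SD (n−1); CV% is reported to 2 decimals.
* **Dilution linearity** is an OLS fit of total products on cell
  equivalents; $R^2$ is the squared Pearson correlation of fitted vs
  observed — the convention of ordinary spreadsheet/statistics output.
* **IC50.** Four-parameter logistic
  $y = b + (t - b)/(1 + (d/\mathrm{IC}_{50})^h)$ fit by Levenberg-Marquardt
  least squares with IC50 on the log scale; the zero-dose group anchors the
  top plateau because the curve equals $t$ exactly at $d = 0$. A fit is
  flagged non-convergent when the optimizer fails or the dose-group means
  span less than 20% of the top plateau (no real inhibition); the fallback
  is log-linear interpolation of group means to the half-plateau level.
* **Time courses** use two-sided paired Student's t-tests per timepoint
  against baseline, paired by replicate index, with no multiplicity
  adjustment by default (a Bonferroni flag exists). Degenerate pairs with
  zero difference variance return $t = 0, p = 1$ (identical values) rather
  than NaN.

## Problem sizes and numerical notes

The package's validation experiments run at the assay's native geometry —
17,000 read droplets of 0.85 nl per well — with three replicate dilution
series (100–6.25 cell equivalents), cohorts of 78–300 single-cell wells,
100 NTC wells for background recovery, and the six-dose, nine-replicate
inhibitor design at ~9% CV; these sizes reproduce the published designs
while keeping any single check to seconds. Estimator behavior at the edges
(zero positives, saturation, ties) is pinned by exact tests;
$\hat\lambda$ agrees with a brute-force likelihood grid search to the grid
resolution, and for $\hat p < 0.01$ it deviates from $\hat p$ by less than
0.51% (second-order Taylor bound), so rare-template wells are effectively
in the linear regime.

## A worked example

```{r example, eval = FALSE}
library(ddtrap)

# simulate a three-series limiting dilution of a telomerase-positive line
samples <- unlist(lapply(1:3, function(s)
  lapply(c(100, 50, 25, 12.5, 6.25), function(ce)
    list(model = cell_preset("hela_bulk"),
         protocol = protocol_spec(cells_lysed = ce * 1000),
         n_replicates = 1L, sample_id = sprintf("dil%g_s%d", ce, s)))),
  recursive = FALSE)
plate <- simulate_plate(samples, seed = 1)

tab <- process_plate(plate)
cv_table(tab)
samp <- tab[tab$role == "sample", ]
fit_dilution_series(samp$cell_equivalents, samp$total_products)
```

## Known limitations

* Absolute agreement with vendor droplet-reader software is not claimable:
  the droplet volume and the vendor's exact CI construction are not public,
  and both scale or shape the reported concentrations.
* The amplitude model is a deliberately simple two-band Gaussian (plus
  optional rain); it supports threshold logic but not studies of baseline
  drift or rain morphology.
* Only single-channel (intercalating-dye) data are supported; there is no
  duplex/multi-channel mode.
* Inter-plate normalization beyond per-plate NTC subtraction is out of
  scope.
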