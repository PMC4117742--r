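# ddtrap

Quantification pipeline and assay simulator for **droplet digital TRAP
(ddTRAP)** — the digital-PCR adaptation of the telomere repeat
amplification protocol that counts telomerase extension products as
absolute molecule numbers instead of gel band intensities.

It is written for labs running (or planning) droplet-based telomerase
activity assays, and for methods work that needs a fully in-silico version
of the workflow: every stage from cell lysate to read droplets can be
simulated, so thresholding, Poisson correction, background subtraction and
the downstream statistics are testable without an instrument.

## The model at the core

A 20 ul PCR is partitioned into ~20,000 droplets of ~0.85 nl and read
after endpoint amplification (~17,000 droplets recovered). Since a droplet
can contain more than one template, the positive fraction
*p̂ = n₊/n* is Poisson-corrected to the mean copies per droplet

    λ̂ = −ln(1 − p̂),      copies/ul = λ̂ / v,

with *v* the droplet volume in ul (0.85 × 10⁻³ by default). A Wilson score
95% interval on *p̂* is mapped through the same transform. Telomerase
activity is then

    total products  = (copies/ul − NTC background) × PCR volume (20 ul)
    per-cell activity = total products / cell equivalents,

where the cell equivalents follow the dilution chain
`cells lysed / lysis volume × lysate into extension / extension volume ×
extension into PCR` (canonically 50,000/40 ul = 1250 cells/ul → 25
cells/ul → 50 cell equivalents), and the background is the mean of the
plate's no-template lysis-buffer controls (NTC-LB), subtracted at the
concentration level.

On top of this sit the assay's standard analyses: replicate CV tables,
limiting-dilution linearity (OLS R²), single-cell positivity calling
(mean + 3 SD of the NTCs), four-parameter logistic dose–response IC50
fitting, and paired time-course tests. A seeded generator simulates whole
plates — zero-inflated negative-binomial per-cell product counts,
saturating extension kinetics, binomial aliquot thinning, Poisson
background contamination, multinomial droplet partitioning and two-band
fluorescence amplitudes.

## Worked example

Simulate three replicate dilution series of a telomerase-positive cell
line (100 → 6.25 cell equivalents per PCR), process the plate, and check
reproducibility and linearity:

```r
library(ddtrap)

samples <- unlist(lapply(1:3, function(s)
  lapply(c(100, 50, 25, 12.5, 6.25), function(ce)
    list(model = cell_preset("hela_bulk"),
         protocol = protocol_spec(cells_lysed = ce * 1000),
         n_replicates = 1L, sample_id = sprintf("dil%g_s%d", ce, s)))),
  recursive = FALSE)

plate <- simulate_plate(samples, seed = 1)
#> Simulated plate: 19 wells (15 sample, 3 NTC-LB, 1 no-primer), seed 1

tab <- process_plate(plate)
cv_table(tab)
#>   group_label n_replicates mean_total_products sd_total_products cv_percent
#> 1         100            3           1526.3495          14.88764       0.98
#> 2          50            3            751.5720          64.07714       8.53
#> 3          25            3            411.0566          33.59536       8.17
#> 4        12.5            3            192.0483          18.80203       9.79
#> 5        6.25            3            128.7960          29.88894      23.21

samp <- tab[tab$role == "sample", ]
fit_dilution_series(samp$cell_equivalents, samp$total_products)
#> Dilution linearity: slope 14.98 molecules/cell eq, intercept 21.5, R^2 = 0.9957 (n = 15)
```

Each CV row is the replicate mean/SD of total telomerase products at one
cell-equivalent input (CV% = SD/mean × 100); the fit's slope is the
per-cell-equivalent activity (~15.9 molecules/cell for this preset) and
R² ≥ 0.98 is the linearity benchmark for the assay. A single well's
quantification looks like:

```r
estimate_concentration(list(n_total = 17000, n_positive = 1000))
#> 71.32 copies/ul (95% CI 67.03-75.88), lambda = 0.06062, 1000/17000 droplets positive
```

i.e. 1,000 positive of 17,000 droplets is 71.3 molecules/ul after Poisson
correction — 1,426 total products in a 20 ul PCR.

A command-line wrapper over the same functions is installed at
`system.file("scripts", "ddtrap", package = "ddtrap")` with
`simulate | quantify | pipeline | analyze | run` subcommands.

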