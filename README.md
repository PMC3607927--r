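# endoquant

Quantification of receptor-mediated ligand internalization from two-channel
fluorescence microscopy and flow cytometry.

## The problem

Insulin and IGF-II both signal through the insulin receptor isoform B
(IR-B), but they are taken into the cell at different speeds, and that
difference matters for how a metabolic hormone and a mitogenic growth
factor produce distinct outcomes from one receptor. The measurement
strategy this package implements tracks a quantum-dot (QD)-labeled ligand
bound to a fluorescent-protein-tagged receptor (IR-B–SYFP) in individual
HeLa cells and asks, at each incubation time at 37 °C: *what fraction of
the ligand signal is already inside the cell?*

`endoquant` is aimed at cell biologists and image-analysis people who want
that pipeline as tested, scriptable R functions rather than a chain of
ImageJ/Origin/WinMDI steps: membrane/interior partitioning of segmented
cells, per-cell internalization ratios, logistic kinetics with rate
constants, Manders/PDM colocalization, and threshold-based cytometry
statistics — plus a ground-truthed synthetic-data generator so every stage
is testable without any raw data.

## The measurement model

**Microscopy.** Each field has a receptor channel (SYFP; used for
segmentation and expression estimation) and a QD-ligand channel. After
scalar background subtraction (image median), cells are segmented on the
receptor channel (Otsu, hole filling, area and border filters). For each
cell mask the *pre-interior* is a binary erosion with **alternating
connectivity** (4-connected cross on odd iterations, 8-connected square on
even ones, default 8 iterations), and the *pre-membrane* is the cell minus
the pre-interior. A QD mask (pixels above 3 robust sigma) intersects both,
giving *membrane* and *interior* compartments, and per cell:

```
ratio = QD_interior / (QD_interior + QD_membrane)
```

The ratio is invariant to joint rescaling of both sums — an internal
calibration that cancels detector gain. Only cells with similar receptor
expression (mean SYFP within a 2-fold window of the experiment median) are
kept for statistics; conditions are compared with two-tailed t-tests
(raw-data or summary-based).

**Kinetics.** Per-ligand mean ratios versus time are fitted with a
logistic, default form `y(t) = a / (1 + exp(-k (t - t0)))`, whose first
derivative is maximized to give the maximal internalization rate `k_max`
(min⁻¹) and the half-time `t½ = ln 2 / k_max`. The four-parameter power
logistic `y = a2 + (a1 - a2)/(1 + (t/x0)^p)` is also available and is the
form used by the synthetic-data generator.

**Cytometry.** Events are gated SYFP-positive against a non-transfected
control (0.995 quantile), per-time QD histograms of gated events give
geometric means normalized to t = 0, a marker M1 is placed so that ≈4 % of
time-zero events exceed it and the normalized "Marker/0 min" series tracks
internalized label, and quadrant statistics give labeled fractions
II/(II+IV) and fold-versus-control values.

## Worked example

Fit the bundled reference time courses (per-timepoint mean internalization
ratios for IGF-II and insulin through IR-B) and extract the kinetic
constants:

```r
library(endoquant)
fits <- fit_ligand_kinetics(reference_timecourse(), model = "exp")
kinetics_table(fits)
#> # A tibble: 2 × 9
#>   ligand      a      k    t0  k_max t_at_kmax t_half r_squared converged
#>   <chr>   <dbl>  <dbl> <dbl>  <dbl>     <dbl>  <dbl>     <dbl> <lgl>
#> 1 insulin 0.947 0.0816 21.0  0.0193     21.0    35.9     0.950 TRUE
#> 2 IGF-II  0.931 0.144   8.15 0.0336      8.15   20.6     0.960 TRUE
```

IGF-II reaches its maximal rate (`k_max` ≈ 0.034 min⁻¹, half-time ≈ 21
min) roughly 1.7× faster than insulin — the quantitative core of the
faster-IGF-II claim. `autoplot(fits[["IGF-II"]])` draws the fitted curve.

A fully synthetic end-to-end run (simulate → segment → partition → measure
→ filter → summarize → test → fit):

```r
run <- run_imaging_pipeline(imaging_config(
  simulation = image_dataset_config(fields_per_time = 2, cells_per_field = 3, seed = 7),
  fit_model = "exp"
))
run
#> <imaging_run> 16 fields, 48 cells (0 excluded at measurement, 0 by expression filter, 48 retained)
#> # A tibble: 2 × 9
#>   ligand      a     k    t0  k_max t_at_kmax t_half r_squared converged
#> 1 IGF-II  0.890 0.186  7.83 0.0414      7.83   16.7     0.966 TRUE
#> 2 insulin 0.880 0.140 17.0  0.0309     17.0    22.4     0.999 TRUE
```

The simulated IGF-II-like ligand again fits faster than the insulin-like
one, and `run$comparisons` holds the per-timepoint two-tailed t-tests
(e.g. p ≈ 6 × 10⁻⁶ at 10 min for this seed). The cytometry arm is
`run_cytometry_pipeline(cytometry_config())`; a thin CLI over both lives
in `inst/cli/endoquant-cli.R`.

## Scope notes

Deconvolution, 3-D rendering, spectral unmixing and hardware-specific FCS
compensation are out of scope; the analysis quantifies fixed 2-D snapshots
and threshold-based event statistics. See the methods vignette
(`vignettes/quantifying-internalization.Rmd`) for model assumptions,
parameter defaults and known limitations.
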