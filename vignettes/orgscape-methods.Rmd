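---
title: "Methods: from lambda-scan images to the organelle landscape"
author: "orgscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from lambda-scan images to the organelle landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgscape)
```

## The measurement model

orgscape analyzes *organelle particles*: membranous fragments released by
gentle sonication of cells, which retain the marker composition of their
source organelle. Particles are labeled with up to 8 spectrally distinct
fluorophores (one per organelle marker) and imaged by a lambda scan: one
image plane per narrow emission window, 52 windows of 10 nm bandwidth on
4 spectrometer blocks, each block excited by its own laser line (405, 488,
561 and 640 nm, acquired sequentially and appended into a single series).

A pixel's measured spectrum is modeled as a non-negative linear combination
of the fluorophores' reference emission spectra plus background:

$$y_w = b + \sum_k a_k \, s_{kw} + \varepsilon_w ,$$

where $s_{k\cdot}$ is fluorophore $k$'s unit-sum reference spectrum and
$a_k$ its abundance. The stated block geometry ("13 steps from 411 to
481 nm", and so on) is not arithmetically consistent with a uniform 5-nm
step, so the window centers are generated by spacing the printed step count
evenly between each block's printed first and last center; the endpoints
and counts are treated as authoritative.

## Stage by stage

**Reference spectra** (`estimate_reference_spectra`). Each fluorophore's
spectrum is estimated from a single-color stack: the mean spectrum of the
brightest 1% of pixels (by total counts), minus the per-window median of
the dimmest 50%, clamped at zero and normalized to unit sum. The 1%/50%
fractions are exposed as arguments; they are a robust parameter-light
substitute for instrument-software internals that are not documented
anywhere.

**Linear unmixing** (`unmix`). Per pixel, ordinary least squares against
the reference matrix through one shared QR decomposition; an optional
non-negativity constraint switches to per-pixel active-set NNLS. The
per-pixel residual norm is returned for quality control. All 52 windows
enter one design matrix; no per-laser weighting is applied. Background is
*not* subtracted before unmixing — whether the original acquisition
software does so is unknown, so the package keeps the unmixing step pure
and leaves background handling to the spectrum-estimation rule above.

**Thresholding** (`fit_pixel_gmm`, `compute_threshold`). Pixel intensities
of each unmixed channel are modeled as a 1-D Gaussian mixture with
unequal variances, fitted by EM (mclust, model "V") for each candidate
component count (1–6 by default) and selected by BIC. BIC is reported in
the standard minimized convention $k\ln n - 2\ln\hat L$; mclust's
sign-flipped convention selects the same model. *Crossing points* are the
intensities at which the maximum-responsibility component switches as
intensity increases; they are found analytically as roots of the pairwise
weighted log-density equalities (quadratics), confirmed by evaluating the
winning component on the delimited intervals, with ties broken toward the
higher intensity. The particle/background threshold is the **highest**
crossing point. Numerical choices:

* fits run on a seeded subsample of at most $2\times10^5$ pixels
  (assignment then applies to all pixels);
* if BIC selects one component the channel has no foreground structure:
  its threshold is $+\infty$, it contributes nothing to the mask, and a
  warning is emitted;
* exactly constant channels are refused;
* an optional weak conjugate prior (`regularize = TRUE`,
  mclust's `priorControl()`) stabilizes fits on noiseless synthetic data,
  where the background component would otherwise collapse to zero
  variance and silently drop every multi-component candidate.

**Particle extraction** (`binarize_and_merge`, `extract_particles`). Each
non-excluded channel is binarized at its threshold; the binaries are
merged by union; connected components are labeled. Channels can be
excluded from mask creation (a marker with diffuse signal would bloat the
mask) yet always appear as intensity columns. Components use
8-connectivity by default (4 available). The labeling is implemented
in-package by vectorized minimum-label propagation, because the installed
image packages only provide 4-connected labeling. Border-touching
particles are retained. A `min_area` option rejects sub-resolution
single-pixel specks; the default keeps everything. Per particle, each
channel's **pre-binary** (continuous) intensities are summed over the
particle's pixels, with area = pixel count; small negative unmixing
excursions are clamped at zero.

**Landscape** (`size_factor_normalize`, `embed_landscape`,
`cluster_landscape`). Marker sums are normalized by size factors
($f_i = \text{total}_i / \text{geometric mean of totals}$, so the factors
have geometric mean 1), divided out and log1p-transformed — positive,
heavy-tailed intensities call for a log-family transform. PCA keeps all
components for the 4–8 marker panels. Batch structure across independent
experiments is removed by centering each replicate's PC coordinates on a
common origin — the transparent, testable core of what package batch
aligners do; a caveat is that centering assumes similar class composition
across replicates. UMAP (n_neighbors = 15, min_dist = 0.1, Euclidean,
fixed seed) embeds the aligned PCs in 2-D. Clustering is Leiden modularity
optimization on the k-nearest-neighbor graph of the embedding (k = 60 for
the 8-marker landscape; k = 20 for the contact-site and endosome
analyses). The resolution parameter (0.01) was calibrated once so that the
seven-class simulation below is recovered exactly *and* a single Gaussian
blob stays one cluster, then frozen. `merge_clusters` reproduces the
manual regrouping step (clusters dominated by one marker merged into one).

**Query projection** (`map_query`). A query table is normalized with its
*own* size factors, pushed through the reference PCA and the same
per-batch centering, then embedded with the reference-trained UMAP
transform. Cluster labels transfer by majority vote among the 10 nearest
reference particles in embedding space (ties fall to the single nearest
neighbor). Novelty is flagged through the nearest-reference distance in
aligned PC space — the UMAP transform by construction lands any point
among reference points, so embedding distances carry no novelty signal.

**Cargo time course** (`background_threshold`, `filter_cargo_particles`,
`cluster_proportions`, `sqrt_percent_max`). The positivity threshold for a
fluorescent cargo (EGF, transferrin) is the 99th percentile of its signal
on control particles from cells never exposed to the cargo (type-7 linear
interpolation; the estimator convention is fixed here because the source
procedure does not specify one). Particles with a zero value in any
required endosomal marker (RAB5, RAB7, RAB11 by default) are removed, and
the survivors must be at or above at least one cargo threshold. Positivity
is evaluated on mean pixel intensity (sum/area) by default with a
sum-based mode available — the source procedure describes both
conventions in different places, so both are implemented and the mode is
recorded in the output. Per (condition, timepoint, cargo), cluster counts
are normalized to proportions; zero-positive groups report count 0 with
proportion NA. Display scaling is $\sqrt{100\,v/\max v}$ (max maps to 10).

## What the simulator emulates — and what it does not

`sim_config` / `sample_particles` draw particle classes from a mixture
over organelle classes, per-marker abundances from class-specific
log-normal profiles (positive, heavy-tailed, closed-form moments — a
deliberate match to the heavy-tailed intensity violins seen in real
particle data), and non-overlapping hard-disk geometry.
Defaults represent the study conditions: 7 organelle classes over an
8-marker panel (ER, mitochondria with two OMP25 fusions, Golgi, early
endosomes, plasma membrane, peroxisomes, lysosomes), equal class weights,
log-abundance separation of well over 4 log-sd between a class's own
marker and off-target markers, 3 simulated replicates with configurable
per-batch gain. Contact-site particles carry the summed profiles of a
designated class pair with an asymmetry factor (default 0.2: the attached
ER fragment is much smaller than its mitochondrion). The endosome preset
programs seven maturation states over RAB5/RAB11/RAB7/LAMP1, including a
RAB5+RAB7 conversion state. `render_spectral_stack` renders disks of
uniform interior intensity (abundance spread evenly over the disk's
pixels, so summed counts recover the abundance analytically), adds
constant background, and optionally Poisson shot noise plus Gaussian read
noise. `sample_cargo_timecourse` moves a degradative cargo along
early → conversion → late → lysosome and a recycling cargo along
early → recycling over a 0–40 min chase.

Deliberately *not* modeled: optical point-spread, 3-D structure, chromatic
aberration, autofluorescence, spatially varying background, antibody
labeling efficiency, and touching/overlapping particles (the generator
enforces separation). Passing tests on these simulations therefore
demonstrate the correctness of the computational pipeline under its own
assumptions — linear mixing, disk-shaped particles, log-normal
abundances — not robustness to every property of real microscopy data.

## Problem sizes and determinism

The validation suite runs the full pipeline at n = 7,000 particles
(8 markers, k = 60) and n = 17,000 (4 markers, k = 20) — sizes chosen to
mirror the scale of one combined experiment while keeping a full run in
minutes on one core. Every stochastic stage (sampling, noise, subsampling,
UMAP, Leiden) is driven by explicit seeds; identical configurations
reproduce identical tables byte-for-byte.

## Known limitations

* Background is not subtracted before unmixing or summation; with a
  non-negligible flat background the extracted sums contain a background
  projection term proportional to particle area.
* Per-batch mean-centering is a first-order aligner; replicates with very
  different class compositions would be over-corrected (a
  mutual-nearest-neighbors corrector would be the next step).
* The Leiden resolution is calibrated for well-separated classes;
  continuously varying populations (maturation gradients) are partitioned,
  not modeled as trajectories.
* Label transfer assumes the reference covers the query's populations;
  novel populations are flagged by PC-space distance but still receive a
  (meaningless) nearest-cluster label.
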