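---
title: "From on-the-go vineyard spectra to grape-composition maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From on-the-go vineyard spectra to grape-composition maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinespec)
```

## The problem

Grape ripeness is tracked by total soluble solids (TSS, °Brix), and — in red
varieties — by anthocyanin (mg/berry) and total polyphenol (AU/berry)
accumulation. Wet-chemistry reference assays are destructive and slow, so a
handful of berry samples must stand in for millions of berries per hectare.
Proximal VIS/SW-NIR spectroscopy mounted on a vehicle offers a way out: a
spectrometer pointed at the defoliated fruiting zone records hundreds of
reflectance spectra per row at driving speed, and latent-variable regression
links those spectra to block-level berry chemistry. The catch is that the
raw stream mixes grape clusters with leaves, wood, metal posts and canopy
gaps, and field spectra carry strong multiplicative and additive scatter.
This package implements the complete processing chain that turns such
streams into per-block analyte predictions and vineyard maps, together with
a synthetic data generator that makes every stage testable without field
data.

## Pipeline model and assumptions

**Allocation.** Spectra are georeferenced in planar metres (geographic
coordinates are converted on ingest by a local equirectangular
approximation, accurate well below the GPS error at vineyard scale). Each
spectrum goes to the nearest block centroid within `maxDistance`; ties go to
the lexicographically lower block id, and everything farther is discarded.
Per-block counts plus discards always sum to the stream length.
`allocateToBlocks()` defaults to half the 2.20 m row spacing (1.10 m), the
natural gate when several rows are driven in one stream. The default
pipeline configuration instead uses half the block length (2.5 m for 5 vines
at 1.0 m): a block's own pass then maps entirely to that block, which is the
behaviour a per-block trigger would give, and keeps all ~64 spectra of a
pass available to the filter.

**Signature filtering.** Cluster spectra are retained by plain cosine
similarity between raw absorbance spectra and a manually acquired cluster
signature, with threshold 0.993. We deliberately compute the similarity on
*raw* spectra — pre-processing happens after averaging, matching the field
protocol's step order. Whether the original vendor tool centers spectra
before its cosine is undocumented; plain cosine is the default and a
centered variant is available via `centered = TRUE`. Blocks retaining fewer
than `minCount = 5` spectra are excluded with a warning: a 5-spectrum mean
is the least we consider a usable block average.

**Pre-processing.** Treatment codes follow the compact chemometric
convention: `D1W15` is a Savitzky–Golay first derivative with a 15-channel
window, `SNV + DT D1W15` prepends standard normal variate and polynomial
detrend. Two parameters are not encoded in the codes and had to be fixed:
the Savitzky–Golay polynomial order (default 2, the standard choice for a
first-derivative window of 15) and the detrend degree (default 2, the
classic SNV–detrend pairing); both are arguments. Derivatives are scaled by
the 1.963 nm channel step, so units are absorbance/nm; this scaling cancels
after centering and does not affect model statistics. Edge channels are
computed by evaluating the nearest full window's fitted polynomial at the
edge offsets, preserving the 215-channel length the models expect.

**Outlier screening.** A PCA retaining the smallest number of components
explaining ≥ 95% variance yields Q residuals (squared distance off the
model subspace) and Hotelling T² (Mahalanobis distance within it). Limits at
α = 0.99 use the F-distribution form for T² and the Jackson–Mudholkar
approximation for Q. A sample is flagged only when *both* statistics exceed
their limits — a conservative joint rule, applied in a single pass. Note a
structural property of this rule: an anomaly so large that it dominates the
covariance is absorbed into the retained subspace (its Q collapses), so the
rule targets moderate two-space anomalies, not gross amplitude errors, which
should be caught earlier by the filter. At the 99% level, an occasional
single false alarm among 144 samples is expected and harmless.

**Calibration.** The split is stratified over the response: samples are
ranked by the analyte, the ranking is cut into as many nearly equal
consecutive bins as there are validation samples, and each bin contributes
one random validation sample, so both sets cover the full range. The
calibration size is `ceiling(0.8 n)` — 116 of 144, leaving 28. PLS uses
sequential NIPALS extraction with X-deflation for a univariate response,
chosen over kernel variants because every intermediate quantity can be
checked against closed-form oracles (at full rank it must reproduce the
minimum-norm least-squares fit). X is mean-centered only; channels share
units, so autoscaling is off. Cross-validation uses 10 venetian blinds
(sample i → fold i mod 10, 0-based) on the dataset in block-major,
date-minor order; the fold pattern therefore depends on sample order, as
order-based CV always does. The latent-variable count minimises RMSECV,
ties to the smaller count. R² is reported as explained variance,
1 − SSE/SST, about each set's own mean (the squared-correlation alternative
can be computed from the returned predictions if wanted).

**Mapping.** Block predictions are interpolated by multilevel B-spline
approximation: uniform cubic B-spline control lattices fitted
coarse-to-fine, each level to the residuals of the accumulated surface, with
lattice resolution doubling per level (default 8 levels from a 4 × 4
control lattice). One practical deviation from the textbook cascade: the
data mean is subtracted before fitting and added back at evaluation, which
makes constant fields exact everywhere instead of only at the data points.
Rasters default to 1 m cells over the layout padded by one row spacing;
cells farther than twice the row spacing from any centroid are no-data, so
maps never extrapolate beyond the plot. A map series shares its grid and
colour-scale bounds across dates so ripening dynamics are comparable.

## What the generator emulates — and what it does not

The synthetic vineyard reproduces the statistical structure the analysis
relies on:

* **Layout**: 3 rows × 12 blocks × 5 vines, 2.20 m × 1.0 m spacing, i.e.
  36 blocks and 144 block × date samples over 4 dates.
* **Chemistry**: per-analyte Gaussian random fields over block centroids
  with squared-exponential covariance (correlation length 15 m — structure
  at the scale of a few blocks, matching the patchiness maps show), sampled
  once and shared across dates so maps evolve coherently; monotone
  non-decreasing per-date means from veraison to harvest; values clipped to
  the observed ranges (TSS 10.7–25.2 °Brix, anthocyanins 0.09–4.64
  mg/berry, polyphenols 0.14–4.70 AU/berry). Anthocyanin and polyphenol
  fields share a latent component (correlation 0.8), reflecting their
  near-duplicate spatial patterns in ripe fruit.
* **Streams**: floor(block length / speed × rate) = 64 spectra per 5 m
  block pass at 5 km/h and 18 Hz, classes drawn i.i.d. from
  {cluster 0.35, leaf 0.40, wood 0.10, gap 0.15} — the cluster fraction in a
  defoliated fruiting zone is not published, and 0.35 is our one-time
  choice. Cluster spectra are an idealised absorbance endmember plus
  per-analyte Gaussian absorption bands scaled by the 0–1-scaled
  concentration and a per-analyte spectral SNR (0.20 / 0.055 / 0.018
  absorbance for TSS / anthocyanins / polyphenols). The decreasing SNR
  order encodes the decreasing spectral accessibility of the three analytes
  and is what makes recovered model quality rank the same way.
* **Noise**: per-spectrum multiplicative slope (sd 0.01) and additive
  offset (sd 0.005), per-channel noise (sd 0.01), and — crucially — a
  *per-pass* drift: slope sd 0.03, offset sd 0.012 and a smooth random
  spectral perturbation (four broad Gaussian bumps, amplitude sd 0.012)
  shared by all spectra of one pass. Per-spectrum noise averages out over
  the ~20 retained cluster spectra of a block; the per-pass component does
  not, and is the realistic nuisance (ambient light, canopy geometry,
  sensor drift between passes) that separates the three analytes' model
  quality.
* **The instrument axis** is 215 evenly spaced channels over 570–990 nm.
  The nominal 2 nm resolution would give 211 points; the published channel
  count is treated as authoritative so model matrices have the documented
  dimensionality.

The generator does **not** attempt radiative-transfer or berry-optics
realism: no canopy 3-D geometry, no weather, no within-block composition
gradients, no correlated (non-i.i.d.) class runs along the row, and analyte
bands are clean Gaussians rather than overlapping overtone structures.
Consequently, passing tests demonstrate that the *pipeline* is correct and
that parameter recovery behaves as designed under plausible field-like
noise — they do not certify the prediction accuracy achievable on real
vineyard spectra, which is limited by reference-assay error and
berry-sampling mismatch that the generator intentionally leaves out (its
reference chemistry is exactly the chemistry imprinted on the spectra).

## Numerical choices and degenerate inputs

* Cosine similarity errors on zero-norm inputs; filtering preserves stream
  order; an empty retained set is valid (boundary), but averaging below
  `minCount` errors with the block named.
* The spatial field sampler uses an eigendecomposition with negative
  eigenvalues clamped to zero, so degenerate kernels (infinite correlation
  length → rank-1) sample correctly.
* `splitIndices` distributes rank-bin sizes as evenly as possible
  (difference ≤ 1); with n = 2 and fraction 0.5 the single bin of two
  contributes one validation sample.
* The Q limit is `Inf` when no residual variance exists beyond the retained
  components (exact low-rank data); trailing eigenvalues below machine
  precision are dropped from the Jackson–Mudholkar sums.
* `mbaFit` pads a degenerate automatic bounding box (single point or
  collinear data) by ±0.5 m per degenerate axis, but rejects an explicitly
  supplied zero-area box. Evaluation outside the box is an error, not an
  extrapolation.
* All simulation is seed-driven; identical seed and configuration give
  bit-identical streams, chemistry and artifacts (the run manifest hashes
  are compared in the tests).

## Problem sizes in the test suite

The suite runs the full default campaign (36 blocks × 4 dates, 9216 spectra
of 215 channels) wherever a criterion concerns the end-to-end pipeline, ten
such campaigns for the parameter-recovery check, a 2000 × 10 Monte-Carlo
sample for control-limit calibration, and small (≤ 60 × 15) fixtures for
the algebraic oracles, keeping the whole suite within a few minutes on one
CPU while still exercising the published data dimensions.

## Known limitations

* PLS is univariate-response (three separate models), by design; no PLS2,
  variable selection, or nonlinear regressors.
* The venetian-blinds CV depends on dataset order; reordering samples
  changes folds (inherent to the method, documented above).
* The cosine filter is single-signature; streams with multiple target
  classes would need a classifier, which is out of scope.
* Maps are interpolations of block predictions; masking limits but does not
  eliminate smoothing artifacts between rows.
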