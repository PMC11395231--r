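---
title: "Methods: enumeration and phenotyping of circulating hybrid cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enumeration and phenotyping of circulating hybrid cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridscope)
```

## The problem

Circulating neoplastic-immune hybrid cells (CHCs) are peripheral-blood cells
that co-express a tumor marker (pan-cytokeratin, CK) and the pan-leukocyte
marker CD45. Unlike conventional circulating tumor cells (CTCs, CK+/CD45-),
CHCs are detectable at counts of several per 50,000 peripheral blood
mononuclear cells (PBMCs) in patients with advanced epithelial cancers, which
makes them usable as a longitudinal liquid-biopsy biomarker: counts fall to
zero when treatment works, and climb again when disease resists or recurs.

`hybridscope` implements the full analysis chain for this kind of assay:

1. **Simulation** of immunofluorescence fields, single-cell crops, and
   longitudinal cohorts with known ground truth (`generate_field()`,
   `generate_crop_set()`, `generate_cohort()`);
2. **Segmentation** of nuclei from DAPI and expansion to whole cells along
   the CK/CD45 projection (`segment_field()`);
3. **Gating** against unstained control cells and enumeration per 50,000
   PBMCs (`gate_sample()`);
4. **Longitudinal classification** of treatment courses and
   responsive/resistant phase labels (`classify_course()`,
   `label_chc_phases()`), with an exact Mann-Whitney U test for the small
   baseline comparison (`mann_whitney()`);
5. **Representation learning**: a beta-variational autoencoder over
   64 x 64 x 3 cell crops with per-batch KL annealing (`vae_fit()`), latent
   embeddings (`encode()`), UMAP projection (`embed_umap()`), and a
   phenotype-separation report (`phenotype_report()`).

Because raw patient data for assays like this are typically not deposited,
every stage is developed and validated against the synthetic generator, which
is a first-class, tested component rather than a fixture.

## What the generator emulates (and what it does not)

The generator reproduces the *statistical* structure the analysis depends on:

- **Fields**: three channels ordered (CK, CD45, DAPI); leukocytes (CD45+),
  CHCs (CK+/CD45+), CTCs (CK+), and unstained control cells confined to a
  control strip on the same field, mirroring the on-slide unstained-control
  region used for thresholding. Cells are isotropic Gaussian disks - a
  nucleus on DAPI and a cytoplasm of 1.6x the nuclear radius on the marker
  channels - with additive Gaussian camera noise clipped at zero. Disks are
  truncated at 2.5 sigma (with the edge value subtracted) so that marker
  signal has compact support and cannot bleed into a neighbor's mask;
  placement is by rejection sampling with 100 retries and a minimum
  center-to-center distance, so planted counts are exact.
- **Crops**: two phenotypes - treatment-responsive (CD45-high/CK-low) and
  treatment-resistant (CK-high/CD45-low), the resistant class optionally
  rendered with a punctate CK pattern of 3-6 discrete puncta whose integrated
  intensity matches the diffuse disk they replace.
- **Cohorts**: patient baselines uniform on 7.6-15.5 CHCs per 50,000 PBMCs,
  decline to exactly zero within two post-treatment samples, rebound
  magnitudes uniform on 2.0-49.6 for resistant/progressing regimes, healthy
  subjects at 0 with probability 0.8 and otherwise a single detected cell
  over a 30,000-150,000-PBMC scan (normalized values in (0.33, 1.67]).
  Counts are always integer raw cells; normalized values are derived, so the
  enumeration invariant `normalized = raw * 50000 / total_pbmcs` holds
  exactly and "undetectable" is exactly zero.

It deliberately does **not** model point-spread functions, vignetting,
autofluorescence spectra, cell doublets, focus drift, or staining batch
effects. Tests passing on synthetic data therefore demonstrate that the
*logic* of segmentation, gating, enumeration, and course classification is
correct under separable staining; they do not certify performance on real
microscopy, where segmentation quality and spectral bleed-through dominate.
The segmentation stage is pluggable (`segment_field(segmenter = ...)`)
precisely so a learned segmenter can replace the classical one on real data.

## Segmentation

Nuclei: Gaussian smoothing (sigma 1.5 px), Otsu threshold, hole filling,
distance transform, watershed (EBImage), discarding components under 20 px as
debris. Cells: each nucleus is expanded along a lightly smoothed CK/CD45
maximum projection by seeded propagation, confined to pixels above the
membrane background and within 8 px of a nucleus. Two numerical choices
matter:

- the expansion threshold is a robust noise floor, `median + 5 * mad` of the
  smoothed projection (background pixels dominate a PBMC field, so the median
  and MAD are noise statistics). Thresholding the *smoothed* projection is
  essential: raw-pixel thresholding preferentially annexes single bright
  noise pixels, which are biased high on the marker channels and corrupt the
  per-cell means that gating uses;
- cells touching the field border are kept but flagged, since crops are
  zero-padded anyway.

Coordinates are 0-based (row, col) and bounding boxes half-open, so slicing
is unambiguous across languages.

## Gating and enumeration

Thresholds are a high percentile (default 99.5) of the per-cell mean
intensities of the unstained control cells, computed with linear
interpolation of the empirical CDF (the p-th percentile of n ordered values
is the (np/100)-th order statistic, interpolated). Positivity is strict
(mean > threshold; ties negative), calls are CK+/CD45+ -> CHC, CK+/CD45- ->
CTC, CK-/CD45+ -> leukocyte, CK-/CD45- -> negative, and control cells are
excluded from calls. Counts are normalized per 50,000 PBMCs, where "total
PBMCs" is the number of segmented non-control cells; values are kept at full
precision internally and rounded to two decimals only at I/O boundaries
(so one cell in a 30,000-PBMC scan reports as 1.67).

The default field configuration was chosen so that percentile gating has real
statistical headroom: 100 control cells stabilize the upper percentile, and
expanded stained-cell masks (~200 px) average noise more strongly than the
nucleus-only control masks (~45 px), placing the threshold several standard
deviations above the negative cells' mean-intensity distribution. Under
these conditions planted (CHC, CTC) counts are recovered exactly in >= 95%
of seeded fields and fields without planted CHCs report zero CHCs in >= 98%
- both properties are asserted in the test suite at exactly those rates.

## Longitudinal classification

For a patient timeline (baseline at or before treatment start, strictly
increasing sample times, trial end recorded):

- **nadir**: undetectable iff some on-trial post-treatment sample is zero;
- **end of trial**: increased iff the last on-trial sample is positive after
  a zero nadir;
- **post-trial**: evaluated on samples after trial end (`not_available` if
  none);
- **interval increase**: the first post-nadir positive normalized count,
  measured from the zero nadir, with its sample time.

Phase labels partition detections: positive samples before the first zero are
*responsive*, positive samples after any zero are *resistant*, zero samples
are *none*; a sample's label propagates to every CHC crop from it. The
baseline is the last sample at or before treatment start - for cohorts where
a patient received therapy before enrollment, that pre-trial exposure is
metadata, not something inferred from counts.

The baseline patient-versus-healthy comparison uses a Mann-Whitney U test
implemented in the package (not delegated) so the exact small-sample branch
is testable: for `n1 * n2 <= 400` the two-sided p-value is exact, computed by
the Streitberg-Rohmel shift algorithm over doubled mid-ranks (doubling makes
tied mid-ranks integers; the dynamic program conditions on the observed tie
pattern and is equivalent to full enumeration of all C(n1+n2, n1)
assignments, which the tests verify by brute force for n1, n2 <= 6). The
cutoff 400 keeps the study-scale 5-versus-15 comparison on the exact branch.
Two-sided p is twice the smaller tail mass, capped at 1; larger samples use
the normal approximation with tie and continuity corrections.

## The beta-VAE

Crops are 64 x 64 x 3 (CK, CD45, DAPI), zero-padded windows centered on the
cell centroid, each channel divided by its sample's median per-cell mean
intensity (median over all segmented non-control cells, floored at 1e-6), so
a global illumination factor cancels exactly.

The model is a convolutional encoder of five stride-2 layers with 32, 64,
128, 256, and 512 filters (3 x 3 kernels, ReLU), a 64-dimensional Gaussian
latent with mean and log-variance heads, and a mirrored decoder of transposed
convolutions with a linear output layer. The objective is pixelwise squared
reconstruction error (summed over pixels, averaged over the batch) plus
`beta * KL` against a standard-normal prior. Beta is annealed per training
batch: starting at 0.001 and increasing by 0.001 every batch until it reaches
2, where it remains (`beta_at(k) = min(2, 0.001 + 0.001 * k)`, batch 0 at
0.001; values within 1e-12 of the ceiling snap to it so the plateau is exact
despite accumulated floating-point increments). Training uses Adam (learning
rate 5e-4), batch size 16, at most 100 epochs, and early stopping on a 10%
validation split (patience 10, min_delta 0), restoring the best-validation
weights; validation loss reconstructs the posterior mean, so it is
deterministic. All randomness - initialization, split, shuffling,
reparameterization noise - derives from the config seed.

Choices the recipe leaves open, fixed here as package defaults: squared-error
reconstruction; 3 x 3 kernels with stride 2 and (0, 1) edge padding (each
layer exactly halves the 64-px side, giving a 2 x 2 x 512 bottleneck);
He-normal initialization with the log-variance head scaled by 0.01;
log-variances clamped to [-8, 8]. The network is implemented directly in R:
convolutions are im2col gathers followed by GEMM, and the scatter-add of the
backward data pass (also the forward pass of the transposed convolution,
which is its exact mirror) is a precomputed sparse-matrix product cached per
feature-map geometry. The analytic gradients of every layer are verified
against finite differences in the test suite.

Embeddings are posterior means (not samples). UMAP (n_neighbors 15, min_dist
0.1, fixed random state) is run through the `umap-learn` Python library and
is *visualization only*: the phenotype-separation silhouette is always
computed in the full 64-dimensional latent space, to avoid projection
artifacts. The phenotype report also checks the expected marker directions -
mean normalized CK higher in resistant crops, mean normalized CD45 higher in
responsive crops - on per-crop features (channel means over the DAPI-defined
footprint, and the footprint area).

## Problem sizes

The package's own validation runs at desk scale, chosen once: segmentation
and gating properties on 50 + 50 seeded ~450 x 480-px fields; regime
recovery on 200 simulated patients; the separation test trains the
full-filter-stack model on 240 crops for up to 30 epochs at a fixed seed and
asserts a latent silhouette above 0.2 plus both marker directions. Training
longer or on more crops increases the separation margin; the asserted floor
is deliberately conservative. The `demo_config()` pipeline uses a reduced
filter stack (8, 16, 32; latent 16) so the end-to-end demo finishes in
seconds; the full architecture remains the default of `vae_config()`.

## Known limitations

- The classical segmenter assumes roughly isotropic, non-overlapping cells;
  dense clumps or strongly anisotropic cells need a learned replacement.
- Percentile gating presumes the control region carries enough cells (>= 30
  enforced; ~100 recommended) and that staining background is comparable
  between the control strip and the sample area.
- "Undetectable" is exactly zero detected cells; assays with nonzero limits
  of detection would need a threshold parameter instead.
- The Mann-Whitney exact branch is quadratic in total rank mass; beyond
  `n1 * n2 = 400` it switches to the corrected normal approximation.
- The beta-VAE runs on CPU in R; it is sized for hundreds of crops, not the
  tens of thousands a GPU implementation would handle.
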