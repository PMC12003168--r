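---
title: "Quantification methods in gliaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods in gliaquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliaquant)
```

# Scope

`gliaquant` implements, as tested reusable functions, the bespoke
quantification procedures used to characterise microglial responses around
amyloid plaques and their downstream tissue consequences: a fluorescence
image-analysis pipeline for plaque-proximal marker expression, EM g-ratio
morphometry from annotated axon areas, grade-based phagocytosis scoring,
and compositional/signature statistics for single-nucleus RNA-seq data.
Upstream steps that are performed by well-known external tools in practice
(read alignment, normalisation, clustering, UMAP, doublet scoring,
differential expression) are out of scope: their outputs — label maps,
cluster assignments, doublet flags, DEG tables, embeddings — are inputs
here.

Because no microscopy, EM or sequencing data are shipped
with the package, a synthetic-data module generates ground-truthed stand-ins
for every input type. All tests and the reproduction script run entirely on
these synthetic data.

# The imaging pipeline

## Primitive operators

All operators act on a `channel_image` — a 2D intensity grid plus a
physical pixel size (µm/px) — so every threshold is stated in physical
units and is resolution-independent.

* **Fourier size filter.** A radially symmetric Gaussian transfer function
  applied in the Fourier domain, parameterised by the FWHM of the
  equivalent spatial Gaussian. At the cutoff period a sinusoid keeps
  `exp(-2*pi^2/2.355^2)` (about 2.9%) of its amplitude; at ten times the
  cutoff it keeps about 96.5%. The DC component is untouched, so the
  low-pass preserves the image mean exactly. The direction is switchable:
  `pass-large` returns the low-pass (denoising that removes sub-cutoff
  detail), `pass-small` returns the complement (removal of smooth
  background larger than the cutoff). We chose a Gaussian rather than a
  hard annular mask because it has a closed-form, testable attenuation
  curve and no ringing; the exact kernel of ImageJ's FFT bandpass is not
  reproduced bit-for-bit.
* **Gaussian blur** with physical sigma, separable convolution, kernel
  truncated at 3 sigma and renormalised. The boundary is reflective with
  the edge pixel repeated; this particular reflection makes the operator
  exactly mass-conserving, which the tests assert to 1e-6 relative.
* **Rolling-ball background subtraction.** The background is the grayscale
  morphological opening of the image with a non-flat ball structuring
  element (height `sqrt(r^2 - d^2)`, one intensity unit per pixel of ball
  height), i.e. the classic sphere rolled under the intensity surface.
  Balls larger than 20 px radius trigger the standard acceleration:
  block-minimum shrinking, opening at reduced radius, bilinear
  re-enlargement. The background is clipped to lie under the image, so
  `0 <= output <= input` always holds; on small grids the accelerated path
  is disabled and the opening is exact, which is how the tests compare it
  against a brute-force double-loop oracle.
* **Otsu threshold** on a 256-bin histogram spanning the observed min–max
  (the ImageJ convention), maximising between-class variance over interior
  bin edges, ties broken toward the smallest maximiser; foreground is
  strictly above the threshold. Shift equivariance is exact because the
  bins track the value range.
* **Connected components** are 8-connected (hand-written union-find;
  labels are renumbered in reading order of each object's first pixel),
  with a strict physical-area filter: an "above X µm²" rule keeps areas
  strictly greater than X (130 µm² for plaques).

## Nuclei segmentation

`segment_nuclei()` composes: size filter (2.6 µm cutoff, pass-large) →
Gaussian blur (0.52 µm) → Otsu binarisation → hole filling → Euclidean
distance transform → seeded watershed. Seeds are the local maxima of the
distance map, with maxima closer than the configured minimum peak
separation suppressed in favour of the higher peak; flooding is a
deterministic priority-queue descent of the distance map (marker-controlled
watershed). Pipelines of this kind often rely on a pretrained star-convex nuclei
model for the initial segmentation; here the classical Otsu + EDT
watershed chain is the reference implementation because acceptance is
ground-truth recovery on synthetic blobs, where it suffices. A plug-in hook
(`segmenter =`) accepts any callable returning a `label_map`, and such a
plug-in is held to the same matching contract by the tests.

Two constants are package conventions with no counterpart among the
pipeline's stated processing constants: the minimum
seed separation (4 µm) and the minimum nucleus area (10 µm²), both sized to
typical nuclear diameters and both configurable. Hole filling is on by
default because ring-like nuclear staining otherwise splits the distance
map.

## Plaque segmentation

`segment_plaques()` composes: size filter (26 µm cutoff) → rolling ball
(52 µm) → Otsu → 8-connected labelling with the strict 130 µm² filter.

Size filters specified as acting on structures above some physical scale
(the idiom of common imaging software) admit two readings, and the package
implements both for the 26 µm plaque-channel filter. For the DAPI channel the
corresponding 2.6 µm filter is clearly a low-pass (`pass-large`): it
removes sub-nuclear noise while keeping 5–10 µm nuclei. For the amyloid
channel we default to the complementary reading (`pass-small`): treating
the 26 µm filter as removal of structures larger than 26 µm, i.e.
background suppression before the rolling ball. The reason is quantitative:
plaques in the size range of interest (tens to hundreds of µm²) lie *below*
26 µm in diameter, so a 26 µm low-pass blurs the objects themselves and
roughly doubles their apparent Otsu area, whereas the background-removal
reading leaves plaque area recovery accurate to a few percent on
ground-truthed scenes (exact on noiseless ones). Neither reading is asserted to be canonical; `plaque_filter_mode`
switches between them.

## Per-cell quantification

`measure_cells()` reports the unweighted centroid, area and the mean of
each channel over each nucleus label — the per-nucleus mean being the
expression measure for Iba1 and Clec7a. `classify_positive()` applies Otsu
to the cell means *within one image*; thresholds are never shared across
images. `plaque_proximity()` measures the Euclidean distance from the cell
centroid to the nearest plaque *pixel* (zero inside a plaque): the 30 µm selection is read as a band around
the object boundary, not around plaque centroids. `expression_profile()` implements the
pooling scheme: per-image histograms on shared bin edges, each divided by
its own sum (integral normalisation; with constant bin width the sum is the
integral up to a constant), per-animal
element-wise medians across images, and per-group mean ± s.e.m. (SD with
n−1 over animals). Bin count and range are free parameters; the default is 20 equal-width bins over the pooled range, fixed
across images so profiles are comparable — per-image bins are the obvious
alternative and can be passed explicitly.

`marker_metrics()` collects the simple histology ratios: count ratios
(e.g. Olig2+/DAPI+, CC1+/Olig2+), densities per stated ROI area (e.g. PV+
interneurons per 2×10⁴ µm² in CA1, per 3×10⁴ µm² in cortex) and the
MBP/DAPI mean-gray ratio within an ROI.

# EM morphometry

Diameters derive from annotated cross-section areas by `d = 2*sqrt(A/pi)`;
the g-ratio is `d_axon / d_fiber` and sheath thickness is their
difference. These are exact formula applications — the tests hold them to
machine precision — and the g-ratio is scale-invariant by construction.
`grid_sample_axons()` reproduces an unbiased selection rule: a square
grid is overlaid and objects containing a grid intersection point are
taken, in reading order of the nodes, capped at 20 per image (the grid
origin is configurable; shifting it is the only effect an alternative
node convention would have).

Group comparison follows the nonparametric scheme standard for such
data: Shapiro–Wilk per group as a
reported diagnostic (never a gate), Kruskal–Wallis with tie correction
across all groups, then pairwise two-group Wilcoxon rank-sum tests with
p-values multiplied by the number of comparisons and capped at one
(Bonferroni). Rank-sum tests are used for the pairwise step (exact
p-values at small n, normal approximation with tie correction
otherwise); Dunn's test is a common alternative post hoc. Pooling axons
across animals pseudo-replicates; the default is per-axon with
`animal_id` retained so a per-animal aggregation is a one-liner.

# Phagocytosis scoring

Bead counts map to grades (0 beads → 0; 1–3 → 1; 4–6 → 2; 7–10 → 3; >10 →
4). Per field of view, `pct_phagocytic` is the percentage of counted
microglia with at least one bead, and the phagocytic index is
`sum(grade * pct_in_grade)`. The base of each grade's percentage admits two conventions; the
default takes each grade's percentage over
*all* counted microglia, so the grade percentages sum to the phagocytic
percentage, the index is bounded by 400, and the identity
`index = 100 * mean(grade)` holds exactly (asserted in the tests). The
alternative base (percentage among phagocytic cells only) is available via
`denominator = "phagocytic"`. Aggregation is field → animal (mean) →
group (mean ± s.e.m. over animals).

# Single-nucleus compositional statistics

* **QC filter** (`qc_filter`): genes detected in fewer than 3 cells are
  removed first; then cells with fewer than 200 detected genes, fewer than
  500 or more than 30,000 UMIs, or more than 5% mitochondrial reads are
  removed from the reduced matrix. All inequalities are strict — a cell at exactly 5%
  mitochondrial reads survives. The filter is a single pass by design
  (gene filter, then cell filters); on realistic matrices it is idempotent,
  which the tests check, but a pathological matrix could in principle
  expose new sub-threshold genes after cell removal — rerunning the filter
  makes that explicit rather than hiding an internal iteration.
* **Doublet-cluster rule** (`doublet_cluster_filter`): clusters with
  strictly more than 50% externally flagged doublets are dropped whole;
  every other cluster keeps all its cells, including flagged ones —
  the cluster-level rule, applied after external doublet scoring.
* **Proportion ANOVA** (`proportion_anova_holm`): per-sample counts become
  proportions; each cell type gets a one-way ANOVA across genotypes; the
  family of raw p-values (all cell types in the call) is Holm-adjusted.
  Bartlett and Shapiro–Wilk diagnostics are reported alongside and never
  gate the test. When a cell type shows no between-sample variation at all
  the F statistic is reported as 0 rather than NaN.
* **kNN/KL neighbourhood variability** (`knn_kl_variability`): for each
  cell, the label distribution over its 30 nearest Euclidean neighbours
  (self excluded, ties broken by index) is compared to the global label
  distribution by Kullback–Leibler divergence. Fixed conventions: natural logarithm
  (nats); the embedding is an input (deriving one belongs to the
  clustering pipeline, which is out of scope); labels may be samples
  (replicate × genotype) or genotypes, and summaries are emitted per
  cell, per label class and overall, so any of the three averaging
  levels can be compared to its controls.
  Controls permute labels uniformly on the same neighbour graph with a
  caller-supplied seed; the observed mean is located within the control
  distribution (an empirical percentile), which is the package's
  shuffled-control comparison.
* **DEG filtering and overlap** (`deg_filter_overlap`): significance is
  strict — log2 fold change greater than 0.25 *and* FDR below 0.01; genes
  exactly at either boundary are excluded. Matching is exact symbol
  equality after whitespace trimming; no ortholog mapping is attempted.
  With synthetic tables built to set sizes of 461 (reference), 488
  (study) and 96 (shared) the overlap arithmetic returns 365 reference-only
  and 392 study-only genes.

# The synthetic-data module

`sim_params()` holds one seeded parameter set for all five generators; each
generator derives its own sub-seed (fixed offsets from `rng_seed`), so
adding one generator call never perturbs another's output, and equal seeds
give bit-identical results.

What the scene generator emulates — and deliberately does not:

* Nuclei are isotropic Gaussian-profile disks (sigma = radius/2, truncated
  at the radius), with the peak scaled so the disk-average equals the
  recorded true mean. This is analytically checkable but is not a point
  spread function; no optics are simulated.
* Marker channels (Iba1, Clec7a) are uniform disks at the true mean. This
  is a deliberate design choice: the segmented nuclear region is always a
  subset of the true disk, and only a spatially flat marker makes the mean
  over *any* such subset equal the truth, so measurement bias and
  segmentation bias stay separable in the tests. Real immunofluorescence
  is textured; recovery rates measured here are therefore upper bounds on
  real-data performance.
* The planted gradient sets each Iba1-positive cell's true Clec7a mean to
  `baseline + slope × distance-to-plaque` (defaults 200 and −1.5/µm,
  chosen so the mean stays positive across a 154 µm field; the truth table
  keeps the exact linear value even where rendering would clip).
* Plaques are unions of 3–6 jittered disks — irregular in outline like
  amyloid deposits but with an exact truth mask; no core/halo structure.
* Noise is additive Gaussian (default SD 8 on an intensity scale where
  nuclei average ~500), plus a smooth sinusoidal background (amplitude 30)
  standing in for uneven illumination; Poisson noise is available behind
  `noise_model = "poisson"`. The channel intensity scales are declared conventions, not
  measurements of any particular microscope.
* Iba1-positive and negative mean ranges (250–350 vs 40–80) are kept at
  least five noise SDs apart by validation, the separation the positivity
  tests assume.
* The axon generator emits measurement *tables* (lognormal inner
  diameters, truncated-normal g-ratios around group means of 0.75 for WT,
  0.85 for the amyloid model and 0.77 for the amyloid model without IL-12
  signalling, SD 0.05, 3 animals × 20 axons per group), not EM images.
  Areas are exactly consistent with the sampled diameters.
* Bead counts are zero-inflated Poisson (structural-zero probability 0.3);
  composition counts are multinomial per sample at 1,000 cells; DEG tables
  are constructed to hit their significant-set sizes exactly, with decoy
  genes failing the filter on fold change, on FDR, or sitting exactly on
  the 0.25 boundary.

Passing tests on these data therefore demonstrate the *procedures* are
implemented correctly and recover planted structure under the stated noise
model; they do not certify performance on real micrographs, whose PSF,
texture and artefacts are richer.

# Numerical choices and degenerate inputs

* Otsu on fewer than two distinct values is an error at the operator
  level; `classify_positive()` converts it to an "indeterminate" flag per
  image, and `segment_nuclei()` to an empty label map with a warning.
* An image with no plaques yields infinite distances and all proximity
  flags false (with a warning), never an error.
* Grayscale-ball radii below one pixel are rejected; Fourier cutoffs below
  one pixel return the input with a warning.
* Watershed flooding breaks height ties by insertion order, making label
  maps bit-reproducible.
* kNN ties are broken by cell index; permutation controls use one
  user-visible seed.
* The phagocytosis summary excludes empty counting units with a warning.

# Problem sizes in the shipped tests

The test-suite benchmarks run at the generator defaults: 512 × 512 px
scenes at 0.3 µm/px with 50 nuclei and 3 plaques (20 seeds for the
end-to-end recovery suite), 200 simulation replicates for the ANOVA power
and morphometry recovery properties, 1,000 replicates for the type-I-error
estimate (a rate estimate deserves the extra precision; its binomial SE at
1,000 is under 0.8 percentage points), 100 seeds for KL calibration, and
1,000 random vectors for the Holm oracle. These sizes are the package's
own choices balancing statistical resolution against a test suite that
runs in a couple of minutes on one CPU.

# Known limitations

* The classical nuclei segmenter merges nucleus pairs whose distance-map
  maxima fall closer than the configured 4 µm seed separation; on the
  default benchmark this costs a few percent of heavily overlapping pairs
  (the matched fraction stays above 95% with no spurious labels). A
  learned instance segmenter plugged in through `segmenter =` is the
  recommended route for crowded real tissue.
* The rolling-ball acceleration introduces sub-intensity-unit deviations
  from the exact opening at large radii; the exact path is available via
  `max_kernel_px = Inf`.
* Expression-profile bins are global by default; if acquisition gain
  varies across images, per-image binning (explicit `bins`) may be more
  appropriate.
* The KL statistic is reported descriptively against its shuffled
  controls; no parametric p-value is attached, matching its use as a
  mixing diagnostic.
* `qc_filter` quantifies mitochondrial content from caller-supplied gene
  flags; no gene-name heuristics are applied.
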