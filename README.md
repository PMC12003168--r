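# gliaquant

Quantification pipelines for studies of microglial responses to amyloid
pathology. The package re-implements, as tested R functions, the bespoke
measurement procedures such studies rely on:

* **Plaque-proximal marker quantification** — DAPI denoising (Fourier size
  filter, 2.6 µm cutoff; Gaussian blur, σ = 520 nm), watershed nuclei
  segmentation on the Euclidean distance map, amyloid-plaque segmentation
  (26 µm size filter, 52 µm rolling-ball background subtraction, Otsu,
  objects strictly above 130 µm²), per-nucleus mean intensities as marker
  expression, per-image Otsu positivity calls, selection of marker-positive
  cells within 30 µm of a plaque, and integral-normalised expression
  histograms pooled image → animal (median) → group (mean ± s.e.m.).
* **EM myelin morphometry** — diameters from annotated cross-section areas
  via d = 2·√(A/π), g-ratio d_axon/d_fiber, sheath thickness
  d_fiber − d_axon, unbiased grid sampling of 20 axons per image, and
  Shapiro–Wilk / Kruskal–Wallis / Bonferroni-adjusted pairwise rank tests.
* **Phagocytosis scoring** — bead-uptake grades (1–3 beads = grade 1,
  4–6 = 2, 7–10 = 3, >10 = 4), percentage of phagocytic microglia per
  field, and the phagocytic index Σ grade × percentage-in-grade
  (equivalently 100 × mean grade).
* **Single-nucleus compositional statistics** — strict QC filters (genes in
  <3 nuclei; nuclei with <200 genes, <500 or >30,000 UMIs, >5%
  mitochondrial reads), removal of clusters with >50% doublets, cell-type
  proportion one-way ANOVA with Holm–Bonferroni adjustment and
  Bartlett/Shapiro–Wilk diagnostics, a k-nearest-neighbour
  Kullback–Leibler statistic (k = 30) for how cells distribute among
  samples with shuffled-label controls, and strict DEG filtering
  (log2FC > 0.25, FDR < 0.01) with signature-overlap arithmetic.
* **Synthetic data** — seeded, ground-truthed generators for every input
  type (multichannel scenes with a planted Clec7a-vs-plaque-distance
  gradient, axon area tables, zero-inflated bead counts, multinomial
  compositions, DEG table pairs with exact overlap), so the entire
  pipeline is testable without any microscopy or sequencing download.

The methods vignette (`vignettes/gliaquant-methods.Rmd`) documents the
models, conventions and design decisions in detail.

## Worked example

```r
library(gliaquant)

p  <- sim_params(rng_seed = 1)          # study-condition defaults
sc <- generate_scene(p)
sc
#> <synthetic_scene> 50 nuclei (25 Iba1+), 3 plaques, nuclei/iba1/clec7a/plaque

nuclei  <- segment_nuclei(sc$channels$nuclei)
plaques <- segment_plaques(sc$channels$plaque)
nuclei
#> <label_map> 512 x 512 px @ 0.3 µm/px, 48 objects
plaques
#> <label_map> 512 x 512 px @ 0.3 µm/px, 2 objects
```

48 of the 50 planted nuclei are recovered (two heavily overlapping pairs
merge); the two plaque objects are exactly right — two of the three
planted deposits coalesce, and the truth mask itself has two components
above 130 µm².

```r
cells <- measure_cells(nuclei, sc$channels[c("iba1", "clec7a")])
cells <- classify_positive(cells, "iba1")
cells <- plaque_proximity(cells, plaques, radius_um = 30)
sum(cells$in_proximity)
#> [1] 11    # Iba1+ cells within 30 µm of a plaque

coef(lm(mean_clec7a ~ dist_to_plaque_um,
        data = subset(cells, positive_iba1 & is.finite(dist_to_plaque_um))))
#>       (Intercept) dist_to_plaque_um
#>            216.93             -1.58
```

The fitted Clec7a-vs-distance slope (−1.58 intensity units per µm)
recovers the planted gradient (−1.5/µm): microglial Clec7a expression
decays with distance from the nearest plaque.

```r
phagocytosis_summary(generate_bead_counts(p))
#> <phagocytosis_summary> (all-cell denominator)
#>            group n_animals pct_phagocytic_mean phagocytic_index_mean phagocytic_index_sem
#>           APPPS1         3               54.44                 59.33                2.776
#>  APPPS1.Il12b-/-         3               68.22                103.56                1.975
#>               WT         3               69.11                117.78                4.377
```

The amyloid-model group shows the reduced uptake planted in the generator;
removing IL-12 signalling restores it toward wild type.

```r
tabs <- generate_deg_tables(p)
deg_filter_overlap(tabs$study, tabs$reference)
#> <deg_overlap> log2FC > 0.25 & FDR < 0.01: 96 shared, 365 reference-only, 392 study-only
```

With significant sets of 461 (reference signature) and 488 (study) genes
sharing 96, the strict filter leaves 365 reference-only and 392 study-only
genes.

A thin command-line wrapper over the same functions is installed as
`exec/gliaquant` (subcommands `simulate`, `segment`, `quantify`, `morpho`,
`phago`, `overlap`).

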