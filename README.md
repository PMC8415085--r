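# codexbench

Benchmarking single-cell intensity normalization and unsupervised
clustering for cell-type annotation in CODEX-style multiplexed tissue
imaging.

## The problem

A multiplexed imaging experiment ends in a segmented cell table: one row
per cell with spatial coordinates and a few dozen quantified fluorescence
channels. Annotating cell types from that table requires two early
choices — how to normalize the intensities and how to cluster the cells —
and those choices interact with the data's characteristic noise: channels
with weak signal or heavy background, per-channel exposure differences,
lateral spillover across imperfect segmentation boundaries, and folded
tissue regions that read positive on every marker. `codexbench` makes that
interaction measurable. It provides:

* a **synthetic tissue generator** with exact ground truth that reproduces
  those noise modes at configurable strength (16 colon-style cell types,
  22 markers, 4 spatial compartments, a 0.3% rare type on a low-signal
  channel, a CD69/CD127 phenotypic continuum, a fold-noise region);
* the **five data treatments**: raw, per-marker Z, log double-Z
  (`-ln(1 - Φ(z_cell))` after marker- then cell-wise Z), 1st/99th
  percentile-capped min-max, and `asinh(x/150)`;
* the **four clustering algorithms**: k-means (kmeans++ seeding + Lloyd,
  best of restarts), Leiden on a kNN graph, and a re-implemented X-shift
  (kNN-density ascent with dip-based mode merging) under Euclidean or
  angular distance, plus elbow-point model selection;
* a **hierarchical 2D gating engine** that emulates manual gating and its
  spillover failure mode;
* a 4-level **cell-type hierarchy** (35/20/14/7 classes for the colon
  ontology) with level merging;
* **annotation standards** (majority-vote, profile-correlation, and a
  90-cluster over-clustered standard) and **agreement metrics**: per-type
  F-score (harmonic mean of precision and recall), Cohen's kappa,
  fold-changes of type percentages, all-vs-all cross-comparison;
* spatial **cellular-neighborhood analysis** with enrichment-based naming
  and fold-noise neighborhood detection.

It is aimed at analysts of multiplexed imaging (CODEX/PhenoCycler, and by
extension MIBI/IMC-style channel data) who need to choose a normalization
and clustering strategy with eyes open.

## Worked example

The numbered scripts under `analysis/` run the full study; each writes
tidy CSVs under `results/`. For instance:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_benchmark.R
```

prints (5,000 cells, seed 7):

```
Simulated 5000 cells across 2 regions; 17 level-1 labels.
Rarest populations: Noise 72, Neuroendocrine cell 20, Neutrophil 14
...
Level-4 mean F by treatment (averaged over algorithms):
     arcsinh log_double_z       minmax          raw            z
       0.965        0.975        1.000        1.000        1.000
Level-4 mean F by algorithm (averaged over treatments):
           gated           kmeans           leiden   xshift_angular
           0.827            0.996            1.000            0.991
xshift_euclidean
           0.993
Gated standard level-4 mean F: 0.827; over-clustered standard: 0.999
```

Mean F here scores each annotation against ground truth at the coarsest
granularity, averaging over the union of observed types (missed types
score 0). The headline pattern: at coarse granularity every
clustering-based annotation beats hand-gating emulation (0.83), whose
errors come from spillover-contaminated endothelium and from labelling
fold-region noise cells as real types. `analysis/03_gating_spillover.R`
sweeps the spillover fraction λ and shows gating misassignment of
endothelial cells rising monotonically (0% at λ=0 to ~2% at λ=0.8 at the
default geometry) while profile-annotated Z+Leiden clustering loses ~5×
less endothelial F-score; `analysis/04_neighborhoods.R` shows the
folded-tissue cells isolating into their own cellular neighborhood
("Noise / Goblet cell", 71 cells) even though they are a fraction of a
percent of the tissue. At the finest granularity, the rare neuroendocrine
population (~15 cells, marked only by low-signal CHGA) is found by every
algorithm after Z normalization and by none on raw data — normalization,
not the clustering algorithm, decides whether rare dim populations exist
at all.

A minimal in-R session:

```r
library(codexbench)
ds <- build_default_scenario(5000, seed = 7)
z  <- apply_treatment(intensity_matrix(ds$cell_table), "z")
ca <- cluster_leiden(z, seed = 7)
ann <- annotate_by_majority(ca, truth_annotation(ds))
f_scores(truth_annotation(ds), ann, level = 4, h = ds$hierarchy)$mean_f
```

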