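---
title: "Benchmarking normalization and clustering for multiplexed imaging cell typing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking normalization and clustering for multiplexed imaging cell typing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Cell-type annotation of CODEX-style multiplexed tissue imaging starts from a
segmented single-cell table: one row per cell with spatial coordinates and a
few dozen quantified fluorescence channels. Every downstream biological
claim rests on how those intensities are normalized and how cells are
grouped. `codexbench` implements a controlled benchmark of that pipeline:
five intensity treatments crossed with four unsupervised clustering
algorithms, scored against gating-based and over-clustered reference
annotations at four levels of cell-type granularity, with
cellular-neighborhood analysis downstream. Because real gold standards are
themselves contaminated by the noise being studied, the benchmark runs on a
synthetic tissue generator with exact ground truth that reproduces the four
noise modes that dominate real data: low-signal channels, high-background
channels, lateral segmentation spillover, and folded-tissue regions.

# The synthetic tissue model

## Intensity model

For cell $i$ of type $t$ and marker $m$ the quantified intensity is

$$x_{im} = e_m \left( \rho_{tm} S_{im} + B_{im} \right),$$

where $e_m$ is a per-channel exposure scale (emulating antibody staining
strength and exposure-time differences; defaults span 0.5–4),
$\rho_{tm} \in [0,1]$ is the type's expression level for the marker,
$S_{im}$ is lognormal positive signal and $B_{im}$ Gaussian background
that may go negative, as real background-subtracted data does. The
lognormal is parameterised by its natural-scale mean and standard
deviation (`signal_mean`, `signal_sd`); the mean/CV form was chosen because
fluorescence units, not log-units, are what a panel designer reasons about.
Phenotypic markers (CD69, CD127) draw $\rho$ uniformly from a type-specific
band, so the CD4 T-cell split is a continuum rather than a binary state —
deliberately hard to resolve, as in real data.

The default panel (22 markers, 16 types across epithelium, vasculature,
stroma and muscle; shipped as the versioned fixture
`inst/extdata/synthetic_panel.json` so tests never regenerate it
implicitly) encodes the stress cases the benchmark needs: CHGA is a
low-signal, low-background channel that alone marks the 0.3%
neuroendocrine-like population; CD15/CD16 carry heavy background and mark a
0.3% neutrophil-like population; the cytokeratin-high epithelium band is
spatially adjacent to the CD31/CD34-high vasculature band. CHGA's signal
CV is ~19% — tighter than the 30% used for routine channels — encoding
a channel whose positives are dim but reliable once the channel is
rescaled; with a much wider CV the rare population smears along its one
discriminating axis and no method can find it at desk scale.

## Noise modes

**Segmentation spillover.** Each cell gains
$\lambda \cdot \max(0, \overline{x}_{\mathcal{N}(i),m})$ per channel, the
mean over neighbours within `spillover_radius` (20 tissue units) in the
same region; $\lambda$ defaults to 0.3. Bleed is additive-only (a
neighbour's stain is quantified inside the cell's mask; nothing is removed
from the neighbour) and clamped at zero because negative background noise
cannot bleed. This reproduces the signature failure: endothelial cells
adjacent to epithelium acquire cytokeratin and are mis-gated as epithelial.

**Tissue fold.** Cells inside `fold_region` receive, per channel, an
offset `channel_scale * TruncNormal(1.0, 0.3)` truncated at zero, where
`channel_scale` is the channel's expected positive level
($e_m \cdot$ `signal_mean`). A fold cell therefore reads like a typical
*positive on every marker* — the "all-marker-positive" artifact — while
respecting each channel's exposure: the extra fluorescence of doubled
tissue passes through the same gain as real signal. A single absolute
offset shared across channels was rejected: with exposures spanning 8×, any
offset large enough to look positive on bright channels is 50× the signal
of the dim CHGA channel and obliterates exactly the Z-rescaling the
benchmark studies. Masked cells' truth label becomes "Noise".

## What the generator does not emulate

No pixel-level imaging, no segmentation masks, no cell-size or morphology
effects, no per-cycle drift or tile seams, no batch/donor variation, and
spatial compartments are axis-aligned bands rather than crypt-like
geometry. Passing results therefore demonstrate that the pipeline's
*relative* conclusions (which treatment/algorithm combinations resist which
noise mode) are reproducible under a controlled model — not that absolute
F-scores transfer to any particular tissue.

# The treatments

All five operate per dataset on the cells × markers matrix, preserve shape
and marker order, and never emit NaN:

* **raw** — identity.
* **z** — per-marker centring and scaling by the population (ddof 0)
  standard deviation. The population form is used throughout the package;
  at thousands of cells the ddof choice is immaterial, and one convention
  everywhere keeps the double-Z composition exact.
* **log double-Z** — marker-wise Z, then cell-wise Z across markers, then
  $-\ln(1 - \Phi(z))$. The standard normal CDF is the natural reading of
  "Z score to probability"; the natural log is used; probabilities are
  clipped at $1 - 10^{-12}$ so the output stays finite (the clip point,
  $-\ln 10^{-12} \approx 27.6$, is far above any unclipped value).
  Zero-variance rows/columns map to zeros rather than erroring, so a
  degenerate synthetic channel cannot kill a run (configurable to `error`).
* **min-max** — per marker, clip to the 1st/99th percentiles (type-7
  linear-interpolation quantiles) and rescale to $[0,1]$; the upper cap
  removes artificially high background.
* **arcsinh** — $\operatorname{asinh}(x/150)$; cofactor 150 is the
  fluorescence-scale convention, linear within 0.5% for $|x| \le 15$ and
  logarithmic far above.

# The clustering algorithms

* **k-means**: kmeans++-style greedy seeding followed by Lloyd iterations
  (`stats::kmeans`), best of 10 seeded restarts by WCSS. On every dataset
  with $n \le 8$, $k = 2$ it attains the exhaustive-enumeration optimum
  (tested against a brute-force oracle).
* **Leiden**: symmetric unweighted kNN graph (Euclidean on the treated
  matrix), `igraph::cluster_leiden` under the modularity objective at
  resolution 1. The graph uses **10** neighbours: at the benchmark's
  5,000-cell scale the rare population (~15 cells) is smaller than the
  common 15-neighbour default, which would force every rare cell to wire
  into the bulk and let the modularity resolution limit absorb it; 10
  neighbours is the scale-consistent analog of the common default at
  130,000 cells. Note that on very small inputs modularity subdivides
  internally sparse groups, so well-separated blobs may yield more
  communities than blobs; communities still never mix groups.
* **X-shift** (Euclidean and angular): re-implemented from its published
  description. Density is the inverse mean distance to the K nearest
  neighbours; each point links to the densest of its K neighbours when
  strictly denser (exact ties resolve to the lowest cell index, so
  duplicated points form one mode); clusters are the trees rooted at
  modes. Mode pairs connected by a kNN edge are then merged when the
  density profiled along the segment between them never falls more than
  10% below the lower mode — a genuine valley between populations drops
  density several-fold, so the exact tolerance is uncritical, while a
  strict no-dip rule would be defeated by estimation noise. The
  over-clustered standard disables this merge on purpose (it wants
  fragmentation). No parity with the original Java tool is claimed.
* **Elbow selection**: the interior grid point maximizing the discrete
  second difference of the objective, ties to the smallest value — used
  for k-means WCSS curves and X-shift K → cluster-count curves.

Distances are computed on the full treated matrix with no PCA step, since
the benchmark's point is the treatment's effect on the geometry.

In the factorial benchmark k-means runs at $k = 30$ and X-shift at
$K = 10$: both deliberately over-cluster (~2× the 17 level-1 labels),
consistent with the observation that algorithms yielding more clusters
separate rare phenotypes better; majority annotation merges clusters back
to types afterwards.

# Gating, annotation standards, evaluation

The gating engine descends a tree of 2D rectangle/polygon gates
(boundary-inclusive; even-odd rule for polygons; first matching sibling in
document order wins; unmatched cells take the `rest` branch), so every cell
gets exactly one label. The default tree gates cytokeratin first — which
is precisely why spillover-contaminated endothelium mis-routes into the
epithelial branch, the failure mode the benchmark quantifies. Thresholds
are derived from the panel (midpoint of expected background and expected
positive in arcsinh space), i.e. calibrated on noise-free expectations,
never fitted to a generated dataset.

Cluster-to-type annotation is either **majority vote** against a reference
(the stand-in for expert image-overlay annotation; optimistic for the
reference it votes against, which is documented wherever scores are
reported) or **profile correlation** against expected expression vectors
with an 0.2 floor below which clusters are "Unassigned". The
**over-clustered standard** clusters raw data with angular X-shift into at
least 90 clusters (searching K downward), trims to exactly 90 by merging
the most-correlated profile pair, then agglomeratively merges profiles
with $r \ge 0.9$. Profile correlations are computed after standardizing
each marker across clusters — otherwise the brightest channels dominate
the Pearson statistic and distinct dim types merge.

Evaluation: per-type precision/recall/F with $F = 0$ when undefined;
`mean_f` averages over the union of observed types with absent types
scoring 0, which penalizes missed populations and makes the all-vs-all
cross-comparison matrix exactly symmetric. Cohen's kappa is reported
unclipped (negative = worse than chance); if both annotations are the same
constant labelling it is defined as 1. Fold changes of type percentages
use a 0.01-percentage-point pseudocount.

# Neighborhoods

Each cell's window is itself plus its 9 nearest spatial neighbours within
the same region (windows never span regions, since regions are separate
tissue blocks); window rows are type-composition fractions summing to 1.
k-means on the windows yields neighborhoods; enrichment is
within-neighborhood frequency over tissue-wide frequency, and names join
the top two enriched types. The fold-noise neighborhood counts as detected
when one neighborhood captures at least half the masked cells and masked
cells are its plurality truth label.

# Problem sizes and numerical conventions

The analyses and tests run at 2,000–5,000 cells — the scale at which every
qualitative contrast of the study (rare-type rescue by Z, spillover-driven
gating failure, fold-noise neighborhood detection, granularity
monotonicity) is already stable across seeds, as the 10-seed acceptance
checks verify. Stochastic checks use fixed seed sets; every package
function that consumes randomness takes an explicit seed and restores the
caller's RNG state. Ties are always broken deterministically
(lexicographic for labels, lowest index for densities, smallest k for
elbows), so identical configurations are bit-identical end to end.

# Known limitations

* Majority-vote annotation against truth inflates absolute F-scores; only
  contrasts between treatments/algorithms are meaningful.
* The shipped colon ontology is a reconstruction that reproduces the
  published 35/20/14/7 level counts and named types; the exact published
  membership map lives in supplementary material not shipped here (the
  fixture header lists the known ambiguities).
* X-shift here is a faithful re-implementation of the published idea, not
  the original tool; cluster counts will differ from VorteX.
* Exact kNN by blocked distance computation is quadratic; fine to ~20,000
  cells, wrong tool beyond that.
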