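---
title: "spotmap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spotmap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotmap)
```

Image-based spatially resolved transcriptomics (in situ sequencing, cyclic
smFISH and relatives) delivers its decoded output as a *spot table*: one row
per detected RNA molecule, carrying a gene label and a 2D position in
pixels, typically with 50–200 genes in the panel and $10^5$–$10^6$ reads per
section. spotmap analyses these tables at three levels: directly at read
level, after conversion into a units × genes count matrix ("segmentation"
in a broad sense), and at the level of cell classes defined externally by
scRNA-seq. This vignette explains the statistical machinery, the tunable
parameters, and the design decisions taken where the methods left genuine
choices open.

## Coordinate convention

Coordinates are continuous pixels with the origin at the top-left corner of
the image and y increasing downward, matching how the nuclear-stain raster
is stored, so spot tables overlay images without flips. Pixel `[i, j]` of
an image matrix covers `x` in `[i-1, i)`, `y` in `[j-1, j)`; a read maps to
pixel `[floor(x)+1, floor(y)+1]`. Readers expose `flip_y` for data recorded
with y increasing upward. Regions of interest are half-open boxes
`[xmin, xmax) × [ymin, ymax)`, so tiled ROIs partition reads exactly.

## Expression density maps

`gene_density()` smooths one gene's read positions with an isotropic
Gaussian kernel of standard deviation `bandwidth` (pixels):

$$\hat d(p) = \frac{1}{n}\sum_{i=1}^{n}
  \frac{1}{2\pi\sigma^2}\exp\!\Big(-\frac{\lVert p - r_i\rVert^2}{2\sigma^2}\Big).$$

The estimate is evaluated by exact summation rather than by a binned/FFT
approximation, for two reasons: maps stay true probability densities
(integrating to 1 over the plane, so maps of different genes are
comparable before display scaling), and the density can be queried at
arbitrary off-grid points, which the gradient finder requires. The default
bandwidth is Silverman's rule per gene,
$\hat\sigma\, n^{-1/6}$ with $\hat\sigma$ the mean of the marginal standard
deviations; there is no universally right choice, so the value actually
used is always recorded in the output. The default grid step is
`bandwidth/2`, a resolution/cost compromise; halving it changes the
integrated mass by well under 0.5%. Two-gene overlays rescale each channel
by its own maximum — the composite shows *where* each gene is dense, not
absolute abundance.

## Colocalization by neighborhood enrichment

`neighborhood_enrichment()` asks, for every gene pair, whether reads of the
two genes are spatial neighbors more often than expected if gene identities
were arbitrary. A k-nearest-neighbor graph (default `k = 5`) is built once
from the positions; directed links are counted by gene pair and symmetrized
(both directions summed off-diagonal; the diagonal counts a gene's
self-clustering). The null keeps all positions — and hence the graph —
fixed and shuffles the gene-label vector uniformly at random (default 500
permutations). Rebuilding the graph per permutation would be a no-op since
positions do not change. For observed count $x$ and permutation mean $\mu$
and standard deviation $\sigma$,

$$Z = \frac{x - \mu}{\sigma},$$

positive for enriched (colocalized) pairs, negative for mutually exclusive
ones. Under complete spatial randomness the off-diagonal Z-scores are
close to standard normal (the test suite verifies mean within ±0.3 and sd
within [0.7, 1.3] across 50 simulations).

Two properties deserve awareness. First, ties in neighbor distance are
broken by read index, so results are deterministic; a single seeded RNG
stream drives the permutations, making the full result bit-reproducible.
Second, the total number of directed links is fixed at $nk$, so the
Z-scores are compositional: if one pair is strongly enriched, the other
pairs involving those genes are necessarily depressed relative to the
shuffle null. With a small panel this is visible — in a three-gene fixture
where every A read has a coincident B partner, A–C sits around $Z \approx
-3$ even though C is placed independently, and at `k = 1` the effect is
extreme (the single neighbor slot of every A is consumed by its B partner,
pushing A–C below $-7$). Interpret strongly negative Z between a gene and
the partners of a strongly enriched pair with this constraint in mind, and
prefer moderate `k` (5–10) over `k = 1`.

## Gradient discovery and profiling

`gradient_field()` finds expression gradients de novo. On a regular lattice
of reference points, for each gene the KDE is evaluated at points offset by
$\pm b$ along each axis and the per-axis variation is summed over the gene
panel:

$$G_x(p) = \sum_{g=1}^{n_\text{genes}}
  \big|\, d_g(p - (b, 0)) - d_g(p + (b, 0)) \,\big|,$$

and analogously $G_y$. Because of the absolute value the field encodes
per-axis gradient *intensity* but not sign, so quiver arrows show unsigned
axis magnitudes; `signed = TRUE` drops the absolute value for users who
want a true direction field. Defaults: `b = bandwidth/2` and
`lattice_step = 2b` (roughly Nyquist sampling of the smoothed field).
Offset probe points outside the evaluated grid are legal — the KDE is a
function defined on the whole plane and is evaluated exactly, never
clipped. Lattice points whose probes come closer than three bandwidths to
the data bounding box are flagged non-interior: KDE edge bias is not
corrected there, and near a data edge the density fall-off itself registers
as a (real) gradient.

`project_to_axis()` supports supervised 1D profiling: each read's axis
coordinate is its minimum Euclidean distance to an origin point set,
$d_i = \min_r \lVert (x_i, y_i) - (x_r, y_r) \rVert$. Poly-line origins are
densified to ≤ 1 px vertex spacing first, so the result behaves as distance
to the curve (chord error below 0.05 px). `axis_profiles()` then computes a
1D Gaussian KDE of each gene's $d$ values, evaluated on
$[0, \max d + 3\,\text{bw}]$ with a per-gene Silverman default bandwidth.
Profiles of genes concentrated near $d = 0$ leak some kernel mass below
zero; no boundary correction is applied, which is worth remembering for
layers that touch the origin.

## Segmentation strategies

**Watershed cells from a nuclear stain.** `segment_dapi()` follows the
standard DAPI pipeline: white top-hat with a disc structuring element
(radius chosen larger than a nucleus radius) removes slowly varying
background — and, being a morphological residual, makes the result exactly
invariant to a constant intensity offset; a Gaussian blur
(`smooth_sigma = 2` px) stabilizes the subsequent global threshold (Otsu by
default) against pixel noise; holes are filled and specks below
`min_area = 30` px² removed; a watershed on the distance transform splits
touching nuclei; finally each nucleus is expanded outward by
`expansion = 10` px (bounded nearest-nucleus rule, computed exactly via a
kd-tree over nucleus pixels), approximating a cytoplasmic territory.
Pixels beyond the expansion stay unassigned, and reads falling there are
tallied but not assigned to any cell. Two touching nuclei are separable
when the distance transform of their merged blob retains two maxima; for
Gaussian-bump nuclei this holds from about 3 sd separation upward, while at
2.5 sd the saddle-to-peak gap collapses below any usable watershed
tolerance — a physical limit, not a parameter choice.

**Overlapping bins.** `overlapping_bins()` lays bin centers on a regular
lattice (`spacing` px apart) spanning the data bounding box; each bin is an
axis-aligned square of half-width `radius` (the conventional setting in the
field is radius 250 px with 50 px spacing, i.e. heavy overlap for a smooth
pseudo-cell map). Squares rather than discs make the tiling case exact:
with `spacing = 2·radius` every interior read is counted exactly once.
A `circular` flag switches to discs. Reads are assigned to *every* bin
containing them, so overlapping bins multi-count by design.

**Spot environments.** `spot_environment_bins()` summarizes the gene
composition within `radius` of every read (the focal read included),
producing one unit per read — useful where no meaningful cell or bin
segmentation exists.

**QC.** `qc_filter()` removes units with too few or too many reads, then
genes below a total-read floor, mirroring the usual practice of excluding
out-of-range bins and weakly expressed genes before clustering. The filter
is idempotent and reports what it dropped.

## Normalization, embedding, clustering

`normalize_by_gene_totals()` divides each gene column by its total across
units, so columns sum to 1. This removes the leverage of highly expressed
genes while preserving each gene's spatial pattern; it deliberately leaves
per-unit totals uncontrolled (a flag adds per-unit normalization for users
who want it, but the per-gene form is the default behavior). Zero-total
genes are a hard error directing to `qc_filter()`.

`pca_report()` runs centered PCA and reports scores, loadings and the
variance-explained spectrum; loadings are sign-fixed (largest-magnitude
loading per component made positive) so reported components are
reproducible. `rgb_embedding()` reduces the matrix to three dimensions —
top-3 PCs, or 3D t-SNE/UMAP run directly at three output dimensions — and
min-max scales each dimension to [0, 1] independently, giving every unit an
RGB color; rendering units at their centroids shows expression similarity
as color similarity. t-SNE and UMAP are stochastic: a seed is threaded
through and single-threaded execution keeps runs bit-reproducible, but
unlike PCA they do not guarantee identical colors for identical input rows
(approximate neighbor search), which the test suite acknowledges by
checking that contract on PCA only.

`cluster_units()` offers k-means (10 restarts, seeded), hierarchical
clustering with Ward linkage on Euclidean distance (linkage unstated in
common practice varies; Ward is the standard for expression matrices) cut
to `k`, and DBSCAN (`eps`, `min_samples`; noise labeled 0). DBSCAN is
implemented in-package with dense distance-matrix region queries —
appropriate for the a few thousand units a section yields. Graph-based
community detection (Leiden/Louvain) is intentionally absent.
`cluster_summaries()` reports per-cluster mean expression for annotation.

## Probabilistic cell typing

`pciseq_assign()` classifies segmented cells against scRNA-seq class mean
profiles $\mu_{kg}$ under an independent-Poisson model. A per-cell scale
factor absorbs capture depth,

$$s_c = \frac{\sum_g n_{cg}}{\operatorname{median}_k \sum_g \mu_{kg}},$$

(median over class totals, robust to outlier classes), and the class
log-likelihood up to a count-only constant is

$$L(c, k) = \sum_g \big[\, n_{cg}\,\log(s_c \mu_{kg} + \varepsilon)
  - (s_c \mu_{kg} + \varepsilon) \,\big],$$

with pseudo-expression $\varepsilon = 0.1$ reads guarding $\log 0$ against
genes a class does not express. Posteriors are priors times
$e^{L}$, normalized per cell with the log-sum-exp guard; priors default to
uniform (class abundances in the reference atlas rarely transfer to a
tissue section, but a named prior vector is accepted). Hard assignment is
the argmax, ties resolving to the first class in reference order. This is
deliberately a *cell-level* reduction of probabilistic cell typing:
spot-level reassignment of reads between neighboring cells, explicit
misread/background components and gene-efficiency re-estimation are not
modeled. At 30+ reads per cell and a reference with distinct class
signatures the reduction recovers simulated classes at ≥ 95% accuracy
(verified on 1,000 simulated cells in the test suite); at very low depth
or with near-collinear class profiles the full spot-level model would be
the better tool.

Multiplying all priors by a constant changes nothing; jointly scaling the
reference and the cells' depth leaves assignments invariant ($s_c$ absorbs
the scale); zero-read cells return the prior and are flagged.

## Synthetic fixtures: what they emulate, and what not

`make_layered_tissue()` generates fields with planted structure: axis-
aligned layer bands with per-layer gene multinomials (emulating cortical
layers with layer-restricted markers), genes with a Gaussian density
profile along one axis (smooth gradients), coincident gene pairs at a
fixed offset (colocalization), and uniform background genes (spatial
randomness). `make_nuclei_image()` renders nuclei as Gaussian intensity
bumps with optional noise and offset. `make_typed_cells()` places
non-overlapping disc cells on a jittered grid, draws per-gene Poisson
counts from a scaled class profile, and scatters the reads inside the
footprint (1 px inside the disc edge, so every read's pixel belongs to the
rasterized mask). Every generator is a pure function of its arguments and
seed and returns the ground truth beside the data.

These fixtures validate the statistical machinery, not image-analysis
robustness on real tissue: there is no optical crowding, no decoding
error, no autofluorescence, no irregular cell morphology, and nuclei are
isotropic Gaussians. Passing tests therefore demonstrate correctness of
the algorithms under their stated models, and calibration of the
permutation test under true spatial randomness — they do not certify
segmentation quality on real DAPI images.

## Problem sizes and numerical choices

The test suite and the acceptance script run on deliberately desk-scale
problems: colocalization calibration uses 3 genes × 1,000 reads over 50
generator seeds with 500 permutations each; oracle-equivalence checks use
n ≤ 500 against exhaustive $O(n^2)$ reimplementations; cell typing uses
1,000 cells × 5 classes × 20 genes; nuclei images are a few hundred pixels
square. kNN search and spot environments use chunked dense distance
computations (deterministic, exact, tie-broken by index) — adequate into
the low tens of thousands of reads; beyond that, the per-gene KDE sum and
the distance chunks grow linearly and quadratically respectively, and a
future version would switch to tree-based neighbor search throughout.
Degenerate inputs fail loudly: empty tables, absent genes, zero-variance
matrices, all-filtered QC, zero-total genes and sub-minimum permutation
counts are hard errors or explicit warnings rather than silent NaNs.
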