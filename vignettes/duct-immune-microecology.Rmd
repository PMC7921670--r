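---
title: "Mapping the immune microecology of DCIS ducts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the immune microecology of DCIS ducts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ductscape)
```

## The problem

Ductal carcinoma in situ (DCIS) is a malignant epithelial proliferation
confined within breast ducts. How tumour-infiltrating lymphocytes (TILs)
arrange themselves *around individual ducts* — rather than how abundant they
are overall — carries information about the local tissue ecology and,
potentially, about progression risk. Measuring that arrangement on a
haematoxylin & eosin (H&E) slide requires a chain of stages: find the
tissue, find and segment each duct, detect and classify every cell, exclude
any invasive compartment, and then summarise lymphocyte–duct colocalisation
with a spatial statistic. `ductscape` implements that chain end to end at
desk scale, together with a seeded synthetic-histology generator that gives
every stage exact ground truth, so the whole pipeline is testable without
any external slide.

## The colocalisation model

The ecological core treats a slide as a point pattern of cells and a set of
duct seeds. Duct centroids (in the low-resolution working frame, ~8 µm/px
for a ×20 scan) seed a Voronoi tessellation: region $R_k$ of duct $C_k$
contains all points $x$ with $d(x, C_k) \le d(x, C_j)$ for every other seed
$C_j$. Every lymphocyte is thereby attributed to its nearest duct. Regions
are intersected with a square quadrat grid of side `grid_um` (default
200 µm) to give counting units $i$; with $n_i^l$ lymphocytes and $n_i^e$
in-situ epithelial cells per unit and unit fractions
$p_i^l = n_i^l / \sum_i n_i^l$, $p_i^e = n_i^e / \sum_i n_i^e$, the
slide-level score is the Morisita–Horn similarity

$$\mathrm{score} \;=\; \frac{2\sum_i p_i^l\,p_i^e}
 {\sum_i (p_i^l)^2 + \sum_i (p_i^e)^2} \in [0, 1],$$

which is 1 when lymphocytes distribute proportionally to duct epithelium
across units and 0 when their supports are disjoint. The score is undefined
(reported missing) when either class has zero total count, and slides with
fewer than 5 kept ducts are flagged invalid — too few seeds make the
tessellation statistically meaningless.

Two rules precede the tessellation. First, ducts with fewer than 10
epithelial cells inside their outline are dropped (`filterDucts()`), the
conventional floor below which a "duct" detection is not trusted. Second,
epithelial cells *outside* every kept duct are relabelled `other`; the
union of 50 µm discs around them is treated as the invasive compartment,
and all cells inside it — and any duct seed inside it — are removed from
the analysis. The disc radius is a package decision (the geometric notion
of "region containing other epithelium" is otherwise under-specified);
50 µm is roughly two cell layers beyond the invasive margin, and the value
is configurable and echoed into every output.

Geometry notes: Voronoi regions are computed exactly by successive
half-plane cuts of a convex clip polygon (default: the convex hull of all
cells and seeds), so each region is convex and membership can be
cross-checked against the brute-force nearest-seed rule — the test suite
does exactly that on random configurations. Cells on a bisector go to the
lower duct id; coincident seeds are merged with a warning. Quadrat units
are the positive-area intersections of regions with the grid;
`grid_um = Inf` recovers one unit per region.

## The networks

Three small convolutional networks implement the imaging stages. No deep
learning framework is assumed: forward and backward passes for
convolution, average pooling and stride-2 transpose convolution are
implemented in C++ (RcppArmadillo) behind a minimal reverse-mode tape in R,
and every op is verified against finite differences in the test suite.
All three are fully convolutional and width-scalable; the defaults are the
desk-scale widths used throughout the tests.

**Duct segmentation** uses five inception blocks in the contracting path
and five decoder blocks in the expanding path. Each inception block runs
parallel 1×1, 1×1→3×3, 1×1→5×5 and pooled→1×1 paths (each conv followed by
per-channel normalisation and ReLU) and concatenates them, capturing
structure at several scales at once. The input patch, downsampled by 2 and
by 4, feeds the second and third encoder blocks alongside the pooled
features, so wide spatial context enters early. Decoder blocks upsample by
transpose convolution and concatenate the matching encoder features; the
main sigmoid output sits at input resolution and three auxiliary outputs at
the 1/2, 1/4 and 1/8 decoder resolutions. The loss is weighted
cross-entropy on the main output plus `lambda` (default 0.3) times the
weighted cross-entropy of each auxiliary output against the re-binarised
pooled target, with its weight map recomputed at each scale. The per-pixel
weight map is `balance + w0 * exp(-d^2 / 2 sigma^2))` with `d` the distance
to the nearest duct boundary (defaults `w0 = 2`, `sigma = 5` px): the
class-balance floor keeps sparse foregrounds learnable and the Gaussian
term concentrates gradient on weak duct boundaries. Training uses Adam
from `lr0 = 1e-3` with a tenfold drop every `lr_decay_every = 4` epochs —
a stepped version of the aggressive per-epoch tenfold decay that a
full-scale run would use, which at ten or fewer epochs would freeze
learning after the first two. Random 128 px crops are augmented with
flips, 90° rotations, scaling, Gaussian blur (image only) and
barrel/pincushion distortion, the identical spatial transform applied to
patch and mask.

**Cell detection** regresses a *distance-regularised proximity map*: the
target is 1 at each annotated centroid, decays linearly to 0 at
`proximity_radius_px` (default 6 px ≈ one nucleus radius at 0.5 µm/px) and
combines overlapping cells by pixelwise maximum. The network is a
three-level dense-inception encoder–decoder: each encoder level
concatenates its input with the output of a two-path (1×1, 3×3) inception
block, levels are connected by average pooling, and the decoder
concatenates transpose-convolution upsamplings with the encoder stacks.
Training minimises a weighted squared error on the sigmoid map, with weight
`1 + pos_weight * target` (default `pos_weight = 9`) so the sparse peaks
dominate. The batch Hausdorff agreement metric
$1 / (1 + \tfrac1B \sum_j |HD_P^j - HD_g^j|)$ — where $HD_P$, $HD_g$ are
the two directed Hausdorff distances between predicted and true centroid
sets — is computed on every validation epoch and reported verbatim; it is
1 exactly when the two directed distances agree on every image. Because it
is maximal at agreement, non-differentiable through the detection
threshold, and blind to detections that happen to balance the two directed
distances, it is reported as a monitoring metric while *model selection*
uses the mean symmetric Hausdorff $\max(HD_P, HD_g)$, and the training
objective is the differentiable proximity regression. An empty prediction
set is scored with the patch diagonal, keeping the metric finite. Centroids
are read off the probability map by thresholding at 0.8, labelling
8-connected components and taking each component's centre of mass;
single-pixel components are kept (small nuclei).

**Tissue segmentation** runs at the ×1.25-equivalent working resolution
(`target_mpp = 8`): a plain depth-4 encoder–decoder with skip connections.
Two choices matter here. Normalisation uses *dataset-level* channel
statistics stored in the model, not per-tile standardisation: a uniform
white tile and a uniform stroma tile must map to different inputs, which
per-tile standardisation destroys. For the same reason the tissue net uses
no per-channel instance normalisation internally — absolute stain level is
the signal. The Otsu baseline (`thresholdBaseline()`) thresholds
`max(saturation, 1 - value)`, scoring white near 0 and any stained or dark
region high; it is retained purely as the comparison baseline.

**Cell classification** happens at detected centroids with a small patch
CNN (28×28 px context) under neighbouring-ensemble prediction: the softmax
posteriors of the centre patch and K = 8 patches on a 6 px ring are
averaged, and the class is the argmax with ties broken deterministically
towards the earlier class in the model's class order (H&E:
epithelial < stromal < lymphocyte). Training samples classes in balance
each epoch and jitters each training patch uniformly within the ensemble
ring radius, so the network is trained on exactly the off-centre views the
ensemble averages over — without the jitter, isolated nuclei are
systematically diluted by their off-centre members. All detections are
classified; no detection-score gate is applied.

## The synthetic-histology generator

`generateTile()` emulates the geometry the pipeline cares about, not
photorealism: non-overlapping elliptical ducts (rejection-sampled, ≤ 1000
attempts, explicit error on failure) rendered as a light purple wash with
a darker myoepithelial rim; epithelial nuclei only inside ducts (or inside
an optional "invasive blob" for testing the exclusion stage); elongated
pink stromal nuclei and small dark round lymphocytes over a noisy pink
stroma, finished with additive noise and a mild blur. Lymphocyte placement
is the controllable variable: *colocalised* draws them within
`colocalisation_band_px` of a duct boundary, *dispersed* uniformly over
the stroma, *excluded* at more than twice the band from any duct.
`renderIhcTile()` renders the same geometry in an IHC palette with a
chosen stain-positive fraction. The reference tile conditions are 256×256
px at 0.5 µm/px, five ducts of 18–36 px semi-axis with 15–40 epithelial
nuclei each, stromal and lymphocyte densities of 1500 and 800 cells/mm²
and a 20 px band; cohort-level experiments use a larger 384 px frame at
1 µm/px with eight ducts and matched densities across placement modes, so
that a slide comfortably clears the 5-duct validity floor and carries
~100 lymphocytes. Everything is drawn under a single seed: the same spec
and seed reproduce byte-identical rasters and tables, and cohort seeds are
`base seed + slide index`.

What the generator deliberately does not model: stain variability,
scanner artefacts beyond noise/blur, overlapping nuclei, 3-D duct
structure, or realistic chromatin texture. Class separation is by design
learnable by small networks in minutes on a CPU. Green tests therefore
demonstrate that the *implementations* are correct and that the pipeline
recovers designed spatial structure — they do not certify performance on
real slides, where the originals of these architectures required
GPU-scale training on expert annotations.

## Numerical choices and degenerate inputs

* Coordinates are 0-based, `x` = column, `y` = row, origin top-left,
  pixel centres at integers — fixed package-wide; micron coordinates are
  `px * mpp`.
* Componentisation is 8-connected (diagonally touching components are one
  duct), implemented as a two-pass union-find in C++.
* Probability thresholds: 0.5 for duct maps, 0.8 for cell maps; both
  configurable and echoed into outputs.
* Empty mask → uniform unit weight map; empty centroid list → zero
  proximity raster; empty cell list → lymphocyte% is an explicit error;
  zero class totals → Morisita–Horn is an explicit error, reported as a
  missing value at slide level.
* Undefined ratios in the evaluation panel (zero denominators) are
  reported `NA`, never 0.
* Ratios at boundaries: a duct with exactly 10 epithelial cells is kept; a
  slide with exactly 5 kept ducts is valid; Cohen's d bands are
  small ≤ 0.2 < medium ≤ 0.5 < large, evaluated on |d|.
* Determinism: every training loop and the generator run under explicit
  seeds and restore the caller's RNG state; repeated runs are
  bit-identical.

## Scaled-down benchmarks

The test suite trains every network at desk scale (single CPU, minutes):
duct segmentation on 80 synthetic 256 px tiles for 6 epochs of 128 px
crops, evaluated on 20 held-out tiles against a mean DICE floor of 0.6
(the conventional good-agreement bar for segmentation overlap); cell
detection on 40 tiles against an F1 floor of 0.8 at 6 px matching radius
on 10 held-out tiles; the classifier against 0.85 balanced accuracy; the
tissue net against 0.8 held-out DICE; and the structure-recovery
experiment compares 20 colocalised against 20 dispersed synthetic slides
(matched seeds and densities) with a rank-sum test and Cohen's d. These
problem sizes are the package's chosen benchmark conditions; the same
duct-segmentation benchmark is what `scripts/acceptance.R` re-runs.

## Known limitations

Single-threaded CPU training bounds practical network width; the provided
widths are deliberately small. The Voronoi stage assumes a convex clip
region, so ducts adjacent to a concave tissue boundary can be clipped
against it (mirroring the convex-polygon behaviour of the method it
implements). The invasive compartment is a disc union, not a learned
region. The IHC path shares the H&E detection machinery and was not tuned
separately. Whole-slide pyramidal I/O is out of scope: the unit of work is
the pre-extracted tile.
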