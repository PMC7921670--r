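# ductscape

Immune microecology of ductal carcinoma in situ (DCIS) from histology
tiles: duct segmentation, single-cell detection and classification, and a
slide-level **DCIS immune colocalisation score** built on Voronoi
tessellation of duct centroids and the Morisita–Horn index — together with
a seeded synthetic-histology generator that makes the entire pipeline
testable without external data.

## Who this is for

Computational pathology researchers who want a self-contained, desk-scale
(single CPU, minutes) implementation of the duct-centric TIL analysis
chain: for studying the spatial statistic itself, for benchmarking against
exact synthetic ground truth, or as a reference implementation of the
stage contracts (tile → tissue mask → duct polygons → cell table →
colocalisation score).

## The score

Duct centroids $C_k$ (in the ×1.25 working frame) seed a Voronoi
tessellation: region $R_k = \{x : d(x, C_k) \le d(x, C_j)\ \forall j \ne
k\}$, so every lymphocyte is attributed to its nearest duct. Regions are
cut by a 200 µm quadrat grid into units $i$; with per-unit lymphocyte and
in-situ-epithelial fractions $p_i^l, p_i^e$,

$$\text{score} = \frac{2\sum_i p_i^l p_i^e}{\sum_i (p_i^l)^2 + \sum_i (p_i^e)^2} \in [0,1].$$

High = lymphocytes colocalise with ducts; low = TILs avoid ducts or
cluster around a few. Ducts with < 10 epithelial cells are dropped; slides
with < 5 kept ducts are invalid; epithelial cells outside ducts define an
excluded invasive compartment (50 µm disc union).

The imaging stages are three small CPU-trainable convolutional networks
(an inception-block encoder–decoder with multi-resolution inputs and a
boundary-weighted multi-output loss for ducts; a dense-inception
proximity-map regressor with Hausdorff monitoring for cells; a compact
encoder–decoder for tissue), implemented from scratch on an
RcppArmadillo backend with gradient-checked autodiff. See the methods
vignette (`vignettes/duct-immune-microecology.Rmd`) for the models,
parameters and design decisions.

## Worked example

Generate two synthetic slides that differ only in lymphocyte placement,
run the spatial stage on exact ground truth, and compare scores:

```r
library(ductscape)

spec <- function(mode) syntheticSpec(
  tile_height_px = 384L, tile_width_px = 384L, mpp = 1.0, n_ducts = 8L,
  duct_radius_px_range = c(18, 30), epithelial_per_duct_range = c(15, 30),
  stromal_density = 800, lymphocyte_density = 700,
  placement_mode = mode, colocalisation_band_px = 20, seed = 101L)

score_of <- function(mode) {
  tt <- generateTile(spec(mode))
  ducts <- filterDucts(segmentDucts((tt$truth@ductMask > 0) * 1, mpp = 1.0),
                       tt$truth@cells)
  slideColocalisation(ducts, tt$truth@cells, mpp = 1.0)
}

score_of("colocalised")
#> DCIS immune colocalisation score: 0.9151 (valid; 8 ducts, 18 units, grid 200 um)
score_of("dispersed")
#> DCIS immune colocalisation score: 0.8379 (valid; 8 ducts, 21 units, grid 200 um)
```

The colocalised slide — lymphocytes drawn within 20 px of duct boundaries
— scores markedly higher than the dispersed slide with identical ducts and
densities: the score recovers the designed spatial structure. Over 20
matched seed pairs the separation is large (rank-sum p < 1e-5, Cohen's
d > 1.5; see `tests/testthat/test-acceptance.R`).

To train the networks instead of using ground truth:

```r
data  <- lapply(1:80, function(i) generateTile(syntheticSpec(seed = i)))
model <- trainImnet(lapply(data, `[[`, "tile"),
                    lapply(data, function(d) d$truth@ductMask > 0),
                    imnetConfig(epochs = 6L, crop_px = 128L, seed = 1L))
prob  <- predictDuctProbability(model, data[[1]]$tile)  # duct probability map
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/ductscape` (subcommands `simulate`, `tissue`, `ducts`, `cells`,
`classify`, `spatial`).

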