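# Shared fixtures, generated in code and memoised for the test session.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, make) {
  if (is.null(.fx[[key]])) .fx[[key]] <- make()
  .fx[[key]]
}

# a small fast tile: 128 px, two ducts
small_spec <- function(seed, ...) {
  args <- list(tile_height_px = 128L, tile_width_px = 128L, n_ducts = 2L,
               duct_radius_px_range = c(12, 20),
               epithelial_per_duct_range = c(12, 25), seed = seed)
  do.call(syntheticSpec, utils::modifyList(args, list(...)))
}

fx_small_tile <- function(seed = 1L) {
  fx_memo(paste0("small", seed), function() generateTile(small_spec(seed)))
}

# a hand-built slide: k square ducts with a chosen number of epithelial
# cells each, plus lymphocytes/stroma -- used for exact filter-rule tests
make_duct_grid <- function(k, per_duct = 12L, n_lymph = 40L, size = 300L) {
  mask <- matrix(0L, size, size)
  cells <- list()
  centres <- list()
  side <- 30L
  per_row <- max(1L, (size - 40L) %/% 55L)
  for (i in seq_len(k)) {
    r0 <- 20L + 55L * ((i - 1L) %/% per_row)
    c0 <- 20L + 55L * ((i - 1L) %% per_row)
    mask[r0:(r0 + side), c0:(c0 + side)] <- i
    centres[[i]] <- c(c0 + side / 2, r0 + side / 2)
    if (per_duct > 0) {
      xs <- c0 + 2 + (seq_len(per_duct) * 7) %% (side - 4)
      ys <- r0 + 2 + (seq_len(per_duct) * 11) %% (side - 4)
      cells[[length(cells) + 1L]] <- data.frame(
        x_px = xs, y_px = ys, class = "epithelial", duct = i)
    }
  }
  set.seed(99L)
  cells[[length(cells) + 1L]] <- data.frame(
    x_px = runif(n_lymph, 0, size - 1), y_px = runif(n_lymph, 0, size - 1),
    class = "lymphocyte", duct = NA_integer_)
  list(mask = mask, cells = do.call(rbind, cells),
       centres = do.call(rbind, centres))
}

# slide-scale generator conditions used by the structure-recovery
# experiments (larger frame, matched densities across placement modes)
slide_spec <- function(mode, seed) {
  syntheticSpec(tile_height_px = 384L, tile_width_px = 384L, mpp = 1.0,
                n_ducts = 8L, duct_radius_px_range = c(18, 30),
                epithelial_per_duct_range = c(15, 30),
                stromal_density = 800, lymphocyte_density = 700,
                placement_mode = mode, colocalisation_band_px = 20,
                seed = seed)
}

slide_score <- function(mode, seed) {
  tt <- generateTile(slide_spec(mode, seed))
  ds <- segmentDucts((tt$truth@ductMask > 0) * 1, mpp = 1.0)
  ds <- filterDucts(ds, tt$truth@cells)
  slideColocalisation(ds, tt$truth@cells, 1.0)
}

# numerical gradient of f at p (small problems only)
num_grad <- function(f, p, eps = 1e-6) {
  g <- p * 0
  for (i in seq_along(p)) {
    p1 <- p; p1[i] <- p1[i] + eps
    p2 <- p; p2[i] <- p2[i] - eps
    g[i] <- (f(p1) - f(p2)) / (2 * eps)
  }
  g
}
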