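# Seeded synthetic-histology generator. Emulates H&E-like tiles containing
# elliptical DCIS ducts filled with epithelial nuclei, scattered stromal
# nuclei, and lymphocytes whose placement relative to ducts is controllable,
# plus IHC-like tiles with stain-positive nuclei. Every tile carries exact
# ground truth (duct label mask + cell table), so all downstream stages are
# testable without external data.

#' Specification of one synthetic tile
#'
#' Captures the study conditions a tile is generated under: geometry, cell
#' densities and the lymphocyte placement mode. The same spec + seed always
#' reproduces byte-identical rasters and tables.
#'
#' @slot tileHeightPx,tileWidthPx tile size in pixels.
#' @slot mpp microns per pixel.
#' @slot nDucts number of ducts to place (non-overlapping ellipses).
#' @slot ductRadiusPxRange `(min, max)` semi-axis range in pixels.
#' @slot epithelialPerDuctRange `(min, max)` epithelial nuclei per duct.
#' @slot stromalDensity,lymphocyteDensity cells per mm^2.
#' @slot placementMode one of `"colocalised"`, `"dispersed"`, `"excluded"`.
#' @slot colocalisationBandPx ring width (px) around duct boundaries used by
#'   the colocalised mode; the excluded mode keeps lymphocytes further than
#'   twice this from any duct.
#' @slot ihcPositiveFraction fraction of lymphocytes rendered stain-positive
#'   on IHC-like tiles.
#' @slot invasiveBlob whether to add an extra epithelial blob outside any
#'   duct (an "invasive" compartment for testing the exclusion stage).
#' @slot invasiveCellCount epithelial nuclei in the invasive blob.
#' @slot seed RNG seed.
#' @export
setClass("SyntheticSpec", representation(
  tileHeightPx = "integer", tileWidthPx = "integer", mpp = "numeric",
  nDucts = "integer", ductRadiusPxRange = "numeric",
  epithelialPerDuctRange = "numeric", stromalDensity = "numeric",
  lymphocyteDensity = "numeric", placementMode = "character",
  colocalisationBandPx = "numeric", ihcPositiveFraction = "numeric",
  invasiveBlob = "logical", invasiveCellCount = "integer", seed = "integer"),
  validity = function(object) {
    if (object@tileHeightPx < 32 || object@tileWidthPx < 32)
      return("tile must be at least 32 x 32 px")
    if (object@mpp <= 0) return("mpp must be > 0")
    if (object@nDucts < 0) return("nDucts must be >= 0")
    if (diff(object@ductRadiusPxRange) < 0)
      return("ductRadiusPxRange must be (min, max) with min <= max")
    if (diff(object@epithelialPerDuctRange) < 0)
      return("epithelialPerDuctRange must be (min, max) with min <= max")
    if (object@stromalDensity < 0 || object@lymphocyteDensity < 0)
      return("densities must be >= 0")
    if (!object@placementMode %in% c("colocalised", "dispersed", "excluded"))
      return("placementMode must be colocalised/dispersed/excluded")
    if (object@ihcPositiveFraction < 0 || object@ihcPositiveFraction > 1)
      return("ihcPositiveFraction must lie in [0, 1]")
    TRUE
  })

#' Construct a SyntheticSpec
#'
#' Defaults are the package's reference tile conditions: a 256 x 256 px tile
#' at 0.5 um/px carrying five ducts of 18-36 px semi-axis, 15-40 epithelial
#' nuclei per duct, stromal and lymphocyte densities of 1500 and 800 cells
#' per mm^2, and a 20 px colocalisation band.
#'
#' @param tile_height_px,tile_width_px tile size in pixels.
#' @param mpp microns per pixel.
#' @param n_ducts number of non-overlapping elliptical ducts.
#' @param duct_radius_px_range `(min, max)` duct semi-axis in px.
#' @param epithelial_per_duct_range `(min, max)` epithelial nuclei per duct.
#' @param stromal_density,lymphocyte_density cells per mm^2.
#' @param placement_mode `"colocalised"`, `"dispersed"` or `"excluded"`.
#' @param colocalisation_band_px ring width in px around duct boundaries.
#' @param ihc_positive_fraction fraction of stain-positive lymphocytes.
#' @param invasive_blob add an extra-ductal epithelial blob.
#' @param invasive_cell_count epithelial nuclei in that blob.
#' @param seed RNG seed.
#' @return A validated [SyntheticSpec-class].
#' @export
syntheticSpec <- function(tile_height_px = 256L, tile_width_px = 256L,
                          mpp = 0.5, n_ducts = 5L,
                          duct_radius_px_range = c(18, 36),
                          epithelial_per_duct_range = c(15, 40),
                          stromal_density = 1500, lymphocyte_density = 800,
                          placement_mode = "dispersed",
                          colocalisation_band_px = 20,
                          ihc_positive_fraction = 0.5,
                          invasive_blob = FALSE, invasive_cell_count = 50L,
                          seed = 1L) {
  new("SyntheticSpec", tileHeightPx = as.integer(tile_height_px),
      tileWidthPx = as.integer(tile_width_px), mpp = mpp,
      nDucts = as.integer(n_ducts),
      ductRadiusPxRange = as.numeric(duct_radius_px_range),
      epithelialPerDuctRange = as.numeric(epithelial_per_duct_range),
      stromalDensity = stromal_density,
      lymphocyteDensity = lymphocyte_density,
      placementMode = placement_mode,
      colocalisationBandPx = colocalisation_band_px,
      ihcPositiveFraction = ihc_positive_fraction,
      invasiveBlob = invasive_blob,
      invasiveCellCount = as.integer(invasive_cell_count),
      seed = as.integer(seed))
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# H&E-ish palette (RGB in [0,1])
.pal_he <- list(
  stroma = c(0.91, 0.77, 0.83),
  duct_wash = c(0.82, 0.72, 0.86),
  duct_rim = c(0.58, 0.46, 0.68),
  epithelial = c(0.38, 0.26, 0.56),
  stromal_cell = c(0.72, 0.44, 0.58),
  lymphocyte = c(0.22, 0.21, 0.50))

.pal_ihc <- list(
  stroma = c(0.93, 0.90, 0.87),
  duct_wash = c(0.88, 0.86, 0.84),
  duct_rim = c(0.72, 0.70, 0.72),
  epithelial = c(0.62, 0.64, 0.74),
  stromal_cell = c(0.78, 0.72, 0.70),
  lymphocyte_pos = c(0.48, 0.28, 0.10),
  lymphocyte_neg = c(0.30, 0.34, 0.62))

# paint a filled ellipse (continuous centre, 0-based coords) onto raster
# channels; returns modified raster. mask_env, if given, also records label.
paint_ellipse <- function(img, cx, cy, a, b, theta, col, label = NULL,
                          labmat = NULL) {
  H <- dim(img)[1]; W <- dim(img)[2]
  r0 <- max(1L, floor(cy - max(a, b)) + 1L)
  r1 <- min(H, ceiling(cy + max(a, b)) + 1L)
  c0 <- max(1L, floor(cx - max(a, b)) + 1L)
  c1 <- min(W, ceiling(cx + max(a, b)) + 1L)
  if (r0 > r1 || c0 > c1) return(list(img = img, lab = labmat, n = 0L))
  rows <- r0:r1; cols <- c0:c1
  dy <- rows - 1 - cy
  dx <- cols - 1 - cx
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dy, dx, function(yy, xx) (xx * ct + yy * st) / a)
  v <- outer(dy, dx, function(yy, xx) (-xx * st + yy * ct) / b)
  inside <- u^2 + v^2 <= 1
  for (ch in 1:3) {
    plane <- img[rows, cols, ch]
    plane[inside] <- col[ch]
    img[rows, cols, ch] <- plane
  }
  if (!is.null(labmat)) {
    sub <- labmat[rows, cols]
    sub[inside] <- label
    labmat[rows, cols] <- sub
  }
  list(img = img, lab = labmat, n = sum(inside))
}

# rejection-sample non-overlapping duct ellipses; error if impossible
place_ducts <- function(spec, max_attempts = 1000L) {
  n <- spec@nDucts
  if (n == 0) return(data.frame())
  H <- spec@tileHeightPx; W <- spec@tileWidthPx
  rng <- spec@ductRadiusPxRange
  out <- data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                    b = numeric(0), theta = numeric(0))
  for (k in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      a <- stats::runif(1, rng[1], rng[2])
      b <- stats::runif(1, rng[1], rng[2])
      theta <- stats::runif(1, 0, pi)
      rmax <- max(a, b)
      cx <- stats::runif(1, rmax + 2, W - 1 - rmax - 2)
      cy <- stats::runif(1, rmax + 2, H - 1 - rmax - 2)
      ok <- TRUE
      if (nrow(out)) {
        dd <- sqrt((out$cx - cx)^2 + (out$cy - cy)^2)
        ok <- all(dd > pmax(out$a, out$b) + rmax + 4)
      }
      if (ok) {
        out <- rbind(out, data.frame(cx = cx, cy = cy, a = a, b = b,
                                     theta = theta))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("cannot place %d ducts of radius %g-%g in a %d x %d tile",
                   n, rng[1], rng[2], H, W))
  }
  out
}

# sample points inside an ellipse with a minimum pairwise spacing
sample_in_ellipse <- function(duct, n, spacing = 5, max_attempts = 60L) {
  pts <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    for (att in seq_len(max_attempts)) {
      r <- sqrt(stats::runif(1)); phi <- stats::runif(1, 0, 2 * pi)
      u <- r * cos(phi) * duct$a * 0.92
      v <- r * sin(phi) * duct$b * 0.92
      x <- duct$cx + u * cos(duct$theta) - v * sin(duct$theta)
      y <- duct$cy + u * sin(duct$theta) + v * cos(duct$theta)
      if (!nrow(pts) ||
          min((pts[, 1] - x)^2 + (pts[, 2] - y)^2) > spacing^2) {
        pts <- rbind(pts, c(x, y))
        break
      }
    }
  }
  pts
}

# uniform samples over the tile restricted by a logical matrix of allowed px
sample_where <- function(allowed, n) {
  idx <- which(allowed)
  if (!length(idx) || n == 0) return(matrix(numeric(0), 0, 2))
  pick <- sample(idx, n, replace = TRUE)
  H <- nrow(allowed)
  r <- ((pick - 1) %% H) + 1
  c <- ((pick - 1) %/% H) + 1
  jit <- matrix(stats::runif(2 * n, -0.5, 0.5), n, 2)
  cbind(x = c - 1 + jit[, 1], y = r - 1 + jit[, 2])
}

generate_tile_impl <- function(spec, ihc = FALSE) {
  H <- spec@tileHeightPx; W <- spec@tileWidthPx
  pal <- if (ihc) .pal_ihc else .pal_he
  with_seed(spec@seed, {
    img <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) img[, , ch] <- pal$stroma[ch]
    lab <- matrix(0L, H, W)
    ducts <- place_ducts(spec)
    # duct interior wash + myoepithelial rim, label mask records interiors
    for (k in seq_len(nrow(ducts))) {
      d <- ducts[k, ]
      r <- paint_ellipse(img, d$cx, d$cy, d$a + 2, d$b + 2, d$theta,
                         pal$duct_rim, label = as.integer(k), labmat = lab)
      img <- r$img; lab <- r$lab
      r <- paint_ellipse(img, d$cx, d$cy, d$a, d$b, d$theta, pal$duct_wash,
                         label = as.integer(k), labmat = lab)
      img <- r$img; lab <- r$lab
    }
    area_mm2 <- H * W * spec@mpp^2 / 1e6
    cells <- list()
    # epithelial nuclei inside ducts
    for (k in seq_len(nrow(ducts))) {
      d <- ducts[k, ]
      n_epi <- round(stats::runif(1, spec@epithelialPerDuctRange[1],
                                  spec@epithelialPerDuctRange[2]))
      pts <- sample_in_ellipse(d, n_epi)
      if (nrow(pts))
        cells[[length(cells) + 1L]] <- data.frame(
          x_px = pts[, 1], y_px = pts[, 2], class = "epithelial",
          duct = as.integer(k))
    }
    # optional invasive blob: epithelial nuclei outside any duct
    if (spec@invasiveBlob) {
      blob <- place_blob(spec, ducts)
      pts <- sample_in_ellipse(blob, spec@invasiveCellCount)
      if (nrow(pts))
        cells[[length(cells) + 1L]] <- data.frame(
          x_px = pts[, 1], y_px = pts[, 2], class = "epithelial",
          duct = NA_integer_)
    }
    in_duct <- lab > 0
    # distance (px) of every background pixel to the nearest duct pixel
    dmap <- if (any(in_duct)) {
      as.matrix(EBImage::distmap(matrix(as.numeric(!in_duct), H, W)))
    } else matrix(Inf, H, W)
    n_str <- stats::rpois(1, spec@stromalDensity * area_mm2)
    pts <- sample_where(!in_duct, n_str)
    if (nrow(pts))
      cells[[length(cells) + 1L]] <- data.frame(
        x_px = pts[, 1], y_px = pts[, 2], class = "stromal",
        duct = NA_integer_)
    n_lym <- stats::rpois(1, spec@lymphocyteDensity * area_mm2)
    band <- spec@colocalisationBandPx
    allowed <- switch(spec@placementMode,
      colocalised = if (any(in_duct)) {
        !in_duct & dmap <= band
      } else !in_duct,
      dispersed = !in_duct,
      excluded = !in_duct & dmap > 2 * band)
    if (!any(allowed)) allowed <- !in_duct
    pts <- sample_where(allowed, n_lym)
    lclass <- if (ihc) {
      ifelse(stats::runif(nrow(pts)) < spec@ihcPositiveFraction,
             "lymphocyte_pos", "lymphocyte_neg")
    } else rep("lymphocyte", nrow(pts))
    if (nrow(pts))
      cells[[length(cells) + 1L]] <- data.frame(
        x_px = pts[, 1], y_px = pts[, 2], class = lclass, duct = NA_integer_)
    cells <- if (length(cells)) do.call(rbind, cells) else
      data.frame(x_px = numeric(0), y_px = numeric(0),
                 class = character(0), duct = integer(0))
    # render nuclei (drawn after ducts so they sit on the wash)
    for (i in seq_len(nrow(cells))) {
      cl <- cells$class[i]
      col <- switch(cl, epithelial = pal$epithelial,
                    stromal = pal$stromal_cell,
                    lymphocyte = pal$lymphocyte,
                    lymphocyte_pos = pal$lymphocyte_pos,
                    lymphocyte_neg = pal$lymphocyte_neg)
      geom <- switch(cl,
        epithelial = c(stats::runif(1, 2.6, 3.4), stats::runif(1, 2.2, 3.0)),
        stromal = c(stats::runif(1, 3.2, 4.2), stats::runif(1, 1.0, 1.5)),
        c(stats::runif(1, 1.9, 2.4), stats::runif(1, 1.9, 2.4)))
      th <- stats::runif(1, 0, pi)
      img <- paint_ellipse(img, cells$x_px[i], cells$y_px[i], geom[1],
                           geom[2], th, col)$img
    }
    # additive texture noise + mild blur emulate scanner softness
    img <- img + array(stats::rnorm(H * W * 3, sd = 0.015), dim = dim(img))
    for (ch in 1:3)
      img[, , ch] <- as.matrix(EBImage::gblur(img[, , ch], sigma = 0.6))
    img <- pmin(pmax(img, 0), 1)
    dim(img) <- c(H, W, 3)
    list(tile = HistoTile(img, spec@mpp),
         truth = new("TileTruth", ductMask = lab, cells = cells,
                     placementMode = spec@placementMode))
  })
}

# an ellipse outside every duct, for the invasive compartment
place_blob <- function(spec, ducts, max_attempts = 1000L) {
  H <- spec@tileHeightPx; W <- spec@tileWidthPx
  a <- max(24, 0.12 * W); b <- max(20, 0.1 * H)
  for (att in seq_len(max_attempts)) {
    cx <- stats::runif(1, a + 2, W - 1 - a - 2)
    cy <- stats::runif(1, b + 2, H - 1 - b - 2)
    ok <- TRUE
    if (nrow(ducts)) {
      dd <- sqrt((ducts$cx - cx)^2 + (ducts$cy - cy)^2)
      ok <- all(dd > pmax(ducts$a, ducts$b) + max(a, b) + 4)
    }
    if (ok) return(data.frame(cx = cx, cy = cy, a = a, b = b, theta = 0))
  }
  stop("cannot place invasive blob clear of ducts")
}

#' Generate one synthetic H&E-like tile with exact ground truth
#'
#' Ducts are non-overlapping filled ellipses (rejection-sampled, at most
#' 1000 attempts per duct) rendered as a light purple wash with a darker
#' myoepithelial rim; epithelial nuclei lie only inside ducts (or inside the
#' optional invasive blob), stromal nuclei are scattered over the stroma and
#' lymphocyte placement follows `placement_mode`: colocalised lymphocytes sit
#' within `colocalisation_band_px` of a duct boundary, dispersed ones are
#' uniform over the stroma, excluded ones keep a distance of more than twice
#' the band from any duct.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with elements `tile` ([HistoTile-class]) and `truth`
#'   ([TileTruth-class]).
#' @examples
#' tt <- generateTile(syntheticSpec(n_ducts = 2L, seed = 7L))
#' max(tt$truth@ductMask)
#' @export
generateTile <- function(spec) generate_tile_impl(spec, ihc = FALSE)

#' Generate one synthetic IHC-like tile
#'
#' Same geometry model as [generateTile()], but rendered with an IHC palette:
#' a fraction `ihc_positive_fraction` of lymphocytes is drawn brown
#' (stain-positive), the rest blue (stain-negative), and the ground-truth
#' table records classes `lymphocyte_pos` / `lymphocyte_neg`.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with `tile` and `truth` as in [generateTile()].
#' @export
renderIhcTile <- function(spec) generate_tile_impl(spec, ihc = TRUE)

#' Write a cohort of synthetic slides to disk
#'
#' Writes, per slide, the tile (8-bit RGB PNG), the duct label mask (16-bit
#' single-channel TIFF), the cell table (CSV with columns
#' `x_px,y_px,class,duct`) and a JSON manifest listing per-slide mode and
#' seed. Seeds are `base spec seed + slide index`, so regeneration from the
#' same manifest is byte-identical.
#'
#' @param n_per_mode slides per placement mode.
#' @param base_spec a [SyntheticSpec-class]; its seed is the cohort base seed.
#' @param out_dir output directory (created if missing).
#' @param modes placement modes to generate.
#' @param ihc generate IHC-like tiles instead of H&E-like.
#' @return the manifest as a data.frame (invisibly also written as JSON).
#' @export
generateCohort <- function(n_per_mode, base_spec, out_dir,
                           modes = c("colocalised", "dispersed"),
                           ihc = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(slide = character(0), mode = character(0),
                         seed = integer(0), tile = character(0),
                         mask = character(0), cells = character(0))
  idx <- 0L
  for (mode in modes) {
    for (i in seq_len(n_per_mode)) {
      idx <- idx + 1L
      seed <- base_spec@seed + idx
      spec <- base_spec
      spec@placementMode <- mode
      spec@seed <- seed
      validObject(spec)
      tt <- generate_tile_impl(spec, ihc = ihc)
      id <- sprintf("slide_%03d_%s", idx, mode)
      tile_f <- file.path(out_dir, paste0(id, ".png"))
      mask_f <- file.path(out_dir, paste0(id, "_mask.tif"))
      cells_f <- file.path(out_dir, paste0(id, "_cells.csv"))
      writeTilePng(tt$tile, tile_f)
      writeLabelMaskTiff(tt$truth@ductMask, mask_f)
      utils::write.csv(tt$truth@cells, cells_f, row.names = FALSE)
      manifest <- rbind(manifest, data.frame(
        slide = id, mode = mode, seed = seed, tile = basename(tile_f),
        mask = basename(mask_f), cells = basename(cells_f)))
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  manifest
}

#' Generate a synthetic tissue-segmentation fixture
#'
#' Renders a full-resolution tile with [generateTile()], replaces part of it
#' with white slide background, and downsamples both tile and tissue mask to
#' the low-resolution working frame (`target_mpp`, the x1.25-equivalent) --
#' the domain the tissue segmentation stage operates in.
#'
#' @param spec a [SyntheticSpec-class] at full resolution.
#' @param pattern `"half"` (white half-plane with random orientation),
#'   `"disc"` (white disc), `"none"` (all tissue) or `"all_background"`.
#' @param target_mpp microns per pixel of the returned working-frame tile
#'   (default 8).
#' @return list with `tile` ([HistoTile-class] at `target_mpp`) and `mask`
#'   (logical tissue matrix in the same frame).
#' @export
generateTissueTile <- function(spec, pattern = c("half", "disc", "none",
                                                 "all_background"),
                               target_mpp = 8) {
  pattern <- match.arg(pattern)
  tt <- generateTile(spec)
  img <- tilePixels(tt$tile)
  H <- dim(img)[1]; W <- dim(img)[2]
  bg <- with_seed(spec@seed + 99L, {
    gy <- matrix(rep(0:(H - 1), W), H, W)
    gx <- matrix(rep(0:(W - 1), each = H), H, W)
    b <- switch(pattern,
      half = {
        th <- stats::runif(1, 0, 2 * pi)
        off <- stats::runif(1, -0.2, 0.2)
        cos(th) * (gx / W - 0.5) + sin(th) * (gy / H - 0.5) > off
      },
      disc = {
        cx <- stats::runif(1, 0.25, 0.75) * W
        cy <- stats::runif(1, 0.25, 0.75) * H
        r <- stats::runif(1, 0.2, 0.35) * min(H, W)
        (gx - cx)^2 + (gy - cy)^2 <= r^2
      },
      none = matrix(FALSE, H, W),
      all_background = matrix(TRUE, H, W))
    b
  })
  noise <- with_seed(spec@seed + 101L,
                     matrix(stats::rnorm(H * W, 0.97, 0.008), H, W))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[bg] <- pmin(pmax(noise[bg], 0.9), 1)
    img[, , ch] <- plane
  }
  f <- spec@mpp / target_mpp
  h2 <- max(8L, round(H * f)); w2 <- max(8L, round(W * f))
  small <- as.array(EBImage::resize(EBImage::Image(img, colormode = "Color"),
                                    w = h2, h = w2))
  dim(small) <- c(h2, w2, 3)
  small <- pmin(pmax(small, 0), 1)
  mlow <- as.matrix(EBImage::resize(EBImage::Image((!bg) * 1),
                                    w = h2, h = w2)) > 0.5
  list(tile = HistoTile(small, target_mpp), mask = mlow)
}

#' Tile and mask I/O
#'
#' Tiles are 8-bit RGB PNG; duct label masks are 16-bit single-channel TIFF
#' (integer labels, 0 = background).
#'
#' @param tile a [HistoTile-class]; `mpp` is stored separately by callers.
#' @param path file path.
#' @export
writeTilePng <- function(tile, path) {
  px <- aperm(tilePixels(tile), c(1, 2, 3))
  png::writePNG(px, path)
  invisible(path)
}

#' @rdname writeTilePng
#' @param mpp microns per pixel to attach on read.
#' @export
readTilePng <- function(path, mpp) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  HistoTile(px[, , 1:3, drop = FALSE], mpp)
}

#' @rdname writeTilePng
#' @param mask integer label matrix.
#' @export
writeLabelMaskTiff <- function(mask, path) {
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname writeTilePng
#' @export
readLabelMaskTiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
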