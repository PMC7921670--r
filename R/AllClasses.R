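#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib ductscape, .registration = TRUE
NULL

#' Histology tile with resolution metadata
#'
#' The unit all networks consume: an RGB pixel raster in `[0, 1]` together
#' with its microns-per-pixel resolution. Coordinates throughout the package
#' are 0-based with `x` = column, `y` = row, origin at the top-left corner
#' and pixel centres at integers.
#'
#' @slot pixels numeric array `(height, width, 3)` with values in `[0, 1]`.
#' @slot mpp microns per pixel (scalar, > 0).
#' @export
setClass("HistoTile", representation(pixels = "array", mpp = "numeric"),
         validity = function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3 || d[3] != 3) return("pixels must be (H, W, 3)")
  if (length(object@mpp) != 1 || object@mpp <= 0) return("mpp must be > 0")
  rng <- range(object@pixels)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) return("pixels must lie in [0, 1]")
  TRUE
})

#' Construct a HistoTile
#' @param pixels numeric array `(H, W, 3)` in `[0, 1]`.
#' @param mpp microns per pixel.
#' @return A [HistoTile-class] object.
#' @export
HistoTile <- function(pixels, mpp) new("HistoTile", pixels = pixels, mpp = mpp)

#' Ground truth attached to a synthetic tile
#'
#' @slot ductMask integer matrix; 0 = background, k = duct k (labels are
#'   contiguous `1..n_ducts`).
#' @slot cells data.frame with columns `x_px`, `y_px` (0-based pixel
#'   coordinates), `class` and `duct` (duct label for intraductal epithelial
#'   nuclei, `NA` otherwise).
#' @slot placementMode lymphocyte placement mode used by the generator.
#' @export
setClass("TileTruth", representation(ductMask = "matrix", cells = "data.frame",
                                     placementMode = "character"),
         validity = function(object) {
  lev <- sort(unique(as.vector(object@ductMask)))
  lev <- lev[lev > 0]
  if (length(lev) && !identical(as.integer(lev), seq_along(lev)))
    return("duct labels must be contiguous 1..n")
  need <- c("x_px", "y_px", "class")
  if (!all(need %in% names(object@cells)))
    return("cells needs columns x_px, y_px, class")
  TRUE
})

#' A set of segmented ducts on one tile
#'
#' One row per connected component of the thresholded duct probability map.
#' `kept` marks ducts passing the epithelial-count filter (at least
#' `min_epithelial` epithelial cells inside, default 10).
#'
#' @slot ducts data.frame with columns `id`, `centroid_x`, `centroid_y`
#'   (0-based px), `area_px`, `area_um2`, `n_epithelial`, `kept`,
#'   `on_border`.
#' @slot polygons list of outer-contour rings, one `(n, 2)` matrix of
#'   `(x, y)` pixel coordinates per duct.
#' @slot labelMask integer matrix of duct labels in the tile frame.
#' @slot mpp microns per pixel of the tile the ducts were segmented on.
#' @export
setClass("DuctSet", representation(ducts = "data.frame", polygons = "list",
                                   labelMask = "matrix", mpp = "numeric"))

#' Voronoi tessellation of duct centroids
#'
#' Regions are convex polygons obtained by cutting the clip region with the
#' perpendicular-bisector half-plane against every other seed, so each region
#' contains exactly the points nearer to its seed than to any other.
#' The invasive exclusion region is carried as a set of discs (centres +
#' radius); cells inside it are dropped from all downstream counts.
#'
#' @slot seeds numeric matrix `(k, 2)` of duct centroids, micron coordinates.
#' @slot seedIds integer duct ids, parallel to `seeds`.
#' @slot regions list of `(n, 2)` polygon matrices, micron coordinates.
#' @slot clipRegion `(n, 2)` convex polygon the tessellation is clipped to.
#' @slot excludedCentres `(m, 2)` matrix of disc centres (microns).
#' @slot excludedRadiusUm disc radius in microns.
#' @export
setClass("DuctTessellation",
         representation(seeds = "matrix", seedIds = "integer",
                        regions = "list", clipRegion = "matrix",
                        excludedCentres = "matrix",
                        excludedRadiusUm = "numeric"))

#' Slide-level DCIS immune colocalisation score
#'
#' The Morisita-Horn similarity between the quadrat-level spatial
#' distributions of in-situ lymphocytes and in-situ epithelial cells.
#' Slides with fewer than `minDucts` kept ducts are flagged invalid and the
#' value is reported missing.
#'
#' @slot value score in `[0, 1]`, or `NA` when invalid/undefined.
#' @slot nDucts number of kept ducts seeding the tessellation.
#' @slot nUnits number of quadrat units with positive area.
#' @slot valid whether the slide passed the minimum-duct filter.
#' @slot gridUm quadrat side length used (microns).
#' @slot lymphocytePct percentage of all retained cells that are lymphocytes.
#' @slot droppedCells number of cells dropped by clipping/exclusion.
#' @export
setClass("ColocalisationScore",
         representation(value = "numeric", nDucts = "integer",
                        nUnits = "integer", valid = "logical",
                        gridUm = "numeric", lymphocytePct = "numeric",
                        droppedCells = "integer"),
         validity = function(object) {
  if (!object@valid && !is.na(object@value))
    return("invalid scores must report a missing value")
  if (!is.na(object@value) && (object@value < -1e-9 || object@value > 1 + 1e-9))
    return("score must lie in [0, 1]")
  TRUE
})

setMethod("show", "HistoTile", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("HistoTile %d x %d px, %.3g um/px (%.0f x %.0f um)\n",
              d[1], d[2], object@mpp, d[1] * object@mpp, d[2] * object@mpp))
})

setMethod("show", "DuctSet", function(object) {
  cat(sprintf("DuctSet: %d ducts (%d kept) on a %s tile, %.3g um/px\n",
              nrow(object@ducts), sum(object@ducts$kept),
              paste(dim(object@labelMask), collapse = " x "), object@mpp))
})

setMethod("show", "DuctTessellation", function(object) {
  cat(sprintf("DuctTessellation: %d seeds, %d excluded discs (r = %.1f um)\n",
              nrow(object@seeds), nrow(object@excludedCentres),
              object@excludedRadiusUm))
})

setMethod("show", "ColocalisationScore", function(object) {
  cat(sprintf(
    "DCIS immune colocalisation score: %s (%svalid; %d ducts, %d units, grid %g um)\n",
    ifelse(is.na(object@value), "NA", sprintf("%.4f", object@value)),
    ifelse(object@valid, "", "in"), object@nDucts, object@nUnits,
    object@gridUm))
})

#' Accessors for HistoTile
#' @param x a [HistoTile-class]
#' @return `tilePixels`: the `(H, W, 3)` array; `tileMpp`: microns per pixel.
#' @export
tilePixels <- function(x) x@pixels

#' @rdname tilePixels
#' @export
tileMpp <- function(x) x@mpp

#' Duct table accessor
#' @param x a [DuctSet-class]
#' @return the per-duct data.frame.
#' @export
ductTable <- function(x) x@ducts

#' Score accessors
#' @param x a [ColocalisationScore-class]
#' @return `scoreValue`: the Morisita-Horn value (NA when invalid);
#'   `scoreValid`: logical validity flag.
#' @export
scoreValue <- function(x) x@value

#' @rdname scoreValue
#' @export
scoreValid <- function(x) x@valid
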