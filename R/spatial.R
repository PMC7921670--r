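# The ecological core: invasive-compartment exclusion, Voronoi tessellation
# seeded on duct centroids, quadrat counting, and the Morisita-Horn DCIS
# immune colocalisation score. All geometry here is done in micron
# coordinates in the low-resolution working frame; cell pixel coordinates are
# converted via the tile's microns-per-pixel.

# ---- polygon primitives ----------------------------------------------------

# Sutherland-Hodgman clip of a convex polygon against the half-plane
# a.x <= b (keep side). poly: (n,2) matrix.
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  f <- as.vector(poly %*% a) - b
  inside <- f <= 1e-12
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  out <- matrix(0, 2 * n, 2)
  m <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) {
      m <- m + 1L
      out[m, ] <- poly[i, ]
    }
    if (xor(inside[i], inside[j])) {
      t <- f[i] / (f[i] - f[j])
      m <- m + 1L
      out[m, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(m), , drop = FALSE]
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# even-odd ray casting; pts (m,2), poly (n,2); boundary points may fall on
# either side -- callers resolve those by the nearest-seed rule
point_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  if (n < 3 || nrow(pts) == 0) return(rep(FALSE, nrow(pts)))
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

convex_hull <- function(pts) {
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  pts[idx, , drop = FALSE]
}

# ---- compartments ----------------------------------------------------------

#' Reclassify epithelial cells into in-situ vs other
#'
#' Epithelial cells inside any kept duct become `in_situ`; all other
#' epithelial cells become `other` (invasive or normal ductal epithelium).
#' Non-epithelial cells are left `unassigned` at this step. Membership is
#' evaluated on the duct label mask, so cells on the duct boundary count as
#' inside.
#'
#' @param cells data.frame with `x_px`, `y_px`, `class`.
#' @param ducts a [DuctSet-class] whose `kept` flags are set
#'   (see [filterDucts()]).
#' @return `cells` with a `compartment` column.
#' @export
reclassifyEpithelial <- function(cells, ducts) {
  cells$compartment <- "unassigned"
  epi <- cells$class == "epithelial"
  if (!any(epi)) return(cells)
  kept_ids <- ductTable(ducts)$id[ductTable(ducts)$kept]
  lab <- duct_label_at(ducts, cells$x_px[epi], cells$y_px[epi])
  cells$compartment[epi] <- ifelse(lab %in% kept_ids, "in_situ", "other")
  cells
}

# duct label under each cell centre (0 where none)
duct_label_at <- function(ducts, x_px, y_px) {
  m <- ducts@labelMask
  r <- pmin(pmax(round(y_px) + 1, 1), nrow(m))
  c <- pmin(pmax(round(x_px) + 1, 1), ncol(m))
  m[cbind(r, c)]
}

#' Invasive exclusion region
#'
#' The invasive compartment is modelled as the union of discs of radius
#' `dilation_um` around every `other`-epithelial cell. Cells of any class
#' inside this region are dropped from tessellation statistics; duct seeds
#' falling inside it are omitted.
#'
#' @param cells data.frame with a `compartment` column
#'   (see [reclassifyEpithelial()]).
#' @param mpp microns per pixel of the cell coordinates.
#' @param dilation_um disc radius in microns (default 50).
#' @return list with `centres` (matrix of micron coordinates, possibly
#'   0-row) and `radius_um`.
#' @export
invasiveExclusionRegion <- function(cells, mpp, dilation_um = 50) {
  oth <- cells$compartment == "other"
  centres <- cbind(cells$x_px[oth], cells$y_px[oth]) * mpp
  list(centres = centres, radius_um = dilation_um)
}

in_excluded <- function(pts_um, region) {
  if (is.null(region) || nrow(region$centres) == 0 || nrow(pts_um) == 0)
    return(rep(FALSE, nrow(pts_um)))
  r2 <- region$radius_um^2
  out <- logical(nrow(pts_um))
  for (k in seq_len(nrow(region$centres))) {
    d2 <- (pts_um[, 1] - region$centres[k, 1])^2 +
      (pts_um[, 2] - region$centres[k, 2])^2
    out <- out | d2 <= r2
  }
  out
}

# ---- tessellation ----------------------------------------------------------

#' Voronoi tessellation of duct centroids
#'
#' Each seed's region is the set of points of the clip region at least as
#' close to it as to any other seed, computed exactly by successive
#' half-plane cuts of the (convex) clip polygon with every perpendicular
#' bisector. Coincident seeds are merged with a warning.
#'
#' @param seeds matrix `(k, 2)` of duct centroids in microns.
#' @param clip_region convex polygon `(n, 2)` in microns; defaults to the
#'   bounding box of the seeds grown by 20% when omitted.
#' @param excluded optional exclusion region from
#'   [invasiveExclusionRegion()]; seeds inside it are dropped.
#' @param seed_ids integer ids parallel to `seeds` (defaults to row number).
#' @return A [DuctTessellation-class].
#' @export
tessellate <- function(seeds, clip_region = NULL, excluded = NULL,
                       seed_ids = NULL) {
  seeds <- as.matrix(seeds)
  if (is.null(seed_ids)) seed_ids <- seq_len(nrow(seeds))
  if (nrow(seeds) < 1) stop("tessellation needs at least one seed")
  # merge coincident seeds (keep lowest id)
  key <- paste(signif(seeds[, 1], 12), signif(seeds[, 2], 12))
  if (anyDuplicated(key)) {
    warning("coincident duct centroids merged")
    keep <- !duplicated(key)
    seeds <- seeds[keep, , drop = FALSE]
    seed_ids <- seed_ids[keep]
  }
  if (!is.null(excluded) && nrow(excluded$centres)) {
    drop <- in_excluded(seeds, excluded)
    if (all(drop)) stop("all seeds fall inside the excluded region")
    seeds <- seeds[!drop, , drop = FALSE]
    seed_ids <- seed_ids[!drop]
  }
  if (is.null(clip_region)) {
    rx <- range(seeds[, 1]); ry <- range(seeds[, 2])
    mx <- 0.2 * max(diff(rx), diff(ry), 1)
    clip_region <- cbind(c(rx[1] - mx, rx[2] + mx, rx[2] + mx, rx[1] - mx),
                         c(ry[1] - mx, ry[1] - mx, ry[2] + mx, ry[2] + mx))
  }
  regions <- vector("list", nrow(seeds))
  for (k in seq_len(nrow(seeds))) {
    poly <- clip_region
    for (j in seq_len(nrow(seeds))) {
      if (j == k || nrow(poly) == 0) next
      # keep points with d(x, s_k) <= d(x, s_j):  (s_j - s_k) . x <= b
      a <- seeds[j, ] - seeds[k, ]
      b <- (sum(seeds[j, ]^2) - sum(seeds[k, ]^2)) / 2
      poly <- clip_halfplane(poly, a, b)
    }
    regions[[k]] <- poly
  }
  new("DuctTessellation", seeds = seeds, seedIds = as.integer(seed_ids),
      regions = regions, clipRegion = clip_region,
      excludedCentres = if (is.null(excluded)) matrix(numeric(0), 0, 2)
                        else region_centres(excluded),
      excludedRadiusUm = if (is.null(excluded)) 0 else excluded$radius_um)
}

region_centres <- function(excluded) {
  m <- as.matrix(excluded$centres)
  if (!nrow(m)) matrix(numeric(0), 0, 2) else m
}

#' Assign cells to Voronoi regions
#'
#' Every retained cell is attributed to exactly one duct region: the region
#' polygon containing it, falling back to the nearest seed (ties broken
#' towards the lower duct id) for points on region boundaries. Cells outside
#' the clip region or inside the excluded region are dropped and counted.
#'
#' @param tess a [DuctTessellation-class].
#' @param cells data.frame with `x_px`, `y_px`, `class` (and optionally
#'   `compartment`).
#' @param mpp microns per pixel of the cell coordinates.
#' @return list with `cells` (retained cells plus `duct_region` = seed id and
#'   micron coordinates `x_um`, `y_um`) and `dropped` (count).
#' @export
assignCells <- function(tess, cells, mpp) {
  pts <- cbind(cells$x_px, cells$y_px) * mpp
  n <- nrow(cells)
  if (n == 0) return(list(cells = cbind(cells, duct_region = integer(0)),
                          dropped = 0L))
  in_clip <- point_in_polygon(pts, tess@clipRegion) |
    on_boundary_nearest(pts, tess@clipRegion)
  excl <- in_excluded(pts, list(centres = tess@excludedCentres,
                                radius_um = tess@excludedRadiusUm))
  keep <- in_clip & !excl
  region <- rep(NA_integer_, n)
  for (k in seq_len(nrow(tess@seeds))) {
    inr <- point_in_polygon(pts, tess@regions[[k]])
    region[keep & inr & is.na(region)] <- tess@seedIds[k]
  }
  # boundary / numeric misses: nearest seed, tie to lower id
  miss <- keep & is.na(region)
  if (any(miss)) region[miss] <- nearest_seed(pts[miss, , drop = FALSE],
                                              tess@seeds, tess@seedIds)
  out <- cells[keep, , drop = FALSE]
  out$x_um <- pts[keep, 1]
  out$y_um <- pts[keep, 2]
  out$duct_region <- region[keep]
  list(cells = out, dropped = sum(!keep))
}

# brute-force nearest-seed rule (Eq. 2), ties to the lower duct id; this is
# also the oracle the tests compare polygon membership against
nearest_seed <- function(pts, seeds, seed_ids) {
  if (!nrow(pts)) return(integer(0))
  d2 <- outer(rowSums(pts^2), rep(1, nrow(seeds))) -
    2 * pts %*% t(seeds) + outer(rep(1, nrow(pts)), rowSums(seeds^2))
  ord <- order(seed_ids)
  d2o <- d2[, ord, drop = FALSE]
  pick <- apply(d2o, 1, function(r) which(r <= min(r) + 1e-9)[1])
  seed_ids[ord][pick]
}

on_boundary_nearest <- function(pts, poly, tol = 1e-9) {
  # cheap inclusion rescue for points numerically on the clip boundary
  if (!nrow(pts)) return(logical(0))
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  pts[, 1] >= xr[1] - tol & pts[, 1] <= xr[2] + tol &
    pts[, 2] >= yr[1] - tol & pts[, 2] <= yr[2] + tol &
    !point_in_polygon(pts, poly) &
    apply(pts, 1, function(p) min_dist_to_poly(p, poly)) <= tol
}

min_dist_to_poly <- function(p, poly) {
  n <- nrow(poly)
  d <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- poly[i, ]; b <- poly[j, ]
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), 1e-300)
    t <- min(max(t, 0), 1)
    d <- min(d, sqrt(sum((p - (a + t * ab))^2)))
  }
  d
}

# ---- quadrats & the score --------------------------------------------------

#' Quadrat partition of a tessellation
#'
#' Intersects each Voronoi region with an axis-aligned square grid of side
#' `grid_um`; every intersection with positive area is one counting unit.
#' Counts of in-situ lymphocytes (`n_l`) and in-situ epithelial cells
#' (`n_e`) are tallied per unit from the assigned cells. `grid_um = Inf`
#' recovers one unit per Voronoi region.
#'
#' @param tess a [DuctTessellation-class].
#' @param assigned output of [assignCells()].
#' @param grid_um quadrat side in microns (default 200).
#' @return data.frame with columns `duct_region`, `gx`, `gy`, `n_l`, `n_e`;
#'   attribute `grid_um` records the grid used.
#' @export
quadratPartition <- function(tess, assigned, grid_um = 200) {
  stopifnot(grid_um > 0)
  cells <- assigned$cells
  is_l <- startsWith(cells$class, "lymphocyte")
  is_e <- cells$class == "epithelial"
  if ("compartment" %in% names(cells))
    is_e <- is_e & cells$compartment == "in_situ"
  units <- list()
  for (k in seq_len(nrow(tess@seeds))) {
    poly <- tess@regions[[k]]
    if (nrow(poly) < 3) next
    if (!is.finite(grid_um)) {
      units[[length(units) + 1L]] <- data.frame(
        duct_region = tess@seedIds[k], gx = 0L, gy = 0L)
      next
    }
    gx0 <- floor(min(poly[, 1]) / grid_um); gx1 <- floor(max(poly[, 1]) / grid_um)
    gy0 <- floor(min(poly[, 2]) / grid_um); gy1 <- floor(max(poly[, 2]) / grid_um)
    for (gx in gx0:gx1) for (gy in gy0:gy1) {
      cellpoly <- poly
      cellpoly <- clip_halfplane(cellpoly, c(-1, 0), -gx * grid_um)
      cellpoly <- clip_halfplane(cellpoly, c(1, 0), (gx + 1) * grid_um)
      cellpoly <- clip_halfplane(cellpoly, c(0, -1), -gy * grid_um)
      cellpoly <- clip_halfplane(cellpoly, c(0, 1), (gy + 1) * grid_um)
      if (polygon_area(cellpoly) > 1e-9)
        units[[length(units) + 1L]] <- data.frame(
          duct_region = tess@seedIds[k], gx = gx, gy = gy)
    }
  }
  tab <- do.call(rbind, units)
  if (is.null(tab)) tab <- data.frame(duct_region = integer(0),
                                      gx = integer(0), gy = integer(0))
  tab$n_l <- 0L
  tab$n_e <- 0L
  if (nrow(cells)) {
    cgx <- if (is.finite(grid_um)) floor(cells$x_um / grid_um) else 0L
    cgy <- if (is.finite(grid_um)) floor(cells$y_um / grid_um) else 0L
    key_unit <- paste(tab$duct_region, tab$gx, tab$gy)
    key_cell <- paste(cells$duct_region, cgx, cgy)
    tl <- table(factor(key_cell[is_l], levels = key_unit))
    te <- table(factor(key_cell[is_e], levels = key_unit))
    tab$n_l <- as.integer(tl)
    tab$n_e <- as.integer(te)
  }
  attr(tab, "grid_um") <- grid_um
  tab
}

#' Morisita-Horn colocalisation of two quadrat count distributions
#'
#' `2 * sum(p_l * p_e) / (sum(p_l^2) + sum(p_e^2))` over quadrat units,
#' where `p_l` and `p_e` are the unit fractions of lymphocyte and epithelial
#' counts. 1 for proportional distributions, 0 for disjoint supports.
#' Undefined (error) when either total count is zero.
#'
#' @param table data.frame with columns `n_l` and `n_e`
#'   (see [quadratPartition()]).
#' @return the score in `[0, 1]`.
#' @export
morisitaScore <- function(table) {
  nl <- sum(table$n_l); ne <- sum(table$n_e)
  if (nl == 0 || ne == 0)
    stop("Morisita-Horn score undefined: a class has zero total count")
  pl <- table$n_l / nl
  pe <- table$n_e / ne
  2 * sum(pl * pe) / (sum(pl^2) + sum(pe^2))
}

#' Slide-level DCIS immune colocalisation
#'
#' Runs the full spatial stage for one slide: epithelial reclassification,
#' invasive exclusion, Voronoi tessellation on kept-duct centroids, cell
#' assignment, quadrat counting and the Morisita-Horn score. Slides with
#' fewer than `min_ducts` kept ducts are reported invalid with a missing
#' value, as are slides where the score is undefined (a zero class total).
#'
#' @param ducts a [DuctSet-class] with `kept` flags set.
#' @param cells classified cell table (`x_px`, `y_px`, `class`).
#' @param mpp microns per pixel of the coordinates.
#' @param grid_um quadrat side (microns), default 200.
#' @param min_ducts minimum kept ducts for a valid score (default 5).
#' @param dilation_um invasive-exclusion disc radius (microns), default 50.
#' @param clip_region optional convex clip polygon in microns; defaults to
#'   the convex hull of all cells and duct centroids.
#' @return A [ColocalisationScore-class].
#' @export
slideColocalisation <- function(ducts, cells, mpp, grid_um = 200,
                                min_ducts = 5, dilation_um = 50,
                                clip_region = NULL) {
  cells <- reclassifyEpithelial(cells, ducts)
  excl <- invasiveExclusionRegion(cells, mpp, dilation_um)
  dt <- ductTable(ducts)
  kept <- dt[dt$kept, , drop = FALSE]
  lymph_classes <- startsWith(cells$class, "lymphocyte")
  if (nrow(kept) == 0) {
    return(new("ColocalisationScore", value = NA_real_, nDucts = 0L,
               nUnits = 0L, valid = FALSE, gridUm = grid_um,
               lymphocytePct = if (nrow(cells)) 100 * mean(lymph_classes)
                               else NA_real_,
               droppedCells = 0L))
  }
  seeds <- cbind(kept$centroid_x, kept$centroid_y) * mpp
  if (is.null(clip_region)) {
    pts <- rbind(cbind(cells$x_px, cells$y_px) * mpp, seeds)
    clip_region <- convex_hull(pts)
  }
  tess <- tessellate(seeds, clip_region = clip_region, excluded = excl,
                     seed_ids = kept$id)
  asg <- assignCells(tess, cells, mpp)
  n_seeds <- nrow(tess@seeds)
  lpct <- if (nrow(asg$cells)) {
    100 * mean(startsWith(asg$cells$class, "lymphocyte"))
  } else NA_real_
  if (n_seeds < min_ducts) {
    return(new("ColocalisationScore", value = NA_real_,
               nDucts = as.integer(n_seeds), nUnits = 0L, valid = FALSE,
               gridUm = grid_um, lymphocytePct = lpct,
               droppedCells = as.integer(asg$dropped)))
  }
  tab <- quadratPartition(tess, asg, grid_um)
  val <- tryCatch(morisitaScore(tab), error = function(e) NA_real_)
  new("ColocalisationScore", value = val, nDucts = as.integer(n_seeds),
      nUnits = nrow(tab), valid = !is.na(val), gridUm = grid_um,
      lymphocytePct = lpct, droppedCells = as.integer(asg$dropped))
}
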