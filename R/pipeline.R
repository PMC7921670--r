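# Orchestration: run the full stage chain (tissue -> ducts -> cells ->
# classify -> spatial) for one slide or a cohort, with deterministic
# outputs, JSON provenance and per-slide failure isolation. Any stage can
# run from a trained model or, for synthetic slides, from the tile's ground
# truth (model = "oracle"), which exercises the downstream stages exactly.

#' Pipeline configuration
#'
#' @param mpp microns per pixel of the input tiles.
#' @param grid_um quadrat side for the colocalisation score (default 200).
#' @param min_ducts minimum kept ducts for a valid score (default 5).
#' @param min_epithelial duct filter threshold (default 10).
#' @param dilate_um invasive-exclusion disc radius (default 50).
#' @param duct_prob_threshold duct componentisation threshold (default 0.5).
#' @param cell_threshold centroid extraction threshold (default 0.8).
#' @param seed global seed echoed into provenance.
#' @return config list.
#' @export
pipelineConfig <- function(mpp = 0.5, grid_um = 200, min_ducts = 5L,
                           min_epithelial = 10L, dilate_um = 50,
                           duct_prob_threshold = 0.5, cell_threshold = 0.8,
                           seed = 1L) {
  list(mpp = mpp, grid_um = grid_um, min_ducts = as.integer(min_ducts),
       min_epithelial = as.integer(min_epithelial), dilate_um = dilate_um,
       duct_prob_threshold = duct_prob_threshold,
       cell_threshold = cell_threshold, seed = as.integer(seed))
}

#' Run the full pipeline on one slide
#'
#' Stages are executed in order tissue -> ducts -> cells -> classify ->
#' spatial. Each entry of `models` (`tissue`, `duct`, `cell`,
#' `classifier`) is either a trained model or the string `"oracle"`, which
#' substitutes the slide's ground `truth` for that stage (synthetic slides
#' only). A slide with no ducts yields a score with `valid = FALSE` rather
#' than an error.
#'
#' @param tile a [HistoTile-class].
#' @param models list with elements `tissue`, `duct`, `cell`, `classifier`.
#' @param config from [pipelineConfig()].
#' @param truth optional [TileTruth-class] (required by oracle stages).
#' @param out_dir optional output directory; when given, writes
#'   `<id>_score.json` (with a provenance block), `<id>_ducts.geojson` and
#'   `<id>_cells.csv`.
#' @param slide_id identifier used in filenames and outputs.
#' @return list with `score` ([ColocalisationScore-class]), `ducts`,
#'   `cells`, `tissue_mask` and `lymphocyte_pct`.
#' @export
runSlide <- function(tile, models, config = pipelineConfig(), truth = NULL,
                     out_dir = NULL, slide_id = "slide") {
  arr <- tilePixels(tile)
  H <- dim(arr)[1]; W <- dim(arr)[2]
  oracle <- function(m) identical(m, "oracle")
  need_truth <- any(vapply(models, oracle, TRUE))
  if (need_truth && is.null(truth))
    stop("oracle stages need the slide's ground truth")
  tissue <- if (is.null(models$tissue) || oracle(models$tissue)) {
    matrix(TRUE, H, W)
  } else segmentTissue(tile, models$tissue)
  prob <- if (oracle(models$duct)) {
    (truth@ductMask > 0) * 1
  } else predictDuctProbability(models$duct, tile)
  ducts <- segmentDucts(prob, tileMpp(tile), tissue_mask = tissue,
                        prob_threshold = config$duct_prob_threshold)
  cells <- if (oracle(models$cell)) {
    data.frame(x_px = truth@cells$x_px, y_px = truth@cells$y_px,
               score = 1)
  } else detectCentroids(predictCellProbability(models$cell, tile),
                         config$cell_threshold)
  classified <- if (oracle(models$classifier)) {
    data.frame(id = seq_len(nrow(cells)), x_px = cells$x_px,
               y_px = cells$y_px, detection_score = cells$score,
               class = if (oracle(models$cell)) truth@cells$class
                       else truth_class_at(truth, cells))
  } else classifyCells(tile, cells, models$classifier)
  ducts <- filterDucts(ducts, classified, config$min_epithelial)
  score <- slideColocalisation(ducts, classified, tileMpp(tile),
                               grid_um = config$grid_um,
                               min_ducts = config$min_ducts,
                               dilation_um = config$dilate_um)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeScoreJson(score, config, slide_id,
                   file.path(out_dir, paste0(slide_id, "_score.json")))
    writeDuctsGeojson(ducts, file.path(out_dir,
                                       paste0(slide_id, "_ducts.geojson")))
    utils::write.csv(classified,
                     file.path(out_dir, paste0(slide_id, "_cells.csv")),
                     row.names = FALSE)
  }
  list(score = score, ducts = ducts, cells = classified,
       tissue_mask = tissue,
       lymphocyte_pct = score@lymphocytePct)
}

# nearest ground-truth class for detections (oracle classifier over
# non-oracle detections)
truth_class_at <- function(truth, cells) {
  gt <- truth@cells
  vapply(seq_len(nrow(cells)), function(i) {
    d2 <- (gt$x_px - cells$x_px[i])^2 + (gt$y_px - cells$y_px[i])^2
    gt$class[which.min(d2)]
  }, "")
}

writeScoreJson <- function(score, config, slide_id, path) {
  jsonlite::write_json(list(
    slide_id = slide_id,
    n_ducts = score@nDucts, n_units = score@nUnits,
    lymphocyte_pct = score@lymphocytePct,
    morisita = if (is.na(score@value)) NULL else score@value,
    valid = score@valid, grid_um = score@gridUm,
    dropped_cells = score@droppedCells,
    provenance = c(config, list(package = "ductscape",
                                version = as.character(
                                  utils::packageVersion("ductscape"))))),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write ducts as a GeoJSON FeatureCollection
#'
#' One polygon feature per duct with properties `id`, `area_px`,
#' `area_um2`, `n_epithelial`, `kept`.
#'
#' @param ducts a [DuctSet-class].
#' @param path output path.
#' @export
writeDuctsGeojson <- function(ducts, path) {
  dt <- ductTable(ducts)
  feats <- lapply(seq_len(nrow(dt)), function(k) {
    ring <- ducts@polygons[[k]]
    ring <- rbind(ring, ring[1, , drop = FALSE]) # close the ring
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(i) as.numeric(ring[i, ]))))),
         properties = list(id = dt$id[k], area_px = dt$area_px[k],
                           area_um2 = dt$area_um2[k],
                           n_epithelial = dt$n_epithelial[k],
                           kept = dt$kept[k]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the pipeline over a cohort and compare groups
#'
#' `slides` is a list of entries `list(tile =, truth =, id =, group =,
#' patient =)` (`truth`/`patient` optional). Each slide is processed with
#' [runSlide()]; a failure in one slide is logged and marked, not fatal.
#' Valid scores are compared between the two groups with [groupCompare()]
#' (optionally after patient-level averaging). With fewer than 2 valid
#' scores per group the statistics are skipped with a warning.
#'
#' @param slides list of slide entries.
#' @param models as in [runSlide()].
#' @param config from [pipelineConfig()].
#' @param patient_average average scores per patient before testing.
#' @param out_dir optional output directory (per-slide outputs plus
#'   `cohort.csv`).
#' @return list with `table` (per-slide data.frame) and `stats`
#'   (`NULL` when skipped).
#' @export
runCohort <- function(slides, models, config = pipelineConfig(),
                      patient_average = FALSE, out_dir = NULL) {
  rows <- lapply(slides, function(s) {
    res <- tryCatch(
      runSlide(s$tile, models, config, truth = s$truth, out_dir = out_dir,
               slide_id = if (is.null(s$id)) "slide" else s$id),
      error = function(e) e)
    if (inherits(res, "error")) {
      return(data.frame(id = s$id %||% NA, group = s$group %||% NA,
                        patient = s$patient %||% NA, morisita = NA_real_,
                        lymphocyte_pct = NA_real_, n_ducts = NA_integer_,
                        valid = FALSE, failed = TRUE,
                        error = conditionMessage(res)))
    }
    data.frame(id = s$id %||% NA, group = s$group %||% NA,
               patient = s$patient %||% NA,
               morisita = scoreValue(res$score),
               lymphocyte_pct = res$score@lymphocytePct,
               n_ducts = res$score@nDucts, valid = scoreValid(res$score),
               failed = FALSE, error = "")
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.csv(tab, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
  ok <- tab[tab$valid & !is.na(tab$morisita), , drop = FALSE]
  groups <- unique(stats::na.omit(tab$group))
  stats_out <- NULL
  if (length(groups) == 2) {
    if (patient_average && !all(is.na(ok$patient))) {
      agg <- stats::aggregate(morisita ~ patient + group, data = ok, FUN = mean)
      a <- agg$morisita[agg$group == groups[1]]
      b <- agg$morisita[agg$group == groups[2]]
    } else {
      a <- ok$morisita[ok$group == groups[1]]
      b <- ok$morisita[ok$group == groups[2]]
    }
    if (length(a) >= 2 && length(b) >= 2) {
      stats_out <- c(list(group_a = groups[1], group_b = groups[2],
                          n_a = length(a), n_b = length(b)),
                     groupCompare(a, b))
    } else warning("fewer than 2 valid slides in a group; statistics skipped")
  }
  list(table = tab, stats = stats_out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
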