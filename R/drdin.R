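# Single-cell detection: a dense-inception encoder-decoder regressing a
# distance-regularised proximity map, with Hausdorff-distance monitoring
# (the batch metric 1 / (1 + mean |HD_P - HD_g|)) and centroid extraction
# by thresholding the probability map at 0.8.

#' Configuration for the cell detection network
#'
#' @param width_multiplier channel-width scaling of base widths (8, 16, 32).
#' @param proximity_radius_px radius of the linear-decay proximity target
#'   around each cell centroid (default 6 px at 0.5 um/px).
#' @param centroid_threshold probability threshold for centroid extraction
#'   (default 0.8).
#' @param pos_weight extra loss weight on pixels near centroids
#'   (weight = 1 + pos_weight * target).
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param crop_px random training crop side.
#' @param seed RNG seed.
#' @return config list.
#' @export
drdinConfig <- function(width_multiplier = 1, proximity_radius_px = 6L,
                        centroid_threshold = 0.8, pos_weight = 9,
                        lr = 1e-3, epochs = 8L, crop_px = 128L, seed = 1L) {
  stopifnot(centroid_threshold > 0, centroid_threshold < 1,
            proximity_radius_px >= 1)
  list(width_multiplier = width_multiplier,
       proximity_radius_px = as.integer(proximity_radius_px),
       centroid_threshold = centroid_threshold, pos_weight = pos_weight,
       lr = lr, epochs = as.integer(epochs), crop_px = as.integer(crop_px),
       seed = as.integer(seed))
}

incep2_out <- function(width) 2L * max(1L, as.integer(round(width / 2)))

#' Build the cell detection model
#'
#' Encoder-decoder with two-path inception blocks (1x1 and 3x3 kernels),
#' average-pooling downsampling, transpose-convolution upsampling and dense
#' cross-connections: each encoder level concatenates its input with its
#' inception features, and decoder levels concatenate the upsampled deeper
#' features with the matching encoder stack. Output is a single-channel
#' sigmoid map at input resolution.
#'
#' @param config from [drdinConfig()].
#' @return model object (class `"drdin_model"`).
#' @export
buildDrdin <- function(config = drdinConfig()) {
  wb <- pmax(2L, as.integer(round(c(8, 16, 32) * config$width_multiplier)))
  o1 <- incep2_out(wb[1]); o2 <- incep2_out(wb[2]); o3 <- incep2_out(wb[3])
  c1 <- 3L + o1          # dense: input || features
  c2 <- c1 + o2
  c3 <- c2 + o3
  du <- max(4L, wb[2])   # decoder widths
  dd <- max(4L, wb[1])
  with_seed(config$seed, {
    p <- list()
    p <- add_incep2(p, "b1", 3, wb[1])
    p <- add_incep2(p, "b2", c1, wb[2])
    p <- add_incep2(p, "b3", c2, wb[3])
    p <- nn_param_tconv(p, "u2", c3, du)
    p <- add_conv_bn(p, "d2", 3, du + c2, dd)
    p <- nn_param_tconv(p, "u1", dd, dd)
    p <- add_conv_bn(p, "d1", 3, dd + c1, dd)
    p <- nn_param_conv(p, "head", 1, dd, 1)
    structure(list(params = p, config = config,
                   arch = list(wb = wb, c1 = c1, c2 = c2, c3 = c3)),
              class = "drdin_model")
  })
}

drdin_forward <- function(model, x) {
  tp <- tape_new()
  ids <- nn_leaves(tp, model$params)
  xi <- tp_leaf(tp, x)
  e1 <- t_concat(tp, c(xi, t_incep2(tp, xi, ids, "b1")))
  p1 <- t_avgpool(tp, e1)
  e2 <- t_concat(tp, c(p1, t_incep2(tp, p1, ids, "b2")))
  p2 <- t_avgpool(tp, e2)
  e3 <- t_concat(tp, c(p2, t_incep2(tp, p2, ids, "b3")))
  u2 <- t_tconv(tp, e3, ids[["u2.w"]], ids[["u2.b"]])
  d2 <- t_conv_bn_relu(tp, t_concat(tp, c(u2, e2)), ids, "d2")
  u1 <- t_tconv(tp, d2, ids[["u1.w"]], ids[["u1.b"]])
  d1 <- t_conv_bn_relu(tp, t_concat(tp, c(u1, e1)), ids, "d1")
  z <- t_conv(tp, d1, ids[["head.w"]], ids[["head.b"]])
  prob <- t_sigmoid(tp, z)
  list(tp = tp, ids = ids, prob = prob)
}

#' Distance-regularised proximity target
#'
#' A raster that is 1 at each cell centroid and decays linearly to 0 at
#' `radius` px, combined across centroids by the pixelwise maximum:
#' `t(x) = max_c max(0, 1 - ||x - c|| / radius)`.
#'
#' @param centroids matrix/data.frame of (x, y) 0-based pixel coordinates
#'   (may be empty).
#' @param height,width raster size.
#' @param radius decay radius in px.
#' @return numeric matrix in `[0, 1]`.
#' @export
proximityTarget <- function(centroids, height, width, radius) {
  t <- matrix(0, height, width)
  centroids <- as.matrix(as.data.frame(centroids))
  for (i in seq_len(nrow(centroids))) {
    cx <- centroids[i, 1]; cy <- centroids[i, 2]
    r0 <- max(1L, floor(cy - radius) + 1L)
    r1 <- min(height, ceiling(cy + radius) + 1L)
    c0 <- max(1L, floor(cx - radius) + 1L)
    c1 <- min(width, ceiling(cx + radius) + 1L)
    if (r0 > r1 || c0 > c1) next
    dd <- sqrt(outer(((r0:r1) - 1 - cy)^2, ((c0:c1) - 1 - cx)^2, "+"))
    t[r0:r1, c0:c1] <- pmax(t[r0:r1, c0:c1], pmax(0, 1 - dd / radius))
  }
  t
}

#' Directed Hausdorff distance between two point sets
#'
#' `max_{a in A} min_{b in B} ||a - b||` (Euclidean, asymmetric). Errors on
#' an empty set; callers substitute a configured penalty for empty
#' prediction sets.
#'
#' @param A,B matrices/data.frames of (x, y) coordinates.
#' @return distance in the coordinate units.
#' @export
directedHausdorff <- function(A, B) {
  A <- as.matrix(as.data.frame(A)[, 1:2, drop = FALSE])
  B <- as.matrix(as.data.frame(B)[, 1:2, drop = FALSE])
  if (nrow(A) == 0 || nrow(B) == 0)
    stop("directed Hausdorff distance undefined for an empty set")
  worst <- 0
  step <- max(1L, floor(2e6 / nrow(B)))
  for (s in seq(1, nrow(A), by = step)) {
    e <- min(s + step - 1, nrow(A))
    d2 <- outer(rowSums(A[s:e, , drop = FALSE]^2), rep(1, nrow(B))) -
      2 * A[s:e, , drop = FALSE] %*% t(B) +
      outer(rep(1, e - s + 1), rowSums(B^2))
    worst <- max(worst, max(apply(d2, 1, min)))
  }
  sqrt(max(worst, 0))
}

#' Batch Hausdorff agreement metric
#'
#' For each image j in the batch, `HD_P` is the directed Hausdorff distance
#' from predicted to true centroids and `HD_g` the reverse; the metric is
#' `1 / (1 + (1/B) * sum_j |HD_P^j - HD_g^j|)`, which is 1 exactly when all
#' per-image differences vanish. The mean symmetric Hausdorff
#' `mean_j max(HD_P^j, HD_g^j)` is reported alongside and is what model
#' selection uses. An empty prediction set is scored with
#' `empty_penalty` (typically the patch diagonal) and logged.
#'
#' @param pred_sets,gt_sets lists of (x, y) point matrices, equal length.
#' @param empty_penalty distance substituted for an empty prediction set.
#' @return list with `value`, `hd_p`, `hd_g`, `mean_symmetric`,
#'   `n_empty`.
#' @export
hdBatchMetric <- function(pred_sets, gt_sets, empty_penalty = NULL) {
  B <- length(pred_sets)
  stopifnot(B >= 1, length(gt_sets) == B)
  hd_p <- hd_g <- numeric(B)
  n_empty <- 0L
  for (j in seq_len(B)) {
    pn <- nrow(as.data.frame(pred_sets[[j]]))
    gn <- nrow(as.data.frame(gt_sets[[j]]))
    if (pn == 0 || gn == 0) {
      if (is.null(empty_penalty))
        stop("empty point set and no empty_penalty configured")
      n_empty <- n_empty + 1L
      hd_p[j] <- empty_penalty
      hd_g[j] <- empty_penalty * (gn == 0) # truth empty too: both penalised
      if (gn == 0 && pn == 0) hd_p[j] <- hd_g[j] <- 0
      next
    }
    hd_p[j] <- directedHausdorff(pred_sets[[j]], gt_sets[[j]])
    hd_g[j] <- directedHausdorff(gt_sets[[j]], pred_sets[[j]])
  }
  list(value = 1 / (1 + mean(abs(hd_p - hd_g))), hd_p = hd_p, hd_g = hd_g,
       mean_symmetric = mean(pmax(hd_p, hd_g)), n_empty = n_empty)
}

#' Extract cell centroids from a probability map
#'
#' Thresholds the map (default 0.8), labels 8-connected components and
#' reports each component's centre of mass as one cell centroid, with the
#' component's peak probability as the detection score. Single-pixel
#' components are retained (small nuclei).
#'
#' @param prob_map numeric matrix in `[0, 1]`.
#' @param threshold detection threshold (default 0.8).
#' @return data.frame with `x_px`, `y_px` (0-based), `score`.
#' @export
detectCentroids <- function(prob_map, threshold = 0.8) {
  m <- prob_map >= threshold
  lab <- cpp_label8(m)
  n <- max(lab)
  if (n == 0)
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      score = numeric(0)))
  H <- nrow(lab)
  idx <- which(lab > 0)
  lv <- lab[idx]
  rr <- ((idx - 1) %% H)
  cc <- ((idx - 1) %/% H)
  pv <- prob_map[idx]
  data.frame(
    x_px = as.numeric(tapply(cc, lv, mean)),
    y_px = as.numeric(tapply(rr, lv, mean)),
    score = as.numeric(tapply(pv, lv, max)))
}

#' Train the cell detection network
#'
#' Minimises a weighted pixel regression loss to the proximity target
#' (weights `1 + pos_weight * target` emphasise the centroid peaks). When a
#' validation set is supplied, the batch Hausdorff metric and the mean
#' symmetric Hausdorff distance of the extracted centroids are computed each
#' epoch; the parameters with the best (lowest) mean symmetric Hausdorff
#' are kept. Training aborts on a non-finite loss.
#'
#' @param tiles list of [HistoTile-class] or arrays.
#' @param cell_tables list of data.frames with `x_px`, `y_px` (all cells in
#'   each tile).
#' @param config from [drdinConfig()].
#' @param validation optional `list(tiles = , cells = )` held-out set.
#' @return trained model with `history`, and `val_metrics` when validated.
#' @export
trainDrdin <- function(tiles, cell_tables, config = drdinConfig(),
                       validation = NULL) {
  model <- buildDrdin(config)
  params <- model$params
  st <- adam_new(params)
  history <- numeric(0)
  val_hist <- list()
  best <- list(hd = Inf, params = params)
  with_seed(config$seed + 23L, {
    arrs <- lapply(tiles, function(t)
      if (methods::is(t, "HistoTile")) tilePixels(t) else t)
    for (epoch in seq_len(config$epochs)) {
      losses <- numeric(0)
      for (i in sample(seq_along(arrs))) {
        arr <- arrs[[i]]
        cells <- cell_tables[[i]]
        cp <- config$crop_px
        r0 <- 1L; c0 <- 1L
        if (dim(arr)[1] > cp) {
          r0 <- sample.int(dim(arr)[1] - cp + 1L, 1L)
          c0 <- sample.int(dim(arr)[2] - cp + 1L, 1L)
          arr <- arr[r0:(r0 + cp - 1), c0:(c0 + cp - 1), , drop = FALSE]
        }
        keep <- cells$x_px >= c0 - 1 & cells$x_px <= c0 - 2 + dim(arr)[2] &
          cells$y_px >= r0 - 1 & cells$y_px <= r0 - 2 + dim(arr)[1]
        ctr <- cbind(cells$x_px[keep] - (c0 - 1), cells$y_px[keep] - (r0 - 1))
        target <- proximityTarget(ctr, dim(arr)[1], dim(arr)[2],
                                  config$proximity_radius_px)
        x <- normalize_patch(arr)
        fw <- drdin_forward(model, x)
        w <- 1 + config$pos_weight * target
        loss <- t_wmse(fw$tp, fw$prob, array(target, dim = c(dim(target), 1)),
                       array(w, dim = c(dim(w), 1)))
        lv <- tp_value(fw$tp, loss)
        if (!is.finite(lv)) stop("training diverged (non-finite loss)")
        losses <- c(losses, lv)
        g <- nn_grads(fw$tp, loss, fw$ids)
        upd <- adam_step(params, g, st, config$lr)
        params <- upd$params; st <- upd$state
        model$params <- params
      }
      history <- c(history, mean(losses))
      if (!is.null(validation)) {
        pred_sets <- list(); gt_sets <- list(); diag <- 0
        for (j in seq_along(validation$tiles)) {
          vt <- validation$tiles[[j]]
          va <- if (methods::is(vt, "HistoTile")) tilePixels(vt) else vt
          pr <- predictCellProbability(model, va)
          det <- detectCentroids(pr, config$centroid_threshold)
          pred_sets[[j]] <- cbind(det$x_px, det$y_px)
          vc <- validation$cells[[j]]
          gt_sets[[j]] <- cbind(vc$x_px, vc$y_px)
          diag <- max(diag, sqrt(sum(dim(va)[1:2]^2)))
        }
        vm <- hdBatchMetric(pred_sets, gt_sets, empty_penalty = diag)
        val_hist[[epoch]] <- vm[c("value", "mean_symmetric", "n_empty")]
        if (vm$mean_symmetric < best$hd)
          best <- list(hd = vm$mean_symmetric, params = params)
      }
    }
  })
  if (!is.null(validation) && is.finite(best$hd)) model$params <- best$params
  model$history <- history
  model$val_metrics <- val_hist
  model
}

#' Cell probability map for a tile
#'
#' Standardises the tile, reflection-pads to a multiple of 4 and runs the
#' detection network.
#'
#' @param model a trained `drdin_model`.
#' @param tile a [HistoTile-class] or array.
#' @return probability matrix in the tile frame.
#' @export
predictCellProbability <- function(model, tile, margin = 8L) {
  arr <- if (methods::is(tile, "HistoTile")) tilePixels(tile) else tile
  H <- dim(arr)[1]; W <- dim(arr)[2]
  margin <- min(margin, H - 1L, W - 1L)
  x <- pad_reflect(normalize_patch(arr), margin, margin, margin, margin)
  pd <- pad_to_multiple(x, 4L)
  fw <- drdin_forward(model, pd$x)
  prob <- tp_value(fw$tp, fw$prob)[, , 1]
  prob[margin + seq_len(H), margin + seq_len(W), drop = FALSE]
}
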