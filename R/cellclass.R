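# Single-cell classification at detected centroids: a small patch CNN with
# neighbouring-ensemble prediction (softmax averaged over the centre patch
# and K patches on a ring), H&E classes epithelial/stromal/lymphocyte or
# IHC classes epithelial/lymphocyte_pos/lymphocyte_neg/stromal, plus the
# lymphocyte% summary.

#' Configuration for the cell classifier
#'
#' @param patch_px classification patch side (default 28 px, a typical
#'   nucleus context at 0.5 um/px).
#' @param n_neighbors K patches on the ensemble ring (default 8; 0 reduces
#'   to single-patch softmax).
#' @param ring_radius_px ensemble ring radius (default 6 px).
#' @param per_class_per_epoch balanced sampling: patches drawn per class per
#'   epoch.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param seed RNG seed.
#' @return config list.
#' @export
cellClassifierConfig <- function(patch_px = 28L, n_neighbors = 8L,
                                 ring_radius_px = 6L,
                                 per_class_per_epoch = 300L, lr = 1e-3,
                                 epochs = 4L, seed = 1L) {
  stopifnot(patch_px %% 4 == 0)
  list(patch_px = as.integer(patch_px), n_neighbors = as.integer(n_neighbors),
       ring_radius_px = as.integer(ring_radius_px),
       per_class_per_epoch = as.integer(per_class_per_epoch), lr = lr,
       epochs = as.integer(epochs), seed = as.integer(seed))
}

#' Build the patch classifier
#'
#' conv(3x3, 8) - pool - conv(3x3, 16) - pool - dense(32) - softmax over the
#' classes, in the order given; that order is also the deterministic
#' tie-break order of [classifyCells()].
#'
#' @param classes character vector of class labels (first = tie winner).
#' @param config from [cellClassifierConfig()].
#' @return model object (class `"cellclass_model"`).
#' @export
buildCellClassifier <- function(classes = c("epithelial", "stromal",
                                            "lymphocyte"),
                                config = cellClassifierConfig()) {
  q <- config$patch_px %/% 4L
  with_seed(config$seed, {
    p <- list()
    p <- add_conv_bn(p, "c1", 3, 3, 8)
    p <- add_conv_bn(p, "c2", 3, 8, 16)
    p <- nn_param_dense(p, "f1", q * q * 16L, 32L)
    p <- nn_param_dense(p, "f2", 32L, length(classes))
    structure(list(params = p, config = config, classes = classes),
              class = "cellclass_model")
  })
}

cellclass_forward <- function(model, x) {
  tp <- tape_new()
  ids <- nn_leaves(tp, model$params)
  h <- t_conv_bn_relu(tp, tp_leaf(tp, x), ids, "c1")
  h <- t_avgpool(tp, h)
  h <- t_conv_bn_relu(tp, h, ids, "c2")
  h <- t_avgpool(tp, h)
  h <- t_dense(tp, h, ids[["f1.w"]], ids[["f1.b"]])
  h <- t_relu(tp, h)
  z <- t_dense(tp, h, ids[["f2.w"]], ids[["f2.b"]])
  list(tp = tp, ids = ids, logits = z)
}

# reflect index helper for border patches
reflect_idx <- function(i, n) {
  i <- ((i - 1) %% (2 * n)) + 1
  i[i > n] <- 2 * n + 1 - i[i > n]
  i
}

extract_patch <- function(arr, x, y, size) {
  half <- size %/% 2
  rr <- reflect_idx(round(y) + 1 + seq(-half, length.out = size), dim(arr)[1])
  cc <- reflect_idx(round(x) + 1 + seq(-half, length.out = size), dim(arr)[2])
  arr[rr, cc, , drop = FALSE]
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Train the cell classifier
#'
#' Balanced sampling per epoch (the same number of patches per class, drawn
#' with replacement from the pooled annotated cells), per-patch softmax
#' cross-entropy, Adam.
#'
#' @param tiles list of [HistoTile-class] or arrays.
#' @param cell_tables list of data.frames with `x_px`, `y_px`, `class`.
#' @param config from [cellClassifierConfig()].
#' @param classes class order; defaults to the sorted classes present, with
#'   the conventional H&E order used when it matches.
#' @return trained model with `history`.
#' @export
trainCellClassifier <- function(tiles, cell_tables,
                                config = cellClassifierConfig(),
                                classes = NULL) {
  pool <- do.call(rbind, lapply(seq_along(tiles), function(i) {
    ct <- cell_tables[[i]]
    data.frame(tile = i, x = ct$x_px, y = ct$y_px, class = ct$class)
  }))
  if (is.null(classes)) {
    present <- sort(unique(pool$class))
    he <- c("epithelial", "stromal", "lymphocyte")
    ihc <- c("epithelial", "lymphocyte_pos", "lymphocyte_neg", "stromal")
    classes <- if (setequal(present, he)) he
      else if (setequal(present, ihc)) ihc else present
  }
  model <- buildCellClassifier(classes, config)
  params <- model$params
  st <- adam_new(params)
  arrs <- lapply(tiles, function(t)
    if (methods::is(t, "HistoTile")) tilePixels(t) else t)
  history <- numeric(0)
  with_seed(config$seed + 11L, {
    for (epoch in seq_len(config$epochs)) {
      batch <- do.call(rbind, lapply(classes, function(cl) {
        rows <- which(pool$class == cl)
        pool[sample(rows, config$per_class_per_epoch, replace = TRUE), ]
      }))
      batch <- batch[sample(nrow(batch)), ]
      losses <- numeric(0)
      for (i in seq_len(nrow(batch))) {
        # jitter by up to the ensemble ring radius so the network is
        # trained on the same off-centre views the ensemble averages over
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- config$ring_radius_px * sqrt(stats::runif(1))
        px <- extract_patch(arrs[[batch$tile[i]]],
                            batch$x[i] + rad * cos(ang),
                            batch$y[i] + rad * sin(ang), config$patch_px)
        x <- normalize_patch(px)
        fw <- cellclass_forward(model, x)
        lab <- match(batch$class[i], classes)
        loss <- t_softmax_ce(fw$tp, fw$logits, lab)
        losses <- c(losses, tp_value(fw$tp, loss))
        g <- nn_grads(fw$tp, loss, fw$ids)
        upd <- adam_step(params, g, st, config$lr)
        params <- upd$params; st <- upd$state
        model$params <- params
      }
      history <- c(history, mean(losses))
    }
  })
  model$history <- history
  model
}

#' Classify cells at detected centroids
#'
#' For each centroid the centre patch plus `n_neighbors` patches at fixed
#' offsets on a ring of `ring_radius_px` are classified and their softmax
#' posteriors averaged (neighbouring-ensemble prediction); the class is the
#' argmax with ties broken deterministically towards the earlier class in
#' the model's class order. Patches near the tile border use reflection
#' padding. Permuting centroid order permutes the records but no
#' assignment; the aggregated posterior is invariant to ensemble-member
#' order.
#'
#' @param tile a [HistoTile-class] or array.
#' @param centroids data.frame with `x_px`, `y_px` and optionally `score`.
#' @param model a trained `cellclass_model`.
#' @return data.frame of cell records: `id`, `x_px`, `y_px`,
#'   `detection_score`, `class` and one `posterior_<class>` column per
#'   class.
#' @export
classifyCells <- function(tile, centroids, model) {
  arr <- if (methods::is(tile, "HistoTile")) tilePixels(tile) else tile
  cfg <- model$config
  K <- cfg$n_neighbors
  offs <- if (K > 0) {
    ang <- 2 * pi * (seq_len(K) - 1) / K
    rbind(c(0, 0), cbind(cfg$ring_radius_px * cos(ang),
                         cfg$ring_radius_px * sin(ang)))
  } else matrix(0, 1, 2)
  n <- nrow(centroids)
  post <- matrix(0, n, length(model$classes))
  for (i in seq_len(n)) {
    acc <- numeric(length(model$classes))
    for (k in seq_len(nrow(offs))) {
      px <- extract_patch(arr, centroids$x_px[i] + offs[k, 1],
                          centroids$y_px[i] + offs[k, 2], cfg$patch_px)
      fw <- cellclass_forward(model, normalize_patch(px))
      acc <- acc + softmax(tp_value(fw$tp, fw$logits))
    }
    post[i, ] <- acc / nrow(offs)
  }
  cls <- model$classes[apply(post, 1, which.max)]
  out <- data.frame(id = seq_len(n), x_px = centroids$x_px,
                    y_px = centroids$y_px,
                    detection_score = if ("score" %in% names(centroids))
                      centroids$score else NA_real_,
                    class = if (n) cls else character(0))
  for (j in seq_along(model$classes))
    out[[paste0("posterior_", model$classes[j])]] <- post[, j]
  out
}

#' Lymphocyte percentage
#'
#' `100 * (number of cells of the counted classes) / (all cells)`. By
#' default every lymphocyte class is counted (`lymphocyte`,
#' `lymphocyte_pos`, `lymphocyte_neg`); pass e.g.
#' `classes = "lymphocyte_pos"` for a stain-positive percentage.
#'
#' @param cells data.frame with a `class` column (non-empty).
#' @param classes classes counted in the numerator.
#' @return percentage in `[0, 100]`.
#' @export
lymphocyteFraction <- function(cells, classes = NULL) {
  if (nrow(cells) == 0)
    stop("lymphocyte fraction undefined for an empty cell list")
  hit <- if (is.null(classes)) startsWith(cells$class, "lymphocyte")
    else cells$class %in% classes
  100 * mean(hit)
}
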