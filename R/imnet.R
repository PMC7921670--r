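# Duct detection / segmentation network: an encoder-decoder with five
# inception blocks in the contracting path and five decoder blocks in the
# expanding path. The same patch downsampled by 2 and 4 is fed to the second
# and third encoder blocks so local features and wider spatial context are
# encoded together; the loss is boundary-weighted cross-entropy from the
# main output plus three auxiliary decoder outputs.

#' Configuration for the duct segmentation network
#'
#' @param input_size training patch size in px (>= 64, divisible by 4; the
#'   network itself is fully convolutional and accepts any size divisible
#'   by 16 at inference).
#' @param width_multiplier channel-width scaling of the base widths
#'   (16, 32, 64, 128, 256); the default 0.25 is the desk-scale setting.
#' @param aux_loss_weight weight `lambda` on each auxiliary output's loss.
#' @param lr0 initial learning rate (Adam).
#' @param lr_decay_every epochs per tenfold learning-rate drop.
#' @param epochs training epochs.
#' @param crop_px random training crop side; patches are cropped from the
#'   input tiles each epoch.
#' @param w0,sigma boundary weight map parameters (see
#'   [boundaryWeightMap()]).
#' @param prob_threshold probability threshold for componentising the duct
#'   map (default 0.5).
#' @param min_epithelial_per_duct duct filter: minimum epithelial cells for
#'   a duct to be kept (default 10).
#' @param augment apply random flip/rotation/scaling/blur/distortion during
#'   training.
#' @param seed RNG seed for initialisation, cropping and augmentation.
#' @return config list.
#' @export
imnetConfig <- function(input_size = 256L, width_multiplier = 0.25,
                        aux_loss_weight = 0.3, lr0 = 1e-3,
                        lr_decay_every = 4L, epochs = 6L, crop_px = 128L,
                        w0 = 2, sigma = 5, prob_threshold = 0.5,
                        min_epithelial_per_duct = 10L, augment = TRUE,
                        seed = 1L) {
  stopifnot(input_size >= 64, input_size %% 4 == 0)
  list(input_size = as.integer(input_size),
       width_multiplier = width_multiplier,
       aux_loss_weight = aux_loss_weight, lr0 = lr0,
       lr_decay_every = as.integer(lr_decay_every),
       epochs = as.integer(epochs), crop_px = as.integer(crop_px),
       w0 = w0, sigma = sigma, prob_threshold = prob_threshold,
       min_epithelial_per_duct = as.integer(min_epithelial_per_duct),
       augment = augment, seed = as.integer(seed))
}

incep4_out <- function(width) 4L * max(1L, as.integer(round(width / 4)))

#' Build the duct segmentation model
#'
#' Initialises the parameters of the five-inception-block encoder /
#' five-decoder-block architecture at the widths implied by
#' `width_multiplier`. The returned model carries its parameters, config and
#' architecture metadata; [predictDuctProbability()] runs inference.
#'
#' @param config from [imnetConfig()].
#' @return model object (list with class `"imnet_model"`).
#' @export
buildImnet <- function(config = imnetConfig()) {
  wb <- pmax(4L, as.integer(round(c(16, 32, 64, 128, 256) *
                                  config$width_multiplier)))
  ws <- pmax(2L, wb[1] %/% 2L)
  c1 <- incep4_out(wb[1])
  c2 <- incep4_out(wb[2])
  c3 <- incep4_out(wb[3])
  c4 <- incep4_out(wb[4])
  c5 <- incep4_out(wb[5])
  with_seed(config$seed, {
    p <- list()
    p <- add_conv_bn(p, "stem2", 1, 3, ws)
    p <- add_conv_bn(p, "stem3", 1, 3, ws)
    p <- add_incep4(p, "e1", 3, wb[1])
    p <- add_incep4(p, "e2", c1 + ws, wb[2])
    p <- add_incep4(p, "e3", c2 + ws, wb[3])
    p <- add_incep4(p, "e4", c3, wb[4])
    p <- add_incep4(p, "e5", c4, wb[5])
    p <- add_conv_bn(p, "d5", 3, c5, wb[4])
    p <- nn_param_tconv(p, "u4", wb[4], wb[4])
    p <- add_conv_bn(p, "d4", 3, wb[4] + c4, wb[3])
    p <- nn_param_tconv(p, "u3", wb[3], wb[3])
    p <- add_conv_bn(p, "d3", 3, wb[3] + c3, wb[2])
    p <- nn_param_tconv(p, "u2", wb[2], wb[2])
    p <- add_conv_bn(p, "d2", 3, wb[2] + c2, wb[1])
    p <- nn_param_tconv(p, "u1", wb[1], wb[1])
    p <- add_conv_bn(p, "d1", 3, wb[1] + c1, wb[1])
    p <- nn_param_conv(p, "head", 1, wb[1], 1)
    p <- nn_param_conv(p, "aux1", 1, wb[1], 1)  # 1/2 resolution
    p <- nn_param_conv(p, "aux2", 1, wb[2], 1)  # 1/4
    p <- nn_param_conv(p, "aux3", 1, wb[3], 1)  # 1/8
    structure(list(params = p, config = config,
                   arch = list(wb = wb, ws = ws,
                               ch = c(c1, c2, c3, c4, c5))),
              class = "imnet_model")
  })
}

# forward graph; x is a normalised (H,W,3) array with H, W divisible by 16.
# Returns tape + logit node ids for the main and auxiliary outputs.
imnet_forward <- function(model, x) {
  tp <- tape_new()
  ids <- nn_leaves(tp, model$params)
  x2 <- downsample2(x, 1)
  x4 <- downsample2(x, 2)
  xi <- tp_leaf(tp, x)
  e1 <- t_incep4(tp, xi, ids, "e1", 3)
  s2 <- t_conv_bn_relu(tp, tp_leaf(tp, x2), ids, "stem2")
  e2 <- t_incep4(tp, t_concat(tp, c(t_avgpool(tp, e1), s2)), ids, "e2",
                 model$arch$ch[1] + model$arch$ws)
  s3 <- t_conv_bn_relu(tp, tp_leaf(tp, x4), ids, "stem3")
  e3 <- t_incep4(tp, t_concat(tp, c(t_avgpool(tp, e2), s3)), ids, "e3",
                 model$arch$ch[2] + model$arch$ws)
  e4 <- t_incep4(tp, t_avgpool(tp, e3), ids, "e4", model$arch$ch[3])
  e5 <- t_incep4(tp, t_avgpool(tp, e4), ids, "e5", model$arch$ch[4])
  d5 <- t_conv_bn_relu(tp, e5, ids, "d5")
  u4 <- t_tconv(tp, d5, ids[["u4.w"]], ids[["u4.b"]])
  d4 <- t_conv_bn_relu(tp, t_concat(tp, c(u4, e4)), ids, "d4")
  u3 <- t_tconv(tp, d4, ids[["u3.w"]], ids[["u3.b"]])
  d3 <- t_conv_bn_relu(tp, t_concat(tp, c(u3, e3)), ids, "d3")
  u2 <- t_tconv(tp, d3, ids[["u2.w"]], ids[["u2.b"]])
  d2 <- t_conv_bn_relu(tp, t_concat(tp, c(u2, e2)), ids, "d2")
  u1 <- t_tconv(tp, d2, ids[["u1.w"]], ids[["u1.b"]])
  d1 <- t_conv_bn_relu(tp, t_concat(tp, c(u1, e1)), ids, "d1")
  main <- t_conv(tp, d1, ids[["head.w"]], ids[["head.b"]])
  a1 <- t_conv(tp, d2, ids[["aux1.w"]], ids[["aux1.b"]])
  a2 <- t_conv(tp, d3, ids[["aux2.w"]], ids[["aux2.b"]])
  a3 <- t_conv(tp, d4, ids[["aux3.w"]], ids[["aux3.b"]])
  list(tp = tp, ids = ids, main = main, aux = c(a1, a2, a3))
}

#' Boundary weight map for duct segmentation training
#'
#' Per-pixel training weights emphasising weak duct boundaries:
#' `w(x) = balance(x) + w0 * exp(-d(x)^2 / (2 sigma^2))`, where `d(x)` is
#' the distance to the nearest duct boundary pixel and `balance` is the
#' inverse-frequency class-balance term (foreground and background each
#' normalised to carry half the total weight). An empty (single-class) mask
#' yields uniform unit balance.
#'
#' @param gt_mask binary matrix.
#' @param w0 boundary emphasis amplitude (default 2).
#' @param sigma boundary decay scale in px (default 5).
#' @return numeric weight matrix, same shape.
#' @export
boundaryWeightMap <- function(gt_mask, w0 = 2, sigma = 5) {
  g <- gt_mask > 0
  n <- length(g)
  nf <- sum(g)
  if (nf == 0 || nf == n) return(matrix(1, nrow(g), ncol(g))) # single class
  base <- matrix(n / (2 * (n - nf)), nrow(g), ncol(g))
  base[g] <- n / (2 * nf)
  # boundary = foreground pixels 4-adjacent to background
  er <- g
  er[2:nrow(g), ] <- er[2:nrow(g), ] & g[1:(nrow(g) - 1), ]
  er[1:(nrow(g) - 1), ] <- er[1:(nrow(g) - 1), ] & g[2:nrow(g), ]
  er[, 2:ncol(g)] <- er[, 2:ncol(g)] & g[, 1:(ncol(g) - 1)]
  er[, 1:(ncol(g) - 1)] <- er[, 1:(ncol(g) - 1)] & g[, 2:ncol(g)]
  boundary <- g & !er
  d <- as.matrix(EBImage::distmap(matrix(as.numeric(!boundary), nrow(g))))
  base + w0 * exp(-d^2 / (2 * sigma^2))
}

wbce_prob <- function(p, t, w) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  sum(w * -(t * log(p) + (1 - t) * log(1 - p))) / length(p)
}

#' Multi-output boundary-weighted cross-entropy loss
#'
#' `loss = wCE(main, target) + lambda * sum_i wCE(aux_i, target_i)` where
#' the auxiliary targets are the ground truth average-pooled to each
#' auxiliary resolution and the auxiliary weight maps are recomputed on the
#' (re-thresholded) resized targets. Linear in the weight map; zero when
#' predictions saturate at the target.
#'
#' @param main main-output probability map (matrix, values in `[0, 1]`).
#' @param aux_maps list of auxiliary probability maps at power-of-two
#'   reduced resolutions.
#' @param target binary ground-truth matrix at main resolution.
#' @param weight_map weight matrix at main resolution
#'   (see [boundaryWeightMap()]).
#' @param lambda auxiliary loss weight.
#' @param w0,sigma passed on to the recomputed auxiliary weight maps.
#' @return scalar loss.
#' @export
imnetLoss <- function(main, aux_maps, target, weight_map, lambda,
                      w0 = 2, sigma = 5) {
  if (anyNA(main) || any(vapply(aux_maps, anyNA, TRUE)))
    stop("NaN in predictions")
  loss <- wbce_prob(main, target, weight_map)
  for (a in aux_maps) {
    k <- as.integer(round(log2(nrow(target) / nrow(a))))
    t_a <- (downsample2_mat(target, k) > 0.5) * 1 # re-binarised at aux scale
    w_a <- boundaryWeightMap(t_a, w0, sigma)
    loss <- loss + lambda * wbce_prob(a, t_a, w_a)
  }
  loss
}

#' Paired augmentation of a patch and its mask
#'
#' Applies one random draw of flip / 90-degree rotation / isotropic scaling
#' / Gaussian blur / barrel-pincushion distortion. The identical spatial
#' transform is applied to patch and mask (blur to the image only); with all
#' probabilities zero the inputs are returned unchanged.
#'
#' @param patch `(H, W, 3)` array.
#' @param mask matrix (binary or labels; resampled nearest).
#' @param p named list of probabilities and ranges: `flip`, `rot`, `scale`,
#'   `scale_range`, `blur`, `blur_sigma`, `distort`, `distort_k`.
#' @return list `(patch, mask)`.
#' @export
augmentPair <- function(patch, mask,
                        p = list(flip = 0.5, rot = 0.5, scale = 0.3,
                                 scale_range = c(0.9, 1.1), blur = 0.3,
                                 blur_sigma = c(0.5, 1.2), distort = 0.3,
                                 distort_k = c(-0.08, 0.08))) {
  H <- dim(patch)[1]; W <- dim(patch)[2]
  if (stats::runif(1) < p$flip) {
    if (stats::runif(1) < 0.5) {
      patch <- patch[H:1, , , drop = FALSE]; mask <- mask[H:1, , drop = FALSE]
    } else {
      patch <- patch[, W:1, , drop = FALSE]; mask <- mask[, W:1, drop = FALSE]
    }
  }
  if (stats::runif(1) < p$rot) {
    k <- sample(1:3, 1)
    for (i in seq_len(k)) {
      patch <- aperm(patch, c(2, 1, 3))[dim(patch)[2]:1, , , drop = FALSE]
      mask <- t(mask)[ncol(mask):1, , drop = FALSE]
    }
  }
  remap <- NULL
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  gy <- matrix(rep(0:(H - 1), W), H, W)
  gx <- matrix(rep(0:(W - 1), each = H), H, W)
  if (stats::runif(1) < p$scale) {
    s <- stats::runif(1, p$scale_range[1], p$scale_range[2])
    remap <- list(y = cy + (gy - cy) / s, x = cx + (gx - cx) / s)
  }
  if (stats::runif(1) < p$distort) {
    k <- stats::runif(1, p$distort_k[1], p$distort_k[2])
    ry <- (if (is.null(remap)) gy else remap$y) - cy
    rx <- (if (is.null(remap)) gx else remap$x) - cx
    rn2 <- (ry^2 + rx^2) / max(cy, cx)^2
    remap <- list(y = cy + ry * (1 + k * rn2), x = cx + rx * (1 + k * rn2))
  }
  if (!is.null(remap)) {
    patch <- cpp_remap_bilinear(patch, remap$y, remap$x)
    mm <- cpp_remap_bilinear(array(mask, dim = c(H, W, 1)), remap$y, remap$x)
    mask <- matrix(as.numeric(mm > 0.5), H, W)
  }
  if (stats::runif(1) < p$blur) {
    s <- stats::runif(1, p$blur_sigma[1], p$blur_sigma[2])
    for (ch in 1:3) patch[, , ch] <- as.matrix(EBImage::gblur(patch[, , ch],
                                                              sigma = s))
  }
  list(patch = patch, mask = mask)
}

#' Train the duct segmentation network
#'
#' Scaled-down training loop: per epoch, a random crop of each training tile
#' is (optionally) augmented, standardised to zero mean / unit sd and passed
#' through the network; the boundary-weighted multi-output cross-entropy is
#' minimised with Adam under a stepped tenfold learning-rate decay.
#'
#' @param tiles list of [HistoTile-class] (or `(H, W, 3)` arrays).
#' @param masks list of binary duct masks matching `tiles`.
#' @param config from [imnetConfig()].
#' @param model optionally continue training an existing model.
#' @return trained model with a `history` element (mean epoch loss).
#' @export
trainImnet <- function(tiles, masks, config = imnetConfig(), model = NULL) {
  if (is.null(model)) model <- buildImnet(config)
  params <- model$params
  st <- adam_new(params)
  history <- numeric(0)
  with_seed(config$seed + 17L, {
    for (epoch in seq_len(config$epochs)) {
      lr <- config$lr0 / 10^((epoch - 1) %/% config$lr_decay_every)
      losses <- numeric(0)
      for (i in sample(seq_along(tiles))) {
        arr <- if (methods::is(tiles[[i]], "HistoTile"))
          tilePixels(tiles[[i]]) else tiles[[i]]
        msk <- masks[[i]] > 0
        cp <- config$crop_px
        if (nrow(msk) > cp) {
          r0 <- sample.int(nrow(msk) - cp + 1L, 1L)
          c0 <- sample.int(ncol(msk) - cp + 1L, 1L)
          arr <- arr[r0:(r0 + cp - 1), c0:(c0 + cp - 1), , drop = FALSE]
          msk <- msk[r0:(r0 + cp - 1), c0:(c0 + cp - 1)]
        }
        if (config$augment) {
          au <- augmentPair(arr, msk)
          arr <- au$patch; msk <- au$mask > 0
        }
        x <- normalize_patch(arr)
        fw <- imnet_forward(model, x)
        w <- boundaryWeightMap(msk, config$w0, config$sigma)
        target <- matrix(as.numeric(msk), nrow(msk))
        lmain <- t_wbce(fw$tp, fw$main, target, w)
        lnodes <- c(lmain)
        for (a in fw$aux) {
          av <- tp_value(fw$tp, a)
          k <- as.integer(round(log2(nrow(target) / dim(av)[1])))
          t_a <- (downsample2_mat(target, k) > 0.5) * 1
          w_a <- boundaryWeightMap(t_a, config$w0, config$sigma)
          lnodes <- c(lnodes, t_wbce(fw$tp, a, t_a, w_a))
        }
        loss <- t_add_scalar(fw$tp, as.list(lnodes),
                             c(1, rep(config$aux_loss_weight, 3)))
        losses <- c(losses, tp_value(fw$tp, loss))
        g <- nn_grads(fw$tp, loss, fw$ids)
        upd <- adam_step(params, g, st, lr)
        params <- upd$params
        st <- upd$state
        model$params <- params
      }
      history <- c(history, mean(losses))
    }
  })
  model$history <- history
  model
}

#' Duct probability map for a tile
#'
#' Standardises the tile, reflection-pads to a multiple of 16 and runs the
#' network; tiles larger than `window` px are processed by sliding-window
#' inference with overlapping windows whose probabilities are averaged.
#'
#' @param model a trained `imnet_model`.
#' @param tile a [HistoTile-class] or `(H, W, 3)` array.
#' @param window sliding-window side (default 512).
#' @param overlap window overlap in px (default 64).
#' @return probability matrix in the tile frame.
#' @export
predictDuctProbability <- function(model, tile, window = 512L,
                                   overlap = 64L) {
  arr <- if (methods::is(tile, "HistoTile")) tilePixels(tile) else tile
  H <- dim(arr)[1]; W <- dim(arr)[2]
  x <- normalize_patch(arr)
  if (H <= window && W <= window) return(imnet_infer(model, x, H, W))
  acc <- matrix(0, H, W); cnt <- matrix(0, H, W)
  step <- window - overlap
  r0s <- unique(pmin(seq(1, H, by = step), max(H - window + 1, 1)))
  c0s <- unique(pmin(seq(1, W, by = step), max(W - window + 1, 1)))
  for (r0 in r0s) for (c0 in c0s) {
    r1 <- min(r0 + window - 1, H); c1 <- min(c0 + window - 1, W)
    pr <- imnet_infer(model, x[r0:r1, c0:c1, , drop = FALSE],
                      r1 - r0 + 1, c1 - c0 + 1)
    acc[r0:r1, c0:c1] <- acc[r0:r1, c0:c1] + pr
    cnt[r0:r1, c0:c1] <- cnt[r0:r1, c0:c1] + 1
  }
  acc / cnt
}

imnet_infer <- function(model, x, H, W) {
  pd <- pad_to_multiple(x, 16L)
  fw <- imnet_forward(model, pd$x)
  logit <- tp_value(fw$tp, fw$main)
  prob <- 1 / (1 + exp(-logit[, , 1]))
  prob[1:H, 1:W, drop = FALSE]
}

#' Componentise a duct probability map into a DuctSet
#'
#' Thresholds the probability map (restricted to the tissue mask when
#' given), labels 8-connected components, and derives one duct per
#' component: outer-contour polygon, centroid, pixel and micron areas and a
#' border flag. A ground-truth binary mask can be fed directly as the
#' "probabilities". Epithelial counts and kept flags are attached later by
#' [filterDucts()].
#'
#' @param prob probability matrix in `[0, 1]` (or a binary mask).
#' @param mpp microns per pixel of the map's frame.
#' @param tissue_mask optional logical matrix restricting valid area.
#' @param prob_threshold threshold (default 0.5).
#' @return A [DuctSet-class].
#' @export
segmentDucts <- function(prob, mpp, tissue_mask = NULL,
                         prob_threshold = 0.5) {
  m <- prob >= prob_threshold
  if (!is.null(tissue_mask)) m <- m & (tissue_mask > 0)
  lab <- cpp_label8(m)
  n <- max(lab)
  polys <- list()
  if (n == 0) {
    ducts <- data.frame(id = integer(0), centroid_x = numeric(0),
                        centroid_y = numeric(0), area_px = integer(0),
                        area_um2 = numeric(0), n_epithelial = NA_integer_[0],
                        kept = logical(0), on_border = logical(0))
    return(new("DuctSet", ducts = ducts, polygons = polys, labelMask = lab,
               mpp = mpp))
  }
  oc <- EBImage::ocontour(lab)
  rows <- data.frame(id = seq_len(n), centroid_x = NA_real_,
                     centroid_y = NA_real_, area_px = NA_integer_,
                     area_um2 = NA_real_, n_epithelial = NA_integer_,
                     kept = NA, on_border = NA)
  H <- nrow(lab); W <- ncol(lab)
  idx <- which(lab > 0)
  lv <- lab[idx]
  rr <- ((idx - 1) %% H) + 1
  cc <- ((idx - 1) %/% H) + 1
  for (k in seq_len(n)) {
    sel <- lv == k
    rows$area_px[k] <- sum(sel)
    rows$centroid_x[k] <- mean(cc[sel]) - 1
    rows$centroid_y[k] <- mean(rr[sel]) - 1
    rows$area_um2[k] <- rows$area_px[k] * mpp^2
    rows$on_border[k] <- any(rr[sel] %in% c(1L, H)) ||
      any(cc[sel] %in% c(1L, W))
    ctr <- oc[[as.character(k)]]
    if (is.null(ctr)) ctr <- oc[[k]]
    # ocontour: 0-based (dim1, dim2) = (row, col); polygons are (x, y)
    polys[[k]] <- cbind(x = ctr[, 2], y = ctr[, 1])
  }
  new("DuctSet", ducts = rows, polygons = polys, labelMask = lab, mpp = mpp)
}

#' Apply the epithelial-count duct filter
#'
#' Counts classified epithelial cells whose centre falls inside each duct
#' (mask membership, so boundary cells count) and keeps ducts with at least
#' `min_epithelial` of them.
#'
#' @param ducts a [DuctSet-class].
#' @param cells data.frame with `x_px`, `y_px`, `class`.
#' @param min_epithelial minimum epithelial cells for `kept` (default 10).
#' @return the [DuctSet-class] with `n_epithelial` and `kept` filled in.
#' @export
filterDucts <- function(ducts, cells, min_epithelial = 10) {
  dt <- ductTable(ducts)
  if (nrow(dt) == 0) return(ducts)
  epi <- cells[cells$class == "epithelial", , drop = FALSE]
  counts <- integer(nrow(dt))
  if (nrow(epi)) {
    lab <- duct_label_at(ducts, epi$x_px, epi$y_px)
    tab <- table(factor(lab, levels = dt$id))
    counts <- as.integer(tab)
  }
  dt$n_epithelial <- counts
  dt$kept <- counts >= min_epithelial
  ducts@ducts <- dt
  ducts
}
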