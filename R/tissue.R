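# Tissue-vs-background segmentation at the low-resolution working frame
# (x1.25 equivalent, i.e. ~8 um/px for a x20 0.5 um/px scan), with an Otsu
# threshold baseline for comparison.

#' Configuration for the tissue segmentation network
#'
#' @param patch_size training patch size (divisible by 8).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs training epochs (default 50).
#' @param validation_fraction held-out fraction during training.
#' @param width_multiplier channel-width scaling of base widths
#'   (16, 32, 64, 128).
#' @param target_mpp microns per pixel of the working frame; tiles are
#'   resampled to this before inference (default 8, the x1.25-equivalent of
#'   a x20 scan at 0.5 um/px).
#' @param seed RNG seed.
#' @return config list.
#' @export
tissueNetConfig <- function(patch_size = 512L, learning_rate = 0.001,
                            epochs = 50L, validation_fraction = 0.20,
                            width_multiplier = 0.25, target_mpp = 8.0,
                            seed = 1L) {
  stopifnot(patch_size %% 8 == 0, validation_fraction > 0,
            validation_fraction < 1)
  list(patch_size = as.integer(patch_size), learning_rate = learning_rate,
       epochs = as.integer(epochs),
       validation_fraction = validation_fraction,
       width_multiplier = width_multiplier, target_mpp = target_mpp,
       seed = as.integer(seed))
}

#' Build the tissue segmentation model
#'
#' A plain depth-4 encoder-decoder (three poolings) with skip connections,
#' same-padding convolutions and a sigmoid head.
#'
#' @param config from [tissueNetConfig()].
#' @return model object (class `"tissue_model"`).
#' @export
buildTissueNet <- function(config = tissueNetConfig()) {
  wb <- pmax(2L, as.integer(round(c(16, 32, 64, 128) *
                                  config$width_multiplier)))
  # no per-channel normalisation here: tissue-vs-background hinges on
  # absolute stain level, which instance-style norms would erase on
  # near-uniform tiles
  with_seed(config$seed, {
    p <- list()
    p <- nn_param_conv(p, "e1", 3, 3, wb[1])
    p <- nn_param_conv(p, "e2", 3, wb[1], wb[2])
    p <- nn_param_conv(p, "e3", 3, wb[2], wb[3])
    p <- nn_param_conv(p, "e4", 3, wb[3], wb[4])
    p <- nn_param_tconv(p, "u3", wb[4], wb[3])
    p <- nn_param_conv(p, "d3", 3, 2 * wb[3], wb[3])
    p <- nn_param_tconv(p, "u2", wb[3], wb[2])
    p <- nn_param_conv(p, "d2", 3, 2 * wb[2], wb[2])
    p <- nn_param_tconv(p, "u1", wb[2], wb[1])
    p <- nn_param_conv(p, "d1", 3, 2 * wb[1], wb[1])
    p <- nn_param_conv(p, "head", 1, wb[1], 1)
    structure(list(params = p, config = config, wb = wb,
                   norm = list(mean = rep(0.5, 3), sd = rep(0.25, 3))),
              class = "tissue_model")
  })
}

# normalisation with dataset-level statistics: tissue-vs-background depends
# on absolute stain brightness, so per-tile standardisation (which maps a
# uniform white tile and a uniform pink tile to the same input) is not
# usable here; the training-set channel mean/sd are stored in the model
normalize_fixed <- function(arr, norm) {
  for (ch in 1:3) arr[, , ch] <- (arr[, , ch] - norm$mean[ch]) / norm$sd[ch]
  arr
}

tissue_conv_relu <- function(tp, x, ids, name) {
  t_relu(tp, t_conv(tp, x, ids[[paste0(name, ".w")]],
                    ids[[paste0(name, ".b")]]))
}

tissue_forward <- function(model, x) {
  tp <- tape_new()
  ids <- nn_leaves(tp, model$params)
  e1 <- tissue_conv_relu(tp, tp_leaf(tp, x), ids, "e1")
  e2 <- tissue_conv_relu(tp, t_avgpool(tp, e1), ids, "e2")
  e3 <- tissue_conv_relu(tp, t_avgpool(tp, e2), ids, "e3")
  e4 <- tissue_conv_relu(tp, t_avgpool(tp, e3), ids, "e4")
  d3 <- tissue_conv_relu(tp, t_concat(tp, c(
    t_tconv(tp, e4, ids[["u3.w"]], ids[["u3.b"]]), e3)), ids, "d3")
  d2 <- tissue_conv_relu(tp, t_concat(tp, c(
    t_tconv(tp, d3, ids[["u2.w"]], ids[["u2.b"]]), e2)), ids, "d2")
  d1 <- tissue_conv_relu(tp, t_concat(tp, c(
    t_tconv(tp, d2, ids[["u1.w"]], ids[["u1.b"]]), e1)), ids, "d1")
  main <- t_conv(tp, d1, ids[["head.w"]], ids[["head.b"]])
  list(tp = tp, ids = ids, main = main)
}

#' Train the tissue segmentation network
#'
#' Tiles are standardised ("mean normalisation") and trained full-frame with
#' unweighted cross-entropy; a `validation_fraction` of the tiles is held
#' out and its DICE recorded each epoch.
#'
#' @param tiles list of [HistoTile-class] or arrays, already at the working
#'   resolution, sides divisible by 8.
#' @param masks list of binary tissue masks.
#' @param config from [tissueNetConfig()].
#' @return trained model with `history` (epoch loss) and `val_dice`.
#' @export
trainTissueNet <- function(tiles, masks, config = tissueNetConfig()) {
  model <- buildTissueNet(config)
  params <- model$params
  st <- adam_new(params)
  n <- length(tiles)
  with_seed(config$seed + 5L, {
    nval <- max(1L, round(config$validation_fraction * n))
    val_idx <- sample(n, nval)
    tr_idx <- setdiff(seq_len(n), val_idx)
    history <- numeric(0); val_dice <- numeric(0)
    arrs <- lapply(tiles, function(t)
      if (methods::is(t, "HistoTile")) tilePixels(t) else t)
    tr_stack <- sapply(1:3, function(ch)
      unlist(lapply(arrs[tr_idx], function(a) as.vector(a[, , ch]))))
    model$norm <- list(mean = colMeans(tr_stack),
                       sd = pmax(apply(tr_stack, 2, stats::sd), 1e-3))
    for (epoch in seq_len(config$epochs)) {
      losses <- numeric(0)
      for (i in sample(tr_idx)) {
        x <- normalize_fixed(arrs[[i]], model$norm)
        fw <- tissue_forward(model, x)
        target <- matrix(as.numeric(masks[[i]] > 0), nrow(masks[[i]]))
        loss <- t_wbce(fw$tp, fw$main, target, 1)
        losses <- c(losses, tp_value(fw$tp, loss))
        g <- nn_grads(fw$tp, loss, fw$ids)
        upd <- adam_step(params, g, st, config$learning_rate)
        params <- upd$params; st <- upd$state
        model$params <- params
      }
      history <- c(history, mean(losses))
      dv <- vapply(val_idx, function(i) {
        pr <- tissue_infer(model, arrs[[i]])
        d <- segMetrics(pr > 0.5, masks[[i]] > 0)$dice
        if (is.na(d)) 1 else d
      }, 0)
      val_dice <- c(val_dice, mean(dv))
    }
    model$history <- history
    model$val_dice <- val_dice
  })
  model
}

tissue_infer <- function(model, x, margin = 8L) {
  x <- normalize_fixed(x, model$norm)
  # reflect-pad a margin to suppress border convolution artifacts
  margin <- min(margin, dim(x)[1] - 1L, dim(x)[2] - 1L)
  x <- pad_reflect(x, margin, margin, margin, margin)
  pd <- pad_to_multiple(x, 8L)
  fw <- tissue_forward(model, pd$x)
  logit <- tp_value(fw$tp, fw$main)
  prob <- 1 / (1 + exp(-logit[, , 1]))
  prob[margin + seq_len(pd$H - 2 * margin),
       margin + seq_len(pd$W - 2 * margin), drop = FALSE]
}

#' Segment tissue on a tile
#'
#' Resamples the tile to the model's working resolution (`target_mpp`),
#' standardises it, runs the network and maps the thresholded mask back to
#' the tile frame. Tiles smaller than 8 px after resampling are
#' reflection-padded with a warning.
#'
#' @param tile a [HistoTile-class].
#' @param model a trained `tissue_model`.
#' @return logical mask in the tile frame.
#' @export
segmentTissue <- function(tile, model) {
  arr <- tilePixels(tile)
  H <- dim(arr)[1]; W <- dim(arr)[2]
  f <- tileMpp(tile) / model$config$target_mpp
  h2 <- max(1L, round(H * f)); w2 <- max(1L, round(W * f))
  small <- arr
  if (h2 != H || w2 != W)
    small <- as.array(EBImage::resize(EBImage::Image(arr, colormode = "Color"),
                                      w = h2, h = w2))
  dim(small) <- c(h2, w2, 3)
  if (h2 < 8 || w2 < 8) {
    warning("tile smaller than the network receptive field; padding")
    small <- pad_reflect(small, 0, max(0, 8 - h2), 0, max(0, 8 - w2))
  }
  pr <- tissue_infer(model, small)
  pr <- pr[seq_len(min(h2, nrow(pr))), seq_len(min(w2, ncol(pr))),
           drop = FALSE]
  msk <- pr > 0.5
  if (h2 != H || w2 != W) {
    up <- as.matrix(EBImage::resize(EBImage::Image(msk * 1), w = H, h = W,
                                    filter = "none"))
    msk <- up > 0.5
  }
  msk
}

#' Threshold baseline for tissue segmentation
#'
#' Otsu's threshold on a tissue-ness transform `max(saturation, 1 - value)`
#' of the RGB tile: white background scores ~0 and any stained or dark
#' region scores high. Used only as an evaluation baseline.
#'
#' @param tile a [HistoTile-class].
#' @return logical mask in the tile frame.
#' @export
thresholdBaseline <- function(tile) {
  arr <- tilePixels(tile)
  mx <- pmax(arr[, , 1], arr[, , 2], arr[, , 3])
  mn <- pmin(arr[, , 1], arr[, , 2], arr[, , 3])
  sat <- ifelse(mx > 1e-6, (mx - mn) / mx, 0)
  score <- pmax(sat, 1 - mx)
  if (diff(range(score)) < 1e-3) return(score > 0.5)
  th <- EBImage::otsu(EBImage::Image(score), range = c(0, 1))
  score > th
}
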