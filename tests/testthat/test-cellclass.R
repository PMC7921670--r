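# Cell classification: ensemble aggregation properties, the lymphocyte%
# summary, and a scaled-down benchmark on synthetic held-out tiles.

test_that("K = 0 reduces to the single-patch softmax", {
  tt <- fx_small_tile(31L)
  cfg0 <- cellClassifierConfig(n_neighbors = 0L, seed = 3L)
  m <- buildCellClassifier(config = cfg0)
  ctr <- data.frame(x_px = c(30, 60), y_px = c(40, 80))
  out <- classifyCells(tt$tile, ctr, m)
  env <- asNamespace("ductscape")
  px <- env$extract_patch(tilePixels(tt$tile), 30, 40, 28L)
  fw <- env$cellclass_forward(m, env$normalize_patch(px))
  p <- env$softmax(env$tp_value(fw$tp, fw$logits))
  expect_equal(unlist(out[1, paste0("posterior_", m$classes)]), p,
               ignore_attr = TRUE)
  # posteriors sum to one and argmax equals the assigned class
  ps <- as.matrix(out[, paste0("posterior_", m$classes)])
  expect_equal(rowSums(ps), c(1, 1), tolerance = 1e-9)
  expect_equal(m$classes[apply(ps, 1, which.max)], out$class)
})

test_that("permuting centroids permutes records but not assignments", {
  tt <- fx_small_tile(31L)
  m <- buildCellClassifier(config = cellClassifierConfig(seed = 3L))
  ctr <- data.frame(x_px = c(20, 50, 90, 64), y_px = c(25, 70, 40, 100))
  out1 <- classifyCells(tt$tile, ctr, m)
  perm <- c(3, 1, 4, 2)
  out2 <- classifyCells(tt$tile, ctr[perm, ], m)
  expect_equal(out2$class, out1$class[perm])
  expect_equal(out2$posterior_epithelial, out1$posterior_epithelial[perm])
})

test_that("lymphocyte percentage follows the all-cells definition", {
  cells <- data.frame(class = c(rep("epithelial", 5), "stromal",
                                rep("lymphocyte", 2)))
  expect_equal(lymphocyteFraction(cells), 25)
  expect_equal(lymphocyteFraction(data.frame(class = rep("lymphocyte", 4))),
               100)
  expect_equal(lymphocyteFraction(data.frame(class = rep("stromal", 9))), 0)
  expect_error(lymphocyteFraction(data.frame(class = character(0))),
               "empty")
  # IHC: positive% counts only the stain-positive class
  ihc <- data.frame(class = c("epithelial", "lymphocyte_pos",
                              "lymphocyte_neg", "stromal"))
  expect_equal(lymphocyteFraction(ihc), 50)
  expect_equal(lymphocyteFraction(ihc, classes = "lymphocyte_pos"), 25)
})

test_that("scaled-down training reaches balanced accuracy >= 0.85", {
  data <- lapply(1:12, function(i) generateTile(syntheticSpec(seed = 400 + i)))
  tiles <- lapply(data, `[[`, "tile")
  cells <- lapply(data, function(d) d$truth@cells)
  cfg <- cellClassifierConfig(epochs = 3L, per_class_per_epoch = 200L,
                              seed = 1L)
  m <- trainCellClassifier(tiles[1:10], cells[1:10], cfg)
  res <- do.call(rbind, lapply(11:12, function(i) {
    pred <- classifyCells(tiles[[i]],
                          data.frame(x_px = cells[[i]]$x_px,
                                     y_px = cells[[i]]$y_px), m)
    data.frame(truth = cells[[i]]$class, pred = pred$class)
  }))
  tab <- table(factor(res$truth, levels = m$classes),
               factor(res$pred, levels = m$classes))
  balanced <- mean(diag(prop.table(tab, 1)))
  expect_gte(balanced, 0.85)
})

test_that("IHC scheme trains with the four-class contract", {
  data <- lapply(1:4, function(i)
    renderIhcTile(small_spec(600L + i, lymphocyte_density = 2500)))
  tiles <- lapply(data, `[[`, "tile")
  cells <- lapply(data, function(d) d$truth@cells)
  cfg <- cellClassifierConfig(epochs = 2L, per_class_per_epoch = 60L,
                              seed = 2L)
  m <- trainCellClassifier(tiles[1:3], cells[1:3], cfg)
  expect_setequal(m$classes, c("epithelial", "lymphocyte_pos",
                               "lymphocyte_neg", "stromal"))
  pred <- classifyCells(tiles[[4]],
                        data.frame(x_px = cells[[4]]$x_px,
                                   y_px = cells[[4]]$y_px), m)
  expect_true(all(pred$class %in% m$classes))
  expect_equal(ncol(pred), 5 + length(m$classes))
})
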