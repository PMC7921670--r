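# Duct segmentation: architecture contracts, boundary weight map, the
# multi-output loss, paired augmentation, componentisation and the
# epithelial-count duct filter.

test_that("forward pass respects shape, range and determinism contracts", {
  m <- buildImnet(imnetConfig(seed = 2L))
  x <- array(0, dim = c(64, 64, 3))
  env <- asNamespace("ductscape")
  fw <- env$imnet_forward(m, x)
  main <- env$tp_value(fw$tp, fw$main)
  expect_equal(dim(main)[1:2], c(64, 64))
  prob <- 1 / (1 + exp(-main))
  expect_true(all(prob >= 0 & prob <= 1))
  # aux outputs upsample-able by integer factors
  for (a in fw$aux) {
    av <- env$tp_value(fw$tp, a)
    expect_equal(64 %% dim(av)[1], 0)
  }
  # repeated forward with the same weights and input is identical
  set.seed(7)
  x2 <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
  p1 <- env$imnet_infer(m, x2, 64, 64)
  p2 <- env$imnet_infer(m, x2, 64, 64)
  expect_identical(p1, p2)
})

test_that("config invariants are enforced", {
  expect_error(imnetConfig(input_size = 62))
  expect_error(imnetConfig(input_size = 32))
})

test_that("boundary weight map follows its distance-decay form", {
  empty <- boundaryWeightMap(matrix(0, 20, 20), w0 = 2, sigma = 5)
  expect_true(all(empty == empty[1, 1])) # constant for an empty mask
  g <- matrix(0, 40, 40)
  g[10:30, 10:30] <- 1
  w <- boundaryWeightMap(g, w0 = 2, sigma = 5)
  balance_fg <- length(g) / (2 * sum(g))
  # a pixel on the duct boundary carries balance + w0
  expect_equal(w[10, 20], balance_fg + 2, tolerance = 1e-9)
  # weight decreases monotonically with distance from the boundary along rays
  expect_true(all(diff(w[20, 30:20]) <= 1e-12)) # inward ray from col-30 edge
  expect_true(all(diff(w[10:2, 20]) <= 1e-12))  # outward ray
  expect_true(all(is.finite(w)) && all(w > 0))
})

test_that("multi-output loss is zero at saturation and linear in weights", {
  g <- matrix(0, 16, 16); g[5:12, 5:12] <- 1
  w <- boundaryWeightMap(g)
  aux <- lapply(1:3, function(k) {
    t <- ductscape:::downsample2_mat(g, k)
    (t > 0.5) * 1
  })
  perfect <- imnetLoss(g, aux, g, w, lambda = 0.3)
  expect_lt(perfect, 1e-5)
  set.seed(1)
  p <- matrix(runif(256), 16, 16)
  pa <- lapply(1:3, function(k) matrix(runif((16 / 2^k)^2), 16 / 2^k))
  l0 <- imnetLoss(p, pa, g, w, lambda = 0)
  expect_equal(l0, ductscape:::wbce_prob(p, g, w)) # lambda 0 = main only
  # doubling the main weight map doubles the main term
  expect_equal(ductscape:::wbce_prob(p, g, 2 * w),
               2 * ductscape:::wbce_prob(p, g, w))
  expect_error(imnetLoss(matrix(NaN, 16, 16), pa, g, w, 0.3), "NaN")
})

test_that("augmentation transforms image and mask jointly", {
  tt <- fx_small_tile(21L)
  arr <- tilePixels(tt$tile)
  msk <- (tt$truth@ductMask > 0) * 1
  ident <- list(flip = 0, rot = 0, scale = 0, scale_range = c(1, 1),
                blur = 0, blur_sigma = c(1, 1), distort = 0,
                distort_k = c(0, 0))
  au <- augmentPair(arr, msk, ident)
  expect_identical(au$patch, arr)
  expect_identical(au$mask, msk)
  # flips are involutions and preserve duct pixel count
  flipped <- arr[128:1, , , drop = FALSE]
  expect_identical(flipped[128:1, , , drop = FALSE], arr)
  set.seed(5)
  rot_only <- list(flip = 1, rot = 1, scale = 0, scale_range = c(1, 1),
                   blur = 0, blur_sigma = c(1, 1), distort = 0,
                   distort_k = c(0, 0))
  au <- augmentPair(arr, msk, rot_only)
  expect_equal(sum(au$mask), sum(msk)) # flip/rot90 conserve mask sum
  expect_equal(dim(au$patch), dim(arr))
})

test_that("componentisation matches the connected-component oracle", {
  tt <- generateTile(syntheticSpec(n_ducts = 5L, seed = 7L))
  ds <- segmentDucts((tt$truth@ductMask > 0) * 1, mpp = 0.5)
  expect_equal(nrow(ductTable(ds)), 5)
  # centroids within 2 px of the true per-label centroids
  for (k in 1:5) {
    idx <- which(tt$truth@ductMask == k)
    cy <- mean(((idx - 1) %% 256)); cx <- mean(((idx - 1) %/% 256))
    row <- ductTable(ds)[order(ductTable(ds)$centroid_x), ]
    d <- min(sqrt((ductTable(ds)$centroid_x - cx)^2 +
                  (ductTable(ds)$centroid_y - cy)^2))
    expect_lt(d, 2)
  }
  # area conservation: per-duct areas sum to the thresholded foreground
  expect_equal(sum(ductTable(ds)$area_px), sum(tt$truth@ductMask > 0))
  # micron area via mpp^2
  expect_equal(ductTable(ds)$area_um2, ductTable(ds)$area_px * 0.25)
  # empty probability map yields zero ducts
  expect_equal(nrow(ductTable(segmentDucts(matrix(0, 32, 32), 0.5))), 0)
})

test_that("diagonally touching components merge under 8-connectivity", {
  m <- matrix(0, 10, 10)
  m[2:4, 2:4] <- 1
  m[5:7, 5:7] <- 1 # touches only at the (4,4)-(5,5) diagonal
  ds <- segmentDucts(m, 1)
  expect_equal(nrow(ductTable(ds)), 1)
})

test_that("tiles smaller than one window take the single-shot path", {
  m <- buildImnet(imnetConfig(seed = 3L))
  tt <- fx_small_tile(22L)
  env <- asNamespace("ductscape")
  direct <- env$imnet_infer(m, env$normalize_patch(tilePixels(tt$tile)),
                            128, 128)
  stitched <- predictDuctProbability(m, tt$tile, window = 512L)
  expect_identical(stitched, direct)
})

test_that("the epithelial-count filter drops below-10 ducts exactly", {
  dg <- make_duct_grid(3L, per_duct = 0L)
  ds <- segmentDucts(dg$mask, 1)
  nine <- data.frame(x_px = dg$centres[1, 1] + seq(-4, 4),
                     y_px = dg$centres[1, 2] + seq(-4, 4),
                     class = "epithelial")
  ten <- data.frame(x_px = dg$centres[2, 1] + seq(-4.5, 4.5),
                    y_px = dg$centres[2, 2] + seq(-4.5, 4.5),
                    class = "epithelial")
  ds <- filterDucts(ds, rbind(nine, ten))
  dt <- ductTable(ds)
  expect_equal(dt$n_epithelial, c(9L, 10L, 0L))
  expect_equal(dt$kept, c(FALSE, TRUE, FALSE))
})
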