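# Cell detection: proximity target, directed Hausdorff against brute
# force, the batch agreement metric, centroid extraction round-trips and
# architecture contracts.

test_that("forward pass respects shape, range and determinism", {
  env <- asNamespace("ductscape")
  m <- buildDrdin(drdinConfig(seed = 4L))
  set.seed(1)
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  p1 <- predictCellProbability(m, x)
  expect_equal(dim(p1), c(32, 32))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, predictCellProbability(m, x))
  # parameter count shrinks with the width multiplier
  n_par <- function(wm) sum(lengths(
    buildDrdin(drdinConfig(width_multiplier = wm, seed = 1L))$params))
  expect_true(n_par(0.5) < n_par(1) && n_par(1) < n_par(2))
})

test_that("proximity target has unit peaks with linear decay", {
  expect_equal(proximityTarget(cbind(numeric(0), numeric(0)), 8, 8, 3),
               matrix(0, 8, 8))
  t1 <- proximityTarget(cbind(5, 5), 11, 11, 4)
  expect_equal(t1[6, 6], 1)                      # value 1 at the centroid
  expect_equal(t1[6, 10], 0)                     # 0 at distance >= radius
  expect_equal(t1[6, 8], 1 - 2 / 4)              # linear decay
  # two centroids 2*radius apart: max-combined, two unit peaks, no summation
  t2 <- proximityTarget(cbind(c(3, 11), c(6, 6)), 13, 15, 4)
  ref <- pmax(proximityTarget(cbind(3, 6), 13, 15, 4),
              proximityTarget(cbind(11, 6), 13, 15, 4))
  expect_equal(t2, ref)
  expect_equal(sort(t2[t2 == 1], decreasing = TRUE), c(1, 1))
})

test_that("directed Hausdorff equals the brute-force double loop", {
  expect_equal(directedHausdorff(cbind(0, 0), cbind(3, 4)), 5)
  A <- cbind(0, 0); B <- rbind(c(0, 0), c(10, 0))
  expect_equal(directedHausdorff(A, B), 0)
  expect_equal(directedHausdorff(B, A), 10)
  expect_error(directedHausdorff(A[0, , drop = FALSE], B), "empty")
  brute <- function(A, B) {
    worst <- 0
    for (i in seq_len(nrow(A))) {
      best <- Inf
      for (j in seq_len(nrow(B)))
        best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
      worst <- max(worst, best)
    }
    worst
  }
  set.seed(11)
  for (rep in 1:25) {
    A <- matrix(runif(2 * sample(1:200, 1), 0, 50), ncol = 2)
    B <- matrix(runif(2 * sample(1:200, 1), 0, 50), ncol = 2)
    expect_equal(directedHausdorff(A, B), brute(A, B))
  }
})

test_that("batch Hausdorff metric follows the printed formula", {
  gt <- list(cbind(c(0, 5), c(0, 0)), cbind(c(1, 2), c(1, 2)))
  perfect <- hdBatchMetric(gt, gt)
  expect_equal(perfect$value, 1)  # zero differences give 1/(1+0)
  expect_equal(perfect$mean_symmetric, 0)
  # B = 1 with equal directed distances: differences cancel to 1
  a <- cbind(c(0, 2), 0); b <- cbind(c(0, -2), 0)
  expect_equal(directedHausdorff(a, b), directedHausdorff(b, a))
  expect_equal(hdBatchMetric(list(a), list(b))$value, 1)
  # |diffs| = {1, 3}: value = 1/(1+2) = 1/3
  p1 <- rbind(c(0, 0), c(1, 0)); g1 <- cbind(0, 0)  # HD_P 1, HD_g 0
  p2 <- rbind(c(0, 0), c(3, 0)); g2 <- cbind(0, 0)  # HD_P 3, HD_g 0
  m <- hdBatchMetric(list(p1, p2), list(g1, g2))
  expect_equal(m$value, 1 / 3, tolerance = 1e-12)
  # metric lies in (0, 1] and decreases with the mean difference
  expect_true(m$value > 0 && m$value <= 1)
  # empty prediction set uses the configured penalty
  em <- hdBatchMetric(list(p1[0, , drop = FALSE]), list(g1),
                      empty_penalty = 10)
  expect_equal(em$value, 1 / 11)
  expect_equal(em$n_empty, 1L)
  expect_error(hdBatchMetric(list(p1[0, , drop = FALSE]), list(g1)),
               "penalty")
})

test_that("centroid extraction round-trips proximity maps", {
  expect_equal(nrow(detectCentroids(matrix(0, 16, 16))), 0)
  # threshold above every value yields an empty list
  t1 <- proximityTarget(cbind(8, 8), 17, 17, 5)
  expect_equal(nrow(detectCentroids(t1, threshold = 1 + 1e-9)), 0)
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(3:7, 1)
    pts <- 15 + 14 * cbind(seq_len(n) * 2, sample(seq_len(n)) * 2) +
      matrix(runif(2 * n, -0.3, 0.3), ncol = 2)
    pm <- proximityTarget(pts, 250, 250, 6)
    det <- detectCentroids(pm, 0.8)
    expect_equal(nrow(det), n)
    m <- matchPointDetections(cbind(det$x_px, det$y_px), pts, radius_px = 1)
    expect_equal(m$tp, n) # every centroid recovered within 1 px
  }
})

test_that("smoke training reduces the loss and beats the untrained model", {
  data <- lapply(1:10, function(i) generateTile(small_spec(500L + i)))
  tiles <- lapply(data, `[[`, "tile")
  cells <- lapply(data, function(d) d$truth@cells)
  cfg <- drdinConfig(epochs = 3L, crop_px = 128L, seed = 2L)
  m <- trainDrdin(tiles[1:8], cells[1:8], cfg,
                  validation = list(tiles = tiles[9:10],
                                    cells = cells[9:10]))
  expect_lt(m$history[3], m$history[1]) # smoothed non-increase
  expect_true(all(is.finite(m$history)))
  hd_trained <- m$val_metrics[[3]]$mean_symmetric
  m0 <- buildDrdin(cfg)
  pred0 <- lapply(9:10, function(i) {
    d <- detectCentroids(predictCellProbability(m0, tiles[[i]]), 0.8)
    cbind(d$x_px, d$y_px)
  })
  gt <- lapply(9:10, function(i) cbind(cells[[i]]$x_px, cells[[i]]$y_px))
  hd_untrained <- hdBatchMetric(pred0, gt,
                                empty_penalty = sqrt(2) * 128)$mean_symmetric
  expect_lt(hd_trained, hd_untrained)
  # fixed seeds reproduce the final loss
  m2 <- trainDrdin(tiles[1:8], cells[1:8], cfg,
                   validation = list(tiles = tiles[9:10],
                                     cells = cells[9:10]))
  expect_equal(m2$history, m$history, tolerance = 1e-12)
})
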