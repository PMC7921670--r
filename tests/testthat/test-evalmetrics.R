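# Evaluation metrics: confusion-rate panel, point and object matching,
# group statistics.

test_that("segmentation metrics follow their closed forms", {
  g <- matrix(0, 10, 10); g[3:6, 3:6] <- 1
  perfect <- segMetrics(g, g)
  expect_equal(perfect$dice, 1)
  expect_equal(perfect$fpr, 0)
  expect_equal(perfect$fnr, 0)
  # TP=2, FP=1, FN=1 gives dice 4/6
  p <- matrix(c(1, 1, 1, 0), 2)
  q <- matrix(c(1, 1, 0, 1), 2)
  m <- segMetrics(p, q)
  expect_equal(m$dice, 2 / 3, tolerance = 1e-12)
  expect_equal(m$ppv, 2 / 3)
  expect_equal(m$tpr, 2 / 3)
  # both masks empty: dice undefined, tnr = 1
  z <- segMetrics(matrix(0, 4, 4), matrix(0, 4, 4))
  expect_true(is.na(z$dice))
  expect_equal(z$tnr, 1)
  expect_error(segMetrics(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  # overlay uses the four-colour legend
  ov <- m$overlay
  expect_equal(dim(ov), c(2, 2, 3))
  expect_equal(ov[1, 1, ], c(0, 0.8, 0))   # TP green
  expect_equal(ov[2, 2, ], c(1, 0, 1))     # FN magenta
})

test_that("dice equals the precision/recall harmonic mean on random masks", {
  set.seed(12)
  for (rep in 1:60) {
    a <- matrix(rbinom(400, 1, runif(1, 0.2, 0.8)), 20)
    b <- matrix(rbinom(400, 1, runif(1, 0.2, 0.8)), 20)
    m <- segMetrics(a, b)
    if (!is.na(m$ppv) && !is.na(m$tpr) && (m$ppv + m$tpr) > 0)
      expect_equal(m$dice, 2 * m$ppv * m$tpr / (m$ppv + m$tpr),
                   tolerance = 1e-12)
  }
})

test_that("point matching is greedy, one-to-one and bounded", {
  pts <- cbind(c(1, 5, 9), c(1, 5, 9))
  perfect <- matchPointDetections(pts, pts, 2)
  expect_equal(perfect$f1, 1)
  none <- matchPointDetections(pts[0, , drop = FALSE], pts, 2)
  expect_equal(none$recall, 0)
  expect_true(is.na(none$precision))
  expect_equal(none$f1, 0)
  # 3 gt, 2 pred within radius of distinct gt, 1 pred far
  gt <- cbind(c(0, 10, 20), 0)
  pred <- cbind(c(1, 11, 90), 0)
  m <- matchPointDetections(pred, gt, 3)
  expect_equal(c(m$tp, m$fp, m$fn), c(2, 1, 1))
  expect_equal(m$f1, 2 / 3, tolerance = 1e-9)
  # never double-counts: TP <= min(|pred|, |gt|)
  set.seed(13)
  for (rep in 1:20) {
    p <- matrix(runif(2 * sample(1:30, 1), 0, 20), ncol = 2)
    g <- matrix(runif(2 * sample(1:30, 1), 0, 20), ncol = 2)
    mm <- matchPointDetections(p, g, 3)
    expect_lte(mm$tp, min(nrow(p), nrow(g)))
    expect_equal(mm$tp + mm$fp, nrow(p))
    expect_equal(mm$tp + mm$fn, nrow(g))
  }
})

test_that("object-level duct matching applies the IoU threshold", {
  gt <- matrix(0L, 20, 20); gt[2:7, 2:7] <- 1L; gt[12:17, 12:17] <- 2L
  perfect <- ductDetectionPrf(gt, gt, 0.5)
  expect_equal(perfect$f1, 1)
  none <- matrix(0L, 20, 20); none[9:10, 9:10] <- 1L
  expect_equal(ductDetectionPrf(none, gt, 0.5)$f1, 0)
  # one pred overlapping one of two gt at IoU >= 0.5
  pred <- matrix(0L, 20, 20); pred[2:7, 3:8] <- 1L
  m <- ductDetectionPrf(pred, gt, 0.5)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 2 / 3, tolerance = 1e-9)
})

test_that("group comparison bands Cohen's d at the stated cut points", {
  same <- groupCompare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$cohens_d, 0)
  expect_equal(same$d_band, "small")
  # shifted constant-difference groups: d = shift / sd
  set.seed(14)
  base <- rnorm(200)
  g <- groupCompare(base + 1, base)
  expect_equal(g$cohens_d, 1 / sd(base), tolerance = 1e-9)
  # large-sample simulation: unit variance, means 0 and 1 -> d ~ 1
  a <- rnorm(4000, 1, 1); b <- rnorm(4000, 0, 1)
  sim <- groupCompare(a, b)
  expect_equal(sim$cohens_d, 1, tolerance = 0.1)
  expect_equal(sim$d_band, "large")
  expect_lt(sim$wilcoxon_p, 1e-10)
  # exact band edges
  expect_equal(cohensBand(0.2), "small")
  expect_equal(cohensBand(0.5), "medium")
  expect_equal(cohensBand(0.500001), "large")
  expect_equal(cohensBand(-0.7), "large")
  zero_sd <- groupCompare(c(2, 2, 2), c(2, 2, 2))
  expect_true(is.na(zero_sd$cohens_d))
})

test_that("Spearman correlation handles ties, signs and degeneracy", {
  expect_equal(spearmanCor(1:10, 1:10)$rho, 1)
  expect_equal(spearmanCor(1:10, 10:1)$rho, -1)
  expect_equal(spearmanCor(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8)
  expect_true(is.na(spearmanCor(c(1, 1, 1), c(1, 2, 3))$rho))
})
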