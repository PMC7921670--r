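# Synthetic-histology generator: ground-truth consistency, determinism,
# placement-mode geometry and cohort fixtures.

test_that("empty tile has no ducts and no epithelial cells", {
  tt <- generateTile(small_spec(3L, n_ducts = 0L))
  expect_true(all(tt$truth@ductMask == 0))
  expect_equal(sum(tt$truth@cells$class == "epithelial"), 0)
})

test_that("duct label mask has exactly the requested components", {
  tt <- generateTile(syntheticSpec(n_ducts = 5L, seed = 7L))
  lab <- ductscape:::cpp_label8(tt$truth@ductMask > 0)
  expect_equal(max(lab), 5)
  # labels contiguous 1..n and every epithelial duct id present in the mask
  expect_setequal(setdiff(unique(as.vector(tt$truth@ductMask)), 0), 1:5)
  epi <- tt$truth@cells[tt$truth@cells$class == "epithelial", ]
  expect_true(all(epi$duct %in% 1:5))
})

test_that("epithelial centroids lie inside their duct's mask component", {
  tt <- fx_small_tile(11L)
  epi <- tt$truth@cells[tt$truth@cells$class == "epithelial", ]
  lab <- tt$truth@ductMask[cbind(round(epi$y_px) + 1, round(epi$x_px) + 1)]
  expect_true(all(lab == epi$duct))
})

test_that("identical spec and seed reproduce byte-identical outputs", {
  a <- generateTile(small_spec(5L))
  b <- generateTile(small_spec(5L))
  expect_identical(a$tile@pixels, b$tile@pixels)
  expect_identical(a$truth@cells, b$truth@cells)
  expect_identical(a$truth@ductMask, b$truth@ductMask)
})

test_that("generator leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generateTile(small_spec(6L)))
  expect_identical(runif(1), before)
})

test_that("impossible geometry raises a placement error", {
  expect_error(generateTile(small_spec(1L, n_ducts = 40L)),
               "cannot place")
})

test_that("colocalised lymphocytes sit closer to ducts than dispersed ones", {
  dist_to_duct <- function(mode, seed) {
    tt <- generateTile(small_spec(seed, placement_mode = mode,
                                  lymphocyte_density = 3000))
    dm <- as.matrix(EBImage::distmap(
      matrix(as.numeric(tt$truth@ductMask == 0), 128)))
    ly <- tt$truth@cells[startsWith(tt$truth@cells$class, "lymphocyte"), ]
    dm[cbind(round(ly$y_px) + 1, round(ly$x_px) + 1)]
  }
  meds <- sapply(1:20, function(s) c(
    colocalised = median(dist_to_duct("colocalised", 40 + s)),
    dispersed = median(dist_to_duct("dispersed", 40 + s)),
    excluded = median(dist_to_duct("excluded", 40 + s))))
  med <- apply(meds, 1, median)
  expect_lt(med["colocalised"], med["dispersed"])
  expect_lt(med["dispersed"], med["excluded"])
  # mean colocalised distance strictly below dispersed on pooled draws
  expect_lt(mean(meds["colocalised", ]), mean(meds["dispersed", ]))
})

test_that("IHC positive fraction hits its 0 / 1 edges and binomial range", {
  t0 <- renderIhcTile(small_spec(8L, ihc_positive_fraction = 0))
  expect_equal(sum(t0$truth@cells$class == "lymphocyte_pos"), 0)
  t1 <- renderIhcTile(small_spec(8L, ihc_positive_fraction = 1))
  expect_equal(sum(t1$truth@cells$class == "lymphocyte_neg"), 0)
  th <- renderIhcTile(small_spec(9L, ihc_positive_fraction = 0.5,
                                 lymphocyte_density = 50000))
  ly <- th$truth@cells[startsWith(th$truth@cells$class, "lymphocyte"), ]
  n <- nrow(ly)
  pos <- sum(ly$class == "lymphocyte_pos")
  band <- qbinom(c(5e-4, 1 - 5e-4), n, 0.5) # 99.9% binomial interval
  expect_gte(pos, band[1])
  expect_lte(pos, band[2])
})

test_that("cohort writer produces a complete, regenerable fixture", {
  dir0 <- withr::local_tempdir()
  man <- generateCohort(0L, small_spec(1L), dir0)
  expect_equal(nrow(man), 0)
  expect_length(list.files(dir0, pattern = "png$"), 0)

  dir1 <- withr::local_tempdir()
  man <- generateCohort(3L, small_spec(1L), dir1,
                        modes = c("colocalised", "dispersed"))
  expect_equal(nrow(man), 6)
  expect_equal(anyDuplicated(man$seed), 0)
  expect_true(all(file.exists(file.path(dir1, man$tile))))
  # regeneration is byte-identical
  dir2 <- withr::local_tempdir()
  generateCohort(3L, small_spec(1L), dir2,
                 modes = c("colocalised", "dispersed"))
  for (f in man$tile)
    expect_identical(readBin(file.path(dir1, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6))
  # mask TIFF round-trips labels exactly
  m <- readLabelMaskTiff(file.path(dir1, man$mask[1]))
  tt <- generateTile({
    s <- small_spec(1L); s@placementMode <- man$mode[1]
    s@seed <- man$seed[1]; s
  })
  expect_identical(m, tt$truth@ductMask)
})

test_that("tissue fixture masks match their blanked regions", {
  fx <- generateTissueTile(small_spec(2L), "half")
  px <- tilePixels(fx$tile)
  expect_gt(mean(px[, , 1][!fx$mask]), 0.9) # blanked side is white
  expect_equal(dim(fx$mask), dim(px)[1:2])
  all_bg <- generateTissueTile(small_spec(2L), "all_background")
  expect_false(any(all_bg$mask))
})
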