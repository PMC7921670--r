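# The ecological core: compartment reclassification, invasive exclusion,
# Voronoi tessellation against the nearest-seed rule, quadrat counting and
# the Morisita-Horn score.

test_that("epithelial reclassification splits in-situ from other", {
  dg <- make_duct_grid(2L, per_duct = 12L)
  ds <- filterDucts(segmentDucts(dg$mask, 1), dg$cells)
  out <- reclassifyEpithelial(dg$cells, ds)
  epi <- out$class == "epithelial"
  expect_true(all(out$compartment[epi] == "in_situ"))
  expect_true(all(out$compartment[!epi] == "unassigned"))
  # without any duct every epithelial cell is "other"
  none <- segmentDucts(matrix(0, 300, 300), 1)
  out0 <- reclassifyEpithelial(dg$cells, none)
  expect_true(all(out0$compartment[epi] == "other"))
})

test_that("invasive blob cells are labelled other and excluded downstream", {
  tt <- generateTile(small_spec(71L, invasive_blob = TRUE,
                                invasive_cell_count = 50L,
                                lymphocyte_density = 3000))
  ds <- filterDucts(segmentDucts((tt$truth@ductMask > 0) * 1, 0.5),
                    tt$truth@cells)
  cells <- reclassifyEpithelial(tt$truth@cells, ds)
  epi <- cells$class == "epithelial"
  blob <- epi & is.na(tt$truth@cells$duct)
  expect_true(all(cells$compartment[blob] == "other"))
  expect_true(all(cells$compartment[epi & !blob] == "in_situ"))
  # exclusion region: empty without other-epithelium, discs otherwise
  none <- invasiveExclusionRegion(
    within(cells, compartment <- ifelse(compartment == "other",
                                        "in_situ", compartment)), 0.5)
  expect_equal(nrow(none$centres), 0)
  reg <- invasiveExclusionRegion(cells, 0.5, dilation_um = 25)
  expect_equal(nrow(reg$centres), sum(blob))
  expect_equal(reg$radius_um, 25)
  # lymphocytes inside the excluded blob appear in no quadrat unit
  tess <- tessellate(cbind(ductTable(ds)$centroid_x,
                           ductTable(ds)$centroid_y) * 0.5,
                     excluded = reg)
  asg <- assignCells(tess, cells, 0.5)
  kept_ly <- asg$cells[startsWith(asg$cells$class, "lymphocyte"), ]
  expect_false(any(ductscape:::in_excluded(
    cbind(kept_ly$x_um, kept_ly$y_um), reg)))
  tab <- quadratPartition(tess, asg, grid_um = 30)
  expect_equal(sum(tab$n_l), nrow(kept_ly))
  expect_gt(asg$dropped, 0) # the blob really removed cells
})

test_that("tessellation edge cases behave", {
  clip <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  one <- tessellate(cbind(4, 6), clip)
  expect_equal(ductscape:::polygon_area(one@regions[[1]]), 100)
  two <- tessellate(rbind(c(2, 5), c(8, 5)), clip)
  a1 <- ductscape:::polygon_area(two@regions[[1]])
  a2 <- ductscape:::polygon_area(two@regions[[2]])
  expect_equal(a1, 50) # bisector at x = 5 halves the box
  expect_equal(a2, 50)
  expect_true(all(two@regions[[1]][, 1] <= 5 + 1e-9))
  expect_error(tessellate(matrix(numeric(0), 0, 2), clip), "seed")
  expect_warning(tessellate(rbind(c(2, 2), c(2, 2), c(7, 7)), clip),
                 "coincident")
})

test_that("region membership equals brute-force nearest seed", {
  set.seed(33)
  for (rep in 1:15) {
    k <- sample(2:20, 1)
    seeds <- cbind(runif(k, 0, 100), runif(k, 0, 100))
    clip <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
    tess <- tessellate(seeds, clip)
    cells <- data.frame(x_px = runif(400, 0, 100),
                        y_px = runif(400, 0, 100), class = "lymphocyte")
    asg <- assignCells(tess, cells, mpp = 1)
    expect_equal(nrow(asg$cells), 400)
    expect_equal(asg$dropped, 0L)
    bf <- ductscape:::nearest_seed(cbind(cells$x_px, cells$y_px),
                                   tess@seeds, tess@seedIds)
    expect_identical(asg$cells$duct_region, bf)
  }
})

test_that("bisector ties go to the lower duct id", {
  clip <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  tess <- tessellate(rbind(c(2, 5), c(8, 5)), clip, seed_ids = c(4L, 2L))
  on_bis <- data.frame(x_px = 5, y_px = 3, class = "lymphocyte")
  asg <- assignCells(tess, on_bis, mpp = 1)
  expect_equal(asg$cells$duct_region, 2L) # equidistant: lower id wins
})

test_that("quadrat partition conserves counts and refines monotonically", {
  set.seed(44)
  seeds <- cbind(runif(6, 0, 100), runif(6, 0, 100))
  clip <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  tess <- tessellate(seeds, clip)
  cells <- data.frame(
    x_px = runif(300, 0, 100), y_px = runif(300, 0, 100),
    class = sample(c("lymphocyte", "epithelial"), 300, replace = TRUE))
  asg <- assignCells(tess, cells, mpp = 1)
  # grid larger than the clip region: units are the regions themselves
  tab_inf <- quadratPartition(tess, asg, grid_um = Inf)
  expect_equal(nrow(tab_inf), 6)
  tab_big <- quadratPartition(tess, asg, grid_um = 1000)
  expect_equal(nrow(tab_big), 6)
  tab <- quadratPartition(tess, asg, grid_um = 25)
  expect_equal(sum(tab$n_l),
               sum(startsWith(asg$cells$class, "lymphocyte")))
  expect_equal(sum(tab$n_e), sum(asg$cells$class == "epithelial"))
  # halving the grid never decreases the unit count
  tab2 <- quadratPartition(tess, asg, grid_um = 12.5)
  expect_gte(nrow(tab2), nrow(tab))
  # every retained cell appears in exactly one unit
  expect_equal(sum(tab$n_l) + sum(tab$n_e), nrow(asg$cells))
})

test_that("Morisita-Horn score has its closed-form values and bounds", {
  prop <- data.frame(n_l = c(2, 4, 6), n_e = c(1, 2, 3))
  expect_equal(morisitaScore(prop), 1) # proportional distributions
  disj <- data.frame(n_l = c(3, 0, 2), n_e = c(0, 7, 0))
  expect_equal(morisitaScore(disj), 0) # disjoint supports
  hand <- data.frame(n_l = c(1, 1), n_e = c(2, 0))
  expect_equal(morisitaScore(hand), 2 / 3, tolerance = 1e-9)
  expect_error(morisitaScore(data.frame(n_l = c(0, 0), n_e = c(1, 2))),
               "zero")
  # scale invariance in either margin
  set.seed(9)
  tab <- data.frame(n_l = rpois(20, 3), n_e = rpois(20, 5))
  tab$n_l[1] <- tab$n_l[1] + 1; tab$n_e[2] <- tab$n_e[2] + 1
  s <- morisitaScore(tab)
  tab2 <- tab; tab2$n_l <- tab2$n_l * 7
  expect_equal(morisitaScore(tab2), s, tolerance = 1e-12)
})

test_that("slide scores separate the designed placement modes", {
  co <- sapply(1:6, function(i) scoreValue(slide_score("colocalised",
                                                       700L + i)))
  di <- sapply(1:6, function(i) scoreValue(slide_score("dispersed",
                                                       700L + i)))
  expect_true(all(is.finite(co)) && all(is.finite(di)))
  expect_gt(mean(co), mean(di)) # paired-seed recovery of the structure
})
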