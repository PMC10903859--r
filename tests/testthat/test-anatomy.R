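test_that("repair_breaks unions strokes and closes small gaps", {
  # C-shaped ring with a gap, plus a repair stroke across the gap
  ring <- mkdisk(60, 25) & !mkdisk(60, 18)
  ring[29:32, 50:60] <- FALSE                      # break the ring
  rep_roi <- roi_set(list(list(name = "patch",
                               vertices = rbind(c(48, 26), c(59, 26),
                                                c(59, 34), c(48, 34)))),
                     c(60, 60))
  fixed <- repair_breaks(mkmask(ring), rep_roi)
  expect_true(all(fixed$pixels[ring]))             # superset
  filled <- alveoquant:::fill_holes(fixed$pixels)
  expect_gt(sum(filled), sum(fixed$pixels))        # hole now enclosed

  ident <- repair_breaks(mkmask(ring), NULL, 0)
  expect_identical(ident$pixels, ring)
})

test_that("morphological closing bridges gaps by radius >= half the gap", {
  g <- matrix(FALSE, 21, 41)
  g[9:13, 1:18] <- TRUE; g[9:13, 23:41] <- TRUE    # gap of width 4
  closed <- repair_breaks(mkmask(g), NULL, closing_radius = 2)
  expect_true(all(closed$pixels[11, 19:22]))
  open <- repair_breaks(mkmask(g), NULL, closing_radius = 1)
  expect_false(any(open$pixels[11, 19:22]))
  expect_true(all(closed$pixels[g]))
})

test_that("pleura band matches the analytic annulus on a digital disk", {
  d <- mkmask(mkdisk(220, 100))
  b <- define_border(d, 10)
  analytic <- pi * (100^2 - 90^2)
  expect_lt(abs(sum(b$pleura_band$pixels) - analytic) / analytic, 0.03)

  # band and interior partition the filled outline exactly
  filled <- alveoquant:::fill_holes(d$pixels)
  expect_identical(b$pleura_band$pixels | b$interior$pixels, filled)
  expect_false(any(b$pleura_band$pixels & b$interior$pixels))

  gone <- define_border(d, 100)
  expect_false(any(gone$interior$pixels))
  expect_match(gone$ledger$warnings, "interior")
  expect_error(define_border(d, 0.2), "below one pixel")
})

test_that("pleura operates on the filled outline (interior holes are not pleura)", {
  holey <- mkdisk(160, 70) & !mkdisk(160, 12)      # central alveolus-like hole
  b <- define_border(mkmask(holey), 8)
  # no band pixels around the interior hole: band only near the outer rim
  center_dist <- sqrt((row(matrix(0, 160, 160)) - 80.5)^2 +
                      (col(matrix(0, 160, 160)) - 80.5)^2)
  expect_false(any(b$pleura_band$pixels & center_dist < 25))
})

test_that("duct walls are distance annuli clipped to the sample", {
  duct <- mkmask(mkdisk(220, 50), 1, "ducts")
  allm <- mkmask(matrix(TRUE, 220, 220))
  w <- define_duct_walls(duct, 10, allm)
  analytic <- pi * (60^2 - 50^2)
  expect_lt(abs(sum(w$wall_mask$pixels) - analytic) / analytic, 0.03)
  expect_false(any(w$wall_mask$pixels & duct$pixels))

  expect_error(define_duct_walls(duct, 0.3, allm), "below one pixel")

  # duct near the sample edge: wall clipped to the sample
  half <- mkmask(cbind(matrix(TRUE, 220, 120), matrix(FALSE, 220, 100)))
  wc <- define_duct_walls(mkmask(mkdisk(220, 40, cx = 115), 1, "ducts"),
                          15, half)
  expect_true(all(half$pixels[wc$wall_mask$pixels]))
})

test_that("load_air_ducts rasterizes regions and counts them", {
  two <- roi_set(list(
    list(name = "d1", vertices = circle_poly(20, 20, 8)),
    list(name = "d2", vertices = circle_poly(60, 60, 10))), c(90, 90))
  air <- load_air_ducts(two, 1)
  expect_equal(nrow(label_and_measure(air$duct_mask)$table), 2L)
  expect_equal(air$ledger$parameters$n_duct_regions, 2L)

  none <- load_air_ducts(roi_set(list(), c(30, 30)), 1)
  expect_false(any(none$duct_mask$pixels))

  # overlapping circles merge into one component of the union area
  over <- roi_set(list(
    list(name = "a", vertices = circle_poly(30, 30, 10)),
    list(name = "b", vertices = circle_poly(40, 30, 10))), c(70, 70))
  am <- load_air_ducts(over, 1)
  expect_equal(nrow(label_and_measure(am$duct_mask)$table), 1L)
  o1 <- oracle_point_in_polygon(circle_poly(30, 30, 10), 70, 70)
  o2 <- oracle_point_in_polygon(circle_poly(40, 30, 10), 70, 70)
  expect_identical(am$duct_mask$pixels, o1 | o2)
})

test_that("extract_parenchyma removes background, pleura, ducts and walls", {
  im <- calibrated_image(array(100L, c(100, 100, 3)), 1)
  full <- mkmask(matrix(TRUE, 100, 100))
  band <- matrix(FALSE, 100, 100)
  band[c(1:10, 91:100), ] <- TRUE; band[, c(1:10, 91:100)] <- TRUE
  res <- extract_parenchyma(im, full, mkmask(band, 1, "pleura"),
                            empty_mask(100), empty_mask(100))
  expect_equal(res$parenchyma_area, 80 * 80)
  expect_true(all(res$parenchyma_image$pixels[, , 1][band] == 255L))
  expect_true(all(res$parenchyma_image$pixels[11:90, 11:90, 1] == 100L))

  zero <- extract_parenchyma(im, empty_mask(100), empty_mask(100),
                             empty_mask(100), empty_mask(100))
  expect_equal(zero$parenchyma_area, 0)
  expect_match(zero$ledger$warnings, "empty")
})

test_that("parenchyma equals ground-truth tissue minus anatomical regions", {
  g <- generate_slice(test_params(staining = "SR", noise_sd = 0, seed = 6))
  gt <- g$ground_truth$masks
  res <- extract_parenchyma(g$image, gt$sample_tissue, gt$pleura, gt$ducts,
                            gt$duct_walls)
  expect_identical(res$parenchyma_mask$pixels, gt$parenchyma$pixels)
})

test_that("anatomical regions partition the filled sample disjointly", {
  g <- generate_slice(test_params(seed = 7))
  gt <- g$ground_truth$masks
  regions <- list(gt$parenchyma$pixels, gt$pleura$pixels, gt$ducts$pixels,
                  gt$duct_walls$pixels)
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(any(regions[[i]] & regions[[j]]),
                 label = sprintf("overlap between region %d and %d", i, j))
  un <- Reduce(`|`, regions)
  expect_true(all(gt$filled_outline$pixels[un]))
})

test_that("increasing pleura thickness never increases parenchyma area", {
  g <- generate_slice(test_params(seed = 8))
  gt <- g$ground_truth$masks
  im <- g$image
  areas <- vapply(c(10, 30, 60, 90), function(t_um) {
    b <- define_border(gt$sample_tissue, t_um)
    extract_parenchyma(im, gt$sample_tissue, b$pleura_band, gt$ducts,
                       gt$duct_walls)$parenchyma_area
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})
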