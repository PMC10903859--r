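test_that("dual_threshold matches exhaustive band membership", {
  g <- matrix(c(0, 128, 255), 1, 3)
  expect_equal(as.vector(dual_threshold(g, threshold_spec("blue", 100L, 200L))$pixels),
               c(FALSE, TRUE, FALSE))
  expect_true(all(dual_threshold(g, threshold_spec("blue", 0L, 255L))$pixels))
  expect_error(threshold_spec("blue", 200L, 100L), "lower")

  set.seed(3)
  for (rep in 1:20) {
    r <- matrix(sample(0:255, 16 * 16, replace = TRUE), 16, 16)
    b <- sort(sample(0:255, 2))
    spec <- threshold_spec("red", b[1], b[2])
    oracle <- matrix(FALSE, 16, 16)
    for (i in 1:16) for (j in 1:16)
      oracle[i, j] <- r[i, j] >= b[1] && r[i, j] <= b[2]
    expect_identical(dual_threshold(r, spec)$pixels, oracle)
  }
})

test_that("widening a threshold band never removes foreground", {
  set.seed(4)
  r <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  for (rep in 1:10) {
    b <- sort(sample(0:255, 2))
    inner <- dual_threshold(r, threshold_spec("red", b[1], b[2]))$pixels
    lo <- max(0L, b[1] - sample(0:40, 1))
    hi <- min(255L, b[2] + sample(0:40, 1))
    outer <- dual_threshold(r, threshold_spec("red", lo, hi))$pixels
    expect_true(all(outer[inner]))
  }
})

test_that("extract_channel slices the named channel", {
  blue <- calibrated_image(array(rep(c(0L, 0L, 255L), each = 4), c(2, 2, 3)), 1)
  expect_true(all(extract_channel(blue, "blue") == 255L))
  expect_true(all(extract_channel(blue, "red") == 0L))
  expect_error(extract_channel(blue, "chartreuse"), "unknown channel")

  set.seed(5)
  px <- array(sample(0:255, 4 * 5 * 3, replace = TRUE), c(4, 5, 3))
  im <- calibrated_image(px, 1)
  for (k in 1:3)
    expect_equal(extract_channel(im, c("red", "green", "blue")[k]), px[, , k])
})

test_that("particle areas are calibrated and conserved", {
  m <- matrix(FALSE, 30, 30); m[11:20, 11:20] <- TRUE
  lm <- label_and_measure(mkmask(m, 2))
  expect_equal(nrow(lm$table), 1L)
  expect_equal(lm$table$area, 400)  # 100 px * (2 um)^2

  expect_equal(nrow(label_and_measure(empty_mask(8))$table), 0L)

  set.seed(6)
  for (rep in 1:50) {
    px <- matrix(runif(24 * 24) > 0.6, 24, 24)
    s <- runif(1, 0.5, 4)
    lm <- label_and_measure(mkmask(px, s))
    expect_equal(sum(lm$table$area), sum(px) * s^2, tolerance = 1e-12)
  }
})

test_that("labeling is 8-connective", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE; m[4, 4] <- TRUE  # diagonal chain
  expect_equal(nrow(label_and_measure(mkmask(m))$table), 1L)
  m[6, 6] <- TRUE
  expect_equal(nrow(label_and_measure(mkmask(m))$table), 2L)
})

test_that("circularity approaches pi/4 for squares and stays >= 0.9 for disks", {
  sq <- matrix(FALSE, 120, 120); sq[11:110, 11:110] <- TRUE
  tb <- label_and_measure(mkmask(sq))$table
  expect_lt(abs(tb$circularity - pi / 4), 0.05)

  dk <- mkdisk(140, 60)
  tb2 <- label_and_measure(mkmask(dk))$table
  expect_gte(tb2$circularity, 0.90)
  expect_lte(tb2$circularity, 1.0)
})

test_that("measurements are invariant under 90-degree rotation", {
  set.seed(8)
  px <- matrix(runif(40 * 40) > 0.55, 40, 40)
  a <- label_and_measure(mkmask(px))$table
  rot <- t(px)[, nrow(px):1]
  b <- label_and_measure(mkmask(rot))$table
  expect_equal(sort(a$area), sort(b$area))
  expect_equal(sort(a$perimeter), sort(b$perimeter), tolerance = 1e-9)
})

test_that("detect_sample recovers noise-free synthetic tissue exactly", {
  g <- generate_slice(test_params(staining = "SR", noise_sd = 0, seed = 2))
  det <- detect_sample(g$image, threshold_spec("blue", 0L, 249L))
  expect_identical(det$mask$pixels, g$ground_truth$masks$sample_tissue$pixels)

  white <- calibrated_image(array(255L, c(8, 8, 3)), 1)
  dw <- detect_sample(white)
  expect_false(any(dw$mask$pixels))
  expect_equal(dw$ledger$particle_count, 0L)
})

test_that("the sample-detection ledger carries the five protocol settings", {
  im <- calibrated_image(array(100L, c(4, 4, 3)), 1.5, name = "slice_07")
  lg <- detect_sample(im, threshold_spec("blue", 10L, 200L))$ledger
  expect_equal(lg$input_name, "slice_07")
  expect_equal(lg$scale, 1.5)
  expect_equal(lg$parameters$lower_threshold, 10L)
  expect_equal(lg$parameters$upper_threshold, 200L)
  expect_equal(lg$particle_count, 1L)
})

test_that("filter_by_size keeps the calibrated area band", {
  m <- matrix(FALSE, 220, 220)
  m[2:3, 2:3] <- TRUE            # 4 px^2
  m[30:39, 30:39] <- TRUE        # 100 px^2
  m[60:159, 60:159] <- TRUE      # 10000 px^2
  f <- filter_by_size(mkmask(m, 1), size_filter_spec(50, 5000))
  expect_equal(nrow(f$table), 1L)
  expect_equal(f$table$area, 100)
  expect_equal(sum(f$mask$pixels), 100L)

  ident <- filter_by_size(mkmask(m, 1), size_filter_spec(0, Inf))
  expect_identical(ident$mask$pixels, m)
  expect_error(size_filter_spec(10, 5), "exceed")
})

test_that("size filtration equals brute-force table filtering and is idempotent", {
  set.seed(9)
  m <- matrix(FALSE, 120, 120)
  for (i in 1:20) {
    w <- sample(2:9, 2, replace = TRUE)
    y <- sample(1:(120 - w[1]), 1); x <- sample(1:(120 - w[2]), 1)
    m[y:(y + w[1] - 1), x:(x + w[2] - 1)] <- TRUE
  }
  mm <- mkmask(m, 1.3)
  tab <- label_and_measure(mm)$table
  band <- sort(runif(2, 0, max(tab$area) * 1.2))
  spec <- size_filter_spec(band[1], band[2])
  f1 <- filter_by_size(mm, spec)
  keep <- tab$area >= band[1] & tab$area <= band[2]
  expect_equal(sort(f1$table$area), sort(tab$area[keep]))
  f2 <- filter_by_size(f1$mask, spec)
  expect_identical(f2$mask$pixels, f1$mask$pixels)
})

test_that("exclude_particles removes whole components by seed or polygon", {
  m <- matrix(FALSE, 40, 40)
  m[5:10, 5:10] <- TRUE    # blob A
  m[25:30, 25:30] <- TRUE  # blob B
  ex <- exclude_particles(mkmask(m), cbind(7, 7))  # seed inside A (x, y)
  expect_equal(sum(ex$mask$pixels), 36L)
  expect_true(all(which(ex$mask$pixels, arr.ind = TRUE) >= 25))

  ident <- exclude_particles(mkmask(m), matrix(numeric(0), 0, 2))
  expect_identical(ident$mask$pixels, m)

  miss <- exclude_particles(mkmask(m), cbind(2, 2))
  expect_match(miss$ledger$warnings, "no foreground")
  expect_equal(sum(miss$mask$pixels), sum(m))
})

test_that("polygon exclusions remove exactly the intersected components", {
  set.seed(10)
  for (rep in 1:5) {
    m <- matrix(FALSE, 64, 64)
    for (i in 1:5) {
      y <- sample(seq(1, 55, by = 13), 1); x <- sample(seq(1, 55, by = 13), 1)
      m[y:(y + 5), x:(x + 5)] <- TRUE
    }
    mm <- mkmask(m)
    lm <- label_and_measure(mm)
    poly <- cbind(c(0, 63, 63, 0), c(0, 0, 25, 25))
    rs <- roi_set(list(list(name = "cut", vertices = poly)), c(64, 64))
    hit <- unique(lm$labels[oracle_point_in_polygon(poly, 64, 64) & lm$labels > 0])
    ex <- exclude_particles(mm, rs)
    expect_equal(nrow(ex$table), nrow(lm$table) - length(hit))
    expect_false(any(ex$mask$pixels & lm$labels %in% hit))
  }
})
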