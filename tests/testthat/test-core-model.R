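test_that("load_image attaches calibration and promotes grayscale", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(1, c(4, 4, 3)), f)
  im <- load_image(f, 2.0)
  expect_s3_class(im, "calibrated_image")
  expect_true(all(im$pixels == 255L))
  expect_equal(im$microns_per_pixel, 2.0)

  g <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 3, 3), g)
  gm <- load_image(g, 1)
  expect_equal(dim(gm$pixels), c(3L, 3L, 3L))
  expect_true(all(gm$pixels[, , 1] == gm$pixels[, , 3]))

  expect_error(load_image(f, 0), "positive")
  expect_error(load_image("no/such/file.png", 1), "read")
})

test_that("16-bit TIFF is linearly rescaled over the observed range; 8-bit is identity", {
  f16 <- withr::local_tempfile(fileext = ".tif")
  vals <- matrix(as.integer(seq(1000, 60000, length.out = 36)), 6, 6)
  tiff::writeTIFF(vals / 65535, f16, bits.per.sample = 16L)
  im <- load_image(f16, 1)
  # independent per-pixel linear map of the observed range
  expected <- round((vals - min(vals)) / (max(vals) - min(vals)) * 255)
  expect_equal(im$pixels[, , 1], matrix(as.integer(expected), 6, 6))

  f8 <- withr::local_tempfile(fileext = ".tif")
  a8 <- array(as.integer((0:107) %% 256), c(6, 6, 3))
  tiff::writeTIFF(a8 / 255, f8, bits.per.sample = 8L)
  expect_identical(load_image(f8, 1)$pixels, a8)
})

test_that("mask serialization round-trips bit-exactly", {
  f <- withr::local_tempfile(fileext = ".png")
  m <- mkmask(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2), 1.5)
  save_mask(m, f)
  v <- png::readPNG(f) * 255
  expect_equal(as.vector(v), c(255, 0, 0, 255))

  save_mask(empty_mask(4), f)
  expect_true(all(png::readPNG(f) == 0))

  set.seed(7)
  r <- mkmask(matrix(runif(32 * 32) > 0.5, 32, 32), 0.8)
  for (ext in c(".png", ".tif")) {
    p <- withr::local_tempfile(fileext = ext)
    save_mask(r, p)
    expect_identical(load_mask(p, 0.8)$pixels, r$pixels)
  }
})

test_that("ROI JSON round trip preserves names, order, vertices", {
  tri <- roi_set(list(list(name = "t",
                           vertices = rbind(c(0, 0), c(10, 0), c(0, 10)))),
                 c(20, 20))
  f <- withr::local_tempfile(fileext = ".json")
  save_roiset(tri, f)
  back <- load_roiset(f)
  expect_length(back$regions, 1L)
  expect_equal(nrow(back$regions[[1]]$vertices), 3L)

  expect_length(load_roiset(save_roiset(roi_set(list(), c(5, 5)),
                                        withr::local_tempfile(fileext = ".json")))$regions,
                0L)

  set.seed(21)
  regions <- lapply(1:5, function(i) {
    n <- sample(3:8, 1)
    list(name = sprintf("poly_%d", i),
         vertices = cbind(runif(n, 0, 63), runif(n, 0, 63)))
  })
  rs <- roi_set(regions, c(64, 64))
  f2 <- withr::local_tempfile(fileext = ".json")
  save_roiset(rs, f2)
  back2 <- load_roiset(f2)
  expect_equal(vapply(back2$regions, `[[`, character(1), "name"),
               vapply(rs$regions, `[[`, character(1), "name"))
  for (i in 1:5)
    expect_equal(back2$regions[[i]]$vertices, rs$regions[[i]]$vertices)
})

test_that("ROI sets validate vertices against the frame", {
  expect_error(roi_set(list(list(name = "bad",
                                 vertices = rbind(c(0, 0), c(30, 0), c(0, 30)))),
                       c(10, 10)),
               "outside frame.*bad")
  expect_error(roi_set(list(list(name = "a", vertices = rbind(c(0, 0), c(1, 0), c(0, 1))),
                            list(name = "a", vertices = rbind(c(2, 2), c(3, 2), c(2, 3)))),
                       c(10, 10)),
               "unique")
})

test_that("ImageJ .roi and .zip containers import onto the pixel-center convention", {
  # a 10x6 rectangle as an ImageJ polygon on the corner grid covers
  # pixel centers 2..11 x 3..8 -> shifted vertices at half-integers
  bytes <- make_ijroi_polygon(c(2L, 12L, 12L, 2L), c(3L, 3L, 9L, 9L))
  f <- withr::local_tempfile(fileext = ".roi")
  writeBin(bytes, f)
  rs <- load_roiset(f, c(20, 20))
  expect_equal(rs$regions[[1]]$vertices,
               cbind(c(1.5, 11.5, 11.5, 1.5), c(2.5, 2.5, 8.5, 8.5)))
  expect_equal(sum(rasterize(rs)$pixels), 10L * 6L)

  z <- withr::local_tempfile(fileext = ".zip")
  make_zip_stored(list(
    "a.roi" = make_ijroi_polygon(c(0L, 4L, 0L), c(0L, 0L, 4L)),
    "b.roi" = make_ijroi_polygon(c(5L, 9L, 9L, 5L), c(5L, 5L, 9L, 9L))), z)
  zs <- load_roiset(z, c(12, 12))
  expect_equal(vapply(zs$regions, `[[`, character(1), "name"), c("a", "b"))
  expect_error(load_roiset(f), "frame_shape")
})

test_that("rasterize follows the pixel-center rule", {
  rect <- roi_set(list(list(name = "r",
                            vertices = rbind(c(2, 1), c(5, 1), c(5, 3), c(2, 3)))),
                  c(10, 10))
  expect_equal(sum(rasterize(rect)$pixels), 12L)

  expect_equal(sum(rasterize(roi_set(list(), c(8, 8)))$pixels), 0L)

  two <- roi_set(list(
    list(name = "a", vertices = rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))),
    list(name = "b", vertices = rbind(c(5, 5), c(7, 5), c(7, 7), c(5, 7)))),
    c(10, 10))
  expect_equal(sum(rasterize(two)$pixels), 9L + 9L)
})

test_that("rasterize agrees with the exhaustive point-in-polygon oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(3:7, 1)
    v <- cbind(runif(n, 0, 30), runif(n, 0, 30))
    rs <- roi_set(list(list(name = "p", vertices = v)), c(32, 32))
    expect_identical(rasterize(rs)$pixels, oracle_point_in_polygon(v, 32, 32),
                     label = sprintf("random polygon %d", rep))
  }
})

test_that("ledger records round-trip through JSON lines", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  lg <- stage_ledger("sample_detection", "slice_01", 2.0,
                     parameters = list(lower_threshold = 100L,
                                       upper_threshold = 255L),
                     particle_count = 3L)
  write_ledger(lg, f)
  txt <- readLines(f)
  expect_match(txt, "sample_detection")
  expect_match(txt, "\"lower_threshold\":100")
  expect_match(txt, "\"particle_count\":3")

  write_ledger(stage_ledger("border_definition", "slice_01", 2.0,
                            parameters = list(pleura_thickness_um = 25)), f)
  back <- read_ledger(f)
  expect_length(back, 2L)
  expect_equal(back[[1]]$stage, "sample_detection")
  expect_equal(back[[2]]$stage, "border_definition")

  # 12-parameter round trip
  pars <- setNames(as.list(seq_len(12)), paste0("p", 1:12))
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_ledger(stage_ledger("big", "x", 1, parameters = pars,
                            particle_count = 0L), f2)
  got <- read_ledger(f2)[[1]]
  expect_equal(got$parameters[order(names(got$parameters))],
               pars[order(names(pars))])
  expect_equal(got$particle_count, 0L)
})
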