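#' @keywords internal
#' @importFrom EBImage bwlabel distmap fillHull closing makeBrush readImage
#' @importFrom jsonlite fromJSON toJSON read_json write_json
#' @importFrom igraph graph_from_edgelist components make_graph
#' @importFrom tools file_path_sans_ext
#' @importFrom utils unzip write.csv read.csv modifyList head tail
#' @importFrom stats rnorm runif sd setNames
#' @importFrom grDevices col2rgb
"_PACKAGE"

#' Calibrated RGB image
#'
#' The substrate of every pipeline stage: an 8-bit RGB raster together with
#' its spatial calibration in micrometers per pixel. Scale is a mandatory
#' constructor argument -- it is never guessed from file metadata, because a
#' silently wrong scale propagates into every calibrated area and perimeter.
#'
#' @param pixels integer array `H x W x 3`, channel values in `[0, 255]`.
#' @param microns_per_pixel positive scalar, micrometers per pixel.
#' @param name text identifier (usually derived from the file name).
#' @return An object of class `calibrated_image` with fields `pixels`,
#'   `microns_per_pixel` and `name`.
#' @seealso [load_image()], [extract_channel()]
#' @export
calibrated_image <- function(pixels, microns_per_pixel, name = "image") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]", call. = FALSE)
  check_scale(microns_per_pixel)
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, microns_per_pixel = as.numeric(microns_per_pixel),
         name = as.character(name)),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_image> '%s': %d x %d px, %.4g um/px (%.3g x %.3g mm)\n",
              x$name, d[1], d[2], x$microns_per_pixel,
              d[1] * x$microns_per_pixel / 1000, d[2] * x$microns_per_pixel / 1000))
  invisible(x)
}

#' Binary mask
#'
#' A boolean raster aligned to a [calibrated_image()], carrying the region
#' semantics of the stage that produced it (sample, pleura, ducts,
#' duct_walls, parenchyma, fibrosis, airspace, exclusion or repair).
#'
#' @param pixels logical matrix `H x W`.
#' @param microns_per_pixel positive scalar, micrometers per pixel.
#' @param semantics one of the recognized region labels.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, microns_per_pixel, semantics = "sample") {
  semantics <- match.arg(semantics, mask_semantics())
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (!is.logical(pixels)) {
    if (anyNA(pixels) || any(pixels != 0 & pixels != 1))
      stop("mask values must be logical or 0/1", call. = FALSE)
    pixels <- pixels > 0
  }
  check_scale(microns_per_pixel)
  structure(
    list(pixels = pixels, microns_per_pixel = as.numeric(microns_per_pixel),
         semantics = semantics),
    class = "binary_mask")
}

mask_semantics <- function() {
  c("sample", "pleura", "ducts", "duct_walls", "parenchyma", "fibrosis",
    "airspace", "exclusion", "repair")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s: %d x %d px, %d foreground (%.3g mm^2 at %.4g um/px)\n",
              x$semantics, nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              sum(x$pixels) * x$microns_per_pixel^2 / 1e6, x$microns_per_pixel))
  invisible(x)
}

#' Named set of polygonal regions
#'
#' The interchange object for the formerly interactive steps: air-duct
#' outlines, manual exclusions and break repairs all arrive as ROI sets.
#' Vertices are in pixel units under the package coordinate convention:
#' `(x, y) = (column, row)`, 0-based, with the center of pixel `(x, y)` at
#' the point `(x, y)`.
#'
#' @param regions list of regions, each a list with `name` (unique text) and
#'   `vertices` (an `n x 2` numeric matrix of `(x, y)` vertices).
#' @param frame_shape integer vector `c(H, W)` of the annotated frame.
#' @return An object of class `roi_set`.
#' @seealso [load_roiset()], [rasterize()]
#' @export
roi_set <- function(regions = list(), frame_shape) {
  frame_shape <- as.integer(frame_shape)
  if (length(frame_shape) != 2L || any(frame_shape < 1L))
    stop("`frame_shape` must be c(H, W) with positive entries", call. = FALSE)
  regions <- lapply(seq_along(regions), function(i) {
    r <- regions[[i]]
    v <- r$vertices
    if (is.null(dim(v))) v <- matrix(as.numeric(v), ncol = 2, byrow = TRUE)
    v <- matrix(as.numeric(v), ncol = 2, dimnames = NULL)
    if (nrow(v) < 3L)
      stop(sprintf("region %d has fewer than 3 vertices", i), call. = FALSE)
    nm <- if (is.null(r$name)) sprintf("region_%d", i) else as.character(r$name)
    list(name = nm, vertices = v)
  })
  nms <- vapply(regions, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("region names must be unique within the set", call. = FALSE)
  # vertices must lie within frame bounds (pixel-unit coordinates; the frame
  # spans [-0.5, W-0.5] x [-0.5, H-0.5] in continuous coordinates)
  bad <- character(0)
  for (r in regions) {
    v <- r$vertices
    if (any(v[, 1] < -0.5 | v[, 1] > frame_shape[2] - 0.5 |
            v[, 2] < -0.5 | v[, 2] > frame_shape[1] - 0.5))
      bad <- c(bad, r$name)
  }
  if (length(bad))
    stop("vertices outside frame bounds in region(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(regions = regions, frame_shape = frame_shape),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d region(s) on a %d x %d frame\n",
              length(x$regions), x$frame_shape[1], x$frame_shape[2]))
  for (r in x$regions)
    cat(sprintf("  %s: %d vertices\n", r$name, nrow(r$vertices)))
  invisible(x)
}

#' @export
length.roi_set <- function(x) length(x$regions)

#' Per-particle measurement table
#'
#' One row per connected component: `label`, calibrated `area` (um^2),
#' `perimeter` (um) and `circularity` = `min(1, 4*pi*area/perimeter^2)`.
#'
#' @param label positive integer labels.
#' @param area areas in um^2.
#' @param perimeter perimeters in um.
#' @return A data frame of class `c("particle_table", "data.frame")`.
#' @export
particle_table <- function(label = integer(0), area = numeric(0),
                           perimeter = numeric(0)) {
  stopifnot(length(label) == length(area), length(area) == length(perimeter))
  if (length(area) && any(area <= 0))
    stop("particle areas must be positive", call. = FALSE)
  circularity <- if (length(area)) pmin(1, 4 * pi * area / perimeter^2)
                 else numeric(0)
  structure(
    data.frame(label = as.integer(label), area = area, perimeter = perimeter,
               circularity = circularity),
    class = c("particle_table", "data.frame"))
}

check_scale <- function(microns_per_pixel) {
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      is.na(microns_per_pixel) || microns_per_pixel <= 0)
    stop("`microns_per_pixel` must be a positive scalar", call. = FALSE)
  invisible(TRUE)
}

# shared helper: assert two rasters live on the same frame/scale
check_aligned <- function(a, b, what = "masks") {
  da <- if (inherits(a, "calibrated_image")) dim(a$pixels)[1:2] else dim(a$pixels)
  db <- if (inherits(b, "calibrated_image")) dim(b$pixels)[1:2] else dim(b$pixels)
  if (!identical(as.integer(da), as.integer(db)))
    stop(what, " are not aligned: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"), call. = FALSE)
  if (abs(a$microns_per_pixel - b$microns_per_pixel) > 1e-9)
    stop(what, " have different spatial calibrations", call. = FALSE)
  invisible(TRUE)
}
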