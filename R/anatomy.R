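#' Anatomy distances
#'
#' Bundles the three anatomical distances of a study: pleura band
#' thickness, air-duct wall thickness, and the optional automatic
#' break-repair closing radius (0 disables). All are in micrometers and
#' must represent at least one pixel at the image scale when nonzero;
#' there are no universal defaults -- they are set per study.
#'
#' @param pleura_thickness pleura band thickness, um.
#' @param wall_thickness air-duct wall thickness, um.
#' @param closing_radius automatic break-repair closing radius, um.
#' @return An object of class `anatomy_spec`.
#' @export
anatomy_spec <- function(pleura_thickness, wall_thickness,
                         closing_radius = 0) {
  if (pleura_thickness <= 0 || wall_thickness <= 0 || closing_radius < 0)
    stop("anatomy distances must be positive (closing radius >= 0)",
         call. = FALSE)
  structure(list(pleura_thickness = as.numeric(pleura_thickness),
                 wall_thickness = as.numeric(wall_thickness),
                 closing_radius = as.numeric(closing_radius)),
            class = "anatomy_spec")
}

# micrometers -> pixels, rounded half-up (documented for reproducibility)
um_to_px <- function(um, microns_per_pixel) {
  as.integer(floor(um / microns_per_pixel + 0.5))
}

# Euclidean distance of foreground pixels to nearest background pixel
dist_to_background <- function(px) {
  d <- EBImage::distmap(px * 1L, metric = "euclidean")
  matrix(as.numeric(d), nrow(px), ncol(px))
}

fill_holes <- function(px) {
  f <- EBImage::fillHull(px * 1L)
  matrix(as.integer(round(f)) > 0L, nrow(px), ncol(px))
}

#' Repair breaks in the sample mask
#'
#' Tears in the section perimeter let background leak into the sample
#' interior and defeat the later virtual closing. Repairs are
#' declarative: user-drawn repair strokes (an ROI set) are unioned with
#' the sample, and an optional morphological closing with a disk of
#' `closing_radius` um bridges remaining thin gaps automatically. The
#' output is always a superset of the input foreground.
#'
#' @param sample a [binary_mask()] of the detected sample.
#' @param repairs a [roi_set()] of repair strokes, or `NULL`.
#' @param closing_radius disk radius in um; 0 disables closing.
#' @return The repaired [binary_mask()].
#' @export
repair_breaks <- function(sample, repairs = NULL, closing_radius = 0) {
  stopifnot(inherits(sample, "binary_mask"))
  px <- sample$pixels
  if (!is.null(repairs)) {
    stopifnot(inherits(repairs, "roi_set"))
    rm_ <- rasterize(repairs, sample$microns_per_pixel, "repair")
    check_aligned(sample, rm_, "sample and repair masks")
    px <- px | rm_$pixels
  }
  if (closing_radius > 0) {
    rpx <- um_to_px(closing_radius, sample$microns_per_pixel)
    if (rpx >= 1L) {
      brush <- EBImage::makeBrush(2L * rpx + 1L, shape = "disc")
      cl <- EBImage::closing(px * 1L, brush)
      px <- px | (matrix(as.integer(round(cl)), nrow(px), ncol(px)) > 0L)
    }
  }
  out <- sample
  out$pixels <- px
  out
}

#' Define the pleura band and sample interior
#'
#' The pleura is the outer rim of the section: the sample outline is
#' hole-filled (interior alveolar boundaries are not pleura) and then
#' reduced by `pleura_thickness` using the exact Euclidean distance
#' transform. `interior` holds the pixels farther than the thickness
#' from the exterior; `pleura_band` is the filled outline minus the
#' interior, so the two partition the filled outline exactly.
#'
#' @param sample a (repaired) [binary_mask()] of the sample.
#' @param pleura_thickness band thickness in um (>= 1 px at scale).
#' @return A list with `pleura_band`, `interior` (both [binary_mask()])
#'   and `ledger`. An interior emptied by an over-large thickness is
#'   returned empty with a ledger warning.
#' @export
define_border <- function(sample, pleura_thickness) {
  stopifnot(inherits(sample, "binary_mask"))
  tpx <- um_to_px(pleura_thickness, sample$microns_per_pixel)
  if (tpx < 1L)
    stop("`pleura_thickness` is below one pixel at this scale", call. = FALSE)
  filled <- fill_holes(sample$pixels)
  interior <- dist_to_background(filled) > tpx
  band <- filled & !interior
  warnings <- character(0)
  if (!any(interior))
    warnings <- "pleura thickness erases the whole sample interior"
  ledger <- stage_ledger(
    "border_definition", "sample", sample$microns_per_pixel,
    parameters = list(pleura_thickness_um = pleura_thickness,
                      pleura_thickness_px = tpx),
    warnings = warnings)
  list(pleura_band = binary_mask(band, sample$microns_per_pixel, "pleura"),
       interior = binary_mask(interior, sample$microns_per_pixel, "sample"),
       ledger = ledger)
}

#' Ingest user-identified air ducts
#'
#' Conducting airways and large vessels are identified by the user as
#' ROIs (no automatic detection); this rasterizes them to the duct mask.
#' An empty set is legal -- sections without visible ducts.
#'
#' @param rois a [roi_set()] of duct outlines.
#' @param microns_per_pixel scale of the annotated image.
#' @return A list with `duct_mask` ([binary_mask()], semantics
#'   `"ducts"`), the input `rois` (for overlays and ROI-file output) and
#'   `ledger` recording the region count.
#' @export
load_air_ducts <- function(rois, microns_per_pixel) {
  stopifnot(inherits(rois, "roi_set"))
  duct_mask <- rasterize(rois, microns_per_pixel, "ducts")
  ledger <- stage_ledger(
    "air_duct_identification", "sample", microns_per_pixel,
    parameters = list(n_duct_regions = length(rois$regions)))
  list(duct_mask = duct_mask, rois = rois, ledger = ledger)
}

#' Define air-duct walls
#'
#' Peri-duct collagen is physiological, not fibrosis; the wall band of
#' `wall_thickness` um around each duct is excluded from the parenchyma.
#' The band is the set of non-duct pixels within Euclidean distance
#' `wall_thickness` of duct foreground, clipped to the filled sample.
#'
#' @param duct_mask a [binary_mask()] of duct ROIs.
#' @param wall_thickness wall thickness in um (>= 1 px at scale).
#' @param sample_filled the hole-filled sample [binary_mask()].
#' @return A list with `wall_mask` ([binary_mask()], semantics
#'   `"duct_walls"`) and `ledger`.
#' @export
define_duct_walls <- function(duct_mask, wall_thickness, sample_filled) {
  stopifnot(inherits(duct_mask, "binary_mask"),
            inherits(sample_filled, "binary_mask"))
  check_aligned(duct_mask, sample_filled, "duct and sample masks")
  tpx <- um_to_px(wall_thickness, duct_mask$microns_per_pixel)
  if (tpx < 1L)
    stop("`wall_thickness` is below one pixel at this scale", call. = FALSE)
  if (any(duct_mask$pixels)) {
    d <- dist_to_background(!duct_mask$pixels)
    wall <- (d <= tpx) & !duct_mask$pixels & sample_filled$pixels
  } else {
    wall <- matrix(FALSE, nrow(duct_mask$pixels), ncol(duct_mask$pixels))
  }
  ledger <- stage_ledger(
    "air_duct_walls", "ducts", duct_mask$microns_per_pixel,
    parameters = list(wall_thickness_um = wall_thickness,
                      wall_thickness_px = tpx))
  list(wall_mask = binary_mask(wall, duct_mask$microns_per_pixel, "duct_walls"),
       ledger = ledger)
}

#' Extract the parenchyma
#'
#' Deletes everything that is not functional lung tissue from the
#' sample: background (via the sample mask), pleura band, ducts and
#' duct walls. Where regions overlap, precedence is ducts > duct walls >
#' pleura > parenchyma. The parenchyma image keeps the original pixels
#' under the mask and blanks the rest to white.
#'
#' @param image the original [calibrated_image()].
#' @param sample sample tissue [binary_mask()].
#' @param pleura_band pleura [binary_mask()] from [define_border()].
#' @param duct_mask duct [binary_mask()] from [load_air_ducts()].
#' @param wall_mask wall [binary_mask()] from [define_duct_walls()].
#' @return An object of class `parenchyma_result`: `parenchyma_image`,
#'   `parenchyma_mask`, `parenchyma_area` (um^2), `parenchyma_perimeter`
#'   (um, summed over components) and `ledger`.
#' @export
extract_parenchyma <- function(image, sample, pleura_band, duct_mask,
                               wall_mask) {
  stopifnot(inherits(image, "calibrated_image"))
  for (m in list(pleura_band, duct_mask, wall_mask))
    check_aligned(sample, m)
  pmask <- sample$pixels & !pleura_band$pixels & !duct_mask$pixels &
    !wall_mask$pixels
  s <- image$microns_per_pixel
  out_px <- image$pixels
  blank <- !pmask
  for (ch in 1:3) {
    plane <- out_px[, , ch]
    plane[blank] <- 255L
    out_px[, , ch] <- plane
  }
  mask <- binary_mask(pmask, s, "parenchyma")
  lm <- label_and_measure(mask)
  warnings <- character(0)
  if (!any(pmask)) warnings <- "parenchyma is empty"
  ledger <- stage_ledger(
    "parenchyma_extraction", image$name, s,
    parameters = list(removed_regions = "background, pleura, ducts, duct_walls"),
    particle_count = nrow(lm$table), warnings = warnings)
  structure(
    list(parenchyma_image = calibrated_image(out_px, s,
                                             paste0(image$name, "_parenchyma")),
         parenchyma_mask = mask,
         parenchyma_area = sum(pmask) * s^2,
         parenchyma_perimeter = sum(lm$table$perimeter),
         ledger = ledger),
    class = "parenchyma_result")
}

#' @export
print.parenchyma_result <- function(x, ...) {
  cat(sprintf("<parenchyma_result> area %.4g mm^2, perimeter %.4g mm\n",
              x$parenchyma_area / 1e6, x$parenchyma_perimeter / 1e3))
  invisible(x)
}
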