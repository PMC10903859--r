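#' Load a calibrated RGB image
#'
#' Reads a TIFF, PNG or JPEG raster and attaches the mandatory spatial
#' calibration. Grayscale inputs are promoted to RGB by channel
#' replication; an alpha channel, if present, is dropped. Rasters with
#' more than 8 bits per sample are rescaled to 8-bit by a linear map of
#' the observed value range, so every downstream threshold lives on the
#' 0--255 scale.
#'
#' @param path path to a TIFF/PNG/JPEG file.
#' @param microns_per_pixel positive scalar, micrometers per pixel.
#' @param name optional identifier; defaults to the file name without
#'   extension.
#' @return A [calibrated_image()].
#' @export
load_image <- function(path, microns_per_pixel, name = NULL) {
  check_scale(microns_per_pixel)
  px <- read_raster_8bit(path)
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 3L))   # grayscale
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]         # drop alpha
  if (is.null(name)) name <- file_path_sans_ext(basename(path))
  calibrated_image(px, microns_per_pixel, name = name)
}

# Read a raster file to integer values on the 0-255 scale.
# Returns an H x W matrix or H x W x C array.
read_raster_8bit <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path, call. = FALSE)
  ext <- tolower(file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    v <- tiff::readTIFF(path, as.is = TRUE)
    v <- drop_to_array(v)
    # 8-bit data still comes back rescaled to [0, 1]; >8-bit as integers
    if (max(v) <= 1) v <- round(v * 255)
    if (max(v) > 255) v <- rescale_observed(v)
    storage.mode(v) <- "integer"
    return(v)
  }
  if (ext == "png") {
    v <- png::readPNG(path)              # values in [0, 1]
    v <- drop_to_array(v)
    bits <- png_bit_depth(path)
    if (bits > 8L) {
      v <- rescale_observed(round(v * (2^bits - 1)))
    } else {
      v <- round(v * 255)
    }
    storage.mode(v) <- "integer"
    return(v)
  }
  if (ext %in% c("jpg", "jpeg")) {
    v <- round(jpeg::readJPEG(path) * 255)
    storage.mode(v) <- "integer"
    return(drop_to_array(v))
  }
  stop("unsupported raster format: .", ext, call. = FALSE)
}

drop_to_array <- function(v) {
  if (length(dim(v)) == 3L && dim(v)[3] == 1L) v <- v[, , 1]
  v
}

file_ext <- function(path) sub(".*\\.", "", basename(path))

# bit depth field of the PNG IHDR chunk (byte 25 of the file)
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L) return(8L)
  as.integer(hdr[25L])
}

# linear map of the observed range onto 0-255
rescale_observed <- function(v) {
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(array(if (lo > 0) 255L else 0L, dim(v)))
  round((v - lo) / (hi - lo) * 255)
}

#' Save a binary mask as an 8-bit image
#'
#' Foreground is written as 255, background as 0, in a single-channel
#' PNG or TIFF chosen from the file extension. The round trip through
#' [load_mask()] is bit-exact.
#'
#' @param mask a [binary_mask()].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  write_gray_8bit(ifelse(mask$pixels, 255L, 0L), path)
  invisible(path)
}

#' Load a binary mask image
#'
#' Reads an 8-bit mask written by [save_mask()] (or any raster): pixels
#' above 127 are foreground. Multi-channel inputs use the first channel.
#'
#' @param path image path.
#' @param microns_per_pixel positive scalar, micrometers per pixel.
#' @param semantics region label for the returned mask.
#' @return A [binary_mask()].
#' @export
load_mask <- function(path, microns_per_pixel, semantics = "sample") {
  v <- read_raster_8bit(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  binary_mask(v > 127, microns_per_pixel, semantics = semantics)
}

#' Save a calibrated image
#'
#' Writes the RGB raster as PNG or TIFF (from the extension). Spatial
#' calibration is not embedded: it travels through configs and ledgers.
#'
#' @param image a [calibrated_image()].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  write_rgb_8bit(image$pixels, path)
  invisible(path)
}

write_gray_8bit <- function(m, path) {
  ext <- tolower(file_ext(path))
  ok <- switch(ext,
    png  = png::writePNG(m / 255, target = path),
    tif  = ,
    tiff = tiff::writeTIFF(m / 255, where = path, bits.per.sample = 8L),
    stop("unsupported output format: .", ext, call. = FALSE))
  invisible(ok)
}

write_rgb_8bit <- function(a, path) {
  ext <- tolower(file_ext(path))
  ok <- switch(ext,
    png  = png::writePNG(a / 255, target = path),
    tif  = ,
    tiff = tiff::writeTIFF(a / 255, where = path, bits.per.sample = 8L),
    stop("unsupported output format: .", ext, call. = FALSE))
  invisible(ok)
}
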