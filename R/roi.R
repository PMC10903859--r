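#' Load an ROI set
#'
#' Reads either the package JSON ROI dialect
#' (`{"frame": [H, W], "regions": [{"name": ..., "vertices": [[x, y], ...]}]}`)
#' or an ImageJ ROI container: a single binary `.roi` file or a `.zip` of
#' `.roi` files. ImageJ polygon vertices live on the pixel-corner grid;
#' on import they are shifted by -0.5 onto the package's pixel-center
#' convention so that the filled area is preserved.
#'
#' @param path path to a `.json`, `.roi` or `.zip` file.
#' @param frame_shape integer `c(H, W)`; required for `.roi`/`.zip`
#'   inputs and used to validate JSON inputs whose frame disagrees.
#' @return A [roi_set()].
#' @export
load_roiset <- function(path, frame_shape = NULL) {
  if (!file.exists(path)) stop("cannot read ROI file: ", path, call. = FALSE)
  ext <- tolower(file_ext(path))
  if (ext == "json") {
    doc <- read_json(path, simplifyVector = FALSE)
    if (is.null(doc$frame) || is.null(doc$regions))
      stop("not a recognized ROI JSON document (missing 'frame'/'regions'): ",
           path, call. = FALSE)
    fr <- as.integer(unlist(doc$frame))
    if (!is.null(frame_shape) && !identical(fr, as.integer(frame_shape)))
      stop("ROI frame ", paste(fr, collapse = "x"),
           " disagrees with requested frame ",
           paste(frame_shape, collapse = "x"), call. = FALSE)
    regions <- lapply(doc$regions, function(r) {
      v <- do.call(rbind, lapply(r$vertices, function(p) as.numeric(unlist(p))))
      list(name = r$name, vertices = v)
    })
    return(roi_set(regions, fr))
  }
  if (ext == "roi") {
    if (is.null(frame_shape))
      stop("`frame_shape` is required when importing ImageJ .roi files",
           call. = FALSE)
    r <- read_imagej_roi(path)
    return(roi_set(list(r), frame_shape))
  }
  if (ext == "zip") {
    if (is.null(frame_shape))
      stop("`frame_shape` is required when importing ImageJ .zip containers",
           call. = FALSE)
    exdir <- tempfile("ijroi")
    dir.create(exdir)
    on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
    files <- unzip(path, exdir = exdir)
    files <- sort(files[grepl("\\.roi$", files, ignore.case = TRUE)])
    if (!length(files)) stop("zip container holds no .roi entries", call. = FALSE)
    return(roi_set(lapply(files, read_imagej_roi), frame_shape))
  }
  stop("unknown ROI format: .", ext, call. = FALSE)
}

#' Save an ROI set in the package JSON dialect
#'
#' @param rois a [roi_set()].
#' @param path output path ending in `.json`.
#' @return `path`, invisibly.
#' @export
save_roiset <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  doc <- list(
    frame = as.integer(rois$frame_shape),
    regions = lapply(rois$regions, function(r) {
      list(name = r$name,
           vertices = lapply(seq_len(nrow(r$vertices)),
                             function(i) as.numeric(r$vertices[i, ])))
    }))
  write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Minimal reader for ImageJ's binary .roi format ("Iout" files).
# Supports polygon (0), rectangle (1), oval (2), freehand (7) and
# traced (8) ROI types; coordinates are stored as 16-bit offsets from
# the bounding box. Ovals are approximated by a 64-gon.
read_imagej_roi <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout")
    stop("not an ImageJ ROI file: ", path, call. = FALSE)
  be_short <- function(i) {   # signed big-endian 16-bit at byte offset i (0-based)
    v <- as.integer(raw[i + 1L]) * 256L + as.integer(raw[i + 2L])
    if (v >= 32768L) v - 65536L else v
  }
  type   <- as.integer(raw[7L])
  top    <- be_short(8L);  left  <- be_short(10L)
  bottom <- be_short(12L); right <- be_short(14L)
  n      <- be_short(16L)
  name <- file_path_sans_ext(basename(path))
  if (type == 1L) {                       # rectangle
    v <- rbind(c(left, top), c(right, top), c(right, bottom), c(left, bottom))
  } else if (type == 2L) {                # oval -> 64-gon
    cx <- (left + right) / 2; cy <- (top + bottom) / 2
    rx <- (right - left) / 2; ry <- (bottom - top) / 2
    th <- seq(0, 2 * pi, length.out = 65L)[-65L]
    v <- cbind(cx + rx * cos(th), cy + ry * sin(th))
  } else if (type %in% c(0L, 7L, 8L)) {   # polygon / freehand / traced
    if (n < 3L) stop("ImageJ ROI has fewer than 3 vertices: ", path, call. = FALSE)
    xs <- vapply(seq_len(n), function(k) be_short(64L + 2L * (k - 1L)), integer(1))
    ys <- vapply(seq_len(n), function(k) be_short(64L + 2L * n + 2L * (k - 1L)),
                 integer(1))
    v <- cbind(left + xs, top + ys)
  } else {
    stop("unsupported ImageJ ROI type ", type, " in ", path, call. = FALSE)
  }
  # corner-grid -> pixel-center convention
  list(name = name, vertices = v - 0.5)
}

#' Rasterize an ROI set to a binary mask
#'
#' A pixel belongs to the mask iff its center lies inside or on the
#' boundary of any region (even-odd rule for self-intersecting
#' polygons, with an explicit on-edge test so boundary centers are
#' included on every side).
#'
#' @param rois a [roi_set()].
#' @param microns_per_pixel scale to stamp on the returned mask.
#' @param semantics region label for the returned mask.
#' @return A [binary_mask()]; empty sets yield an all-false mask.
#' @export
rasterize <- function(rois, microns_per_pixel = 1, semantics = "sample") {
  stopifnot(inherits(rois, "roi_set"))
  H <- rois$frame_shape[1]; W <- rois$frame_shape[2]
  m <- matrix(FALSE, H, W)
  for (r in rois$regions) m <- m | fill_polygon(r$vertices, H, W)
  binary_mask(m, microns_per_pixel, semantics = semantics)
}

# Fill one polygon on an H x W grid under the pixel-center rule.
fill_polygon <- function(v, H, W) {
  out <- matrix(FALSE, H, W)
  eps <- 1e-9
  x0 <- max(0L, as.integer(ceiling(min(v[, 1]) - eps)))
  x1 <- min(W - 1L, as.integer(floor(max(v[, 1]) + eps)))
  y0 <- max(0L, as.integer(ceiling(min(v[, 2]) - eps)))
  y1 <- min(H - 1L, as.integer(floor(max(v[, 2]) + eps)))
  if (x1 < x0 || y1 < y0) return(out)
  px <- rep(x0:x1, each = y1 - y0 + 1L)
  py <- rep(y0:y1, times = x1 - x0 + 1L)
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  n <- nrow(v)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- v[i, 1]; ay <- v[i, 2]; bx <- v[j, 1]; by <- v[j, 2]
    # even-odd ray crossing (ray toward +x)
    crosses <- (ay > py) != (by > py)
    if (any(crosses)) {
      t <- (py[crosses] - ay) / (by - ay)
      xi <- ax + t * (bx - ax)
      hit <- crosses
      hit[crosses] <- px[crosses] < xi
      inside <- xor(inside, hit)
    }
    # explicit on-segment test
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    if (len2 < eps) next
    tt <- ((px - ax) * dx + (py - ay) * dy) / len2
    tt <- pmin(1, pmax(0, tt))
    d2 <- (ax + tt * dx - px)^2 + (ay + tt * dy - py)^2
    onedge <- onedge | d2 < eps
  }
  keep <- inside | onedge
  out[cbind(py[keep] + 1L, px[keep] + 1L)] <- TRUE
  out
}
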