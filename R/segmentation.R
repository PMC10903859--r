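#' Dual-threshold specification
#'
#' A closed intensity band `[lower, upper]` on one color channel.
#' Thresholds always live on the 0--255 scale, whatever the input bit
#' depth was (see [load_image()]).
#'
#' @param channel one of `"red"`, `"green"`, `"blue"` or
#'   `"deconvolved_collagen"` (the connective-tissue pseudo-RGB green
#'   channel of a Masson's trichrome deconvolution).
#' @param lower,upper integers in `[0, 255]`, `lower <= upper`.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(channel = "blue", lower = 0L, upper = 255L) {
  channel <- match.arg(channel,
                       c("red", "green", "blue", "deconvolved_collagen"))
  lower <- as.integer(lower); upper <- as.integer(upper)
  if (is.na(lower) || is.na(upper) || lower < 0L || upper > 255L)
    stop("thresholds must lie in [0, 255]", call. = FALSE)
  if (lower > upper)
    stop("`lower` must not exceed `upper`", call. = FALSE)
  structure(list(channel = channel, lower = lower, upper = upper),
            class = "threshold_spec")
}

#' Size-filter specification
#'
#' Particle area band in calibrated units (um^2). `max_area = Inf`
#' disables the upper bound.
#'
#' @param min_area minimum particle area in um^2 (>= 0).
#' @param max_area maximum particle area in um^2, or `Inf`.
#' @return An object of class `size_filter_spec`.
#' @export
size_filter_spec <- function(min_area = 0, max_area = Inf) {
  if (min_area < 0) stop("`min_area` must be >= 0", call. = FALSE)
  if (min_area > max_area)
    stop("`min_area` must not exceed `max_area`", call. = FALSE)
  structure(list(min_area = as.numeric(min_area),
                 max_area = as.numeric(max_area)),
            class = "size_filter_spec")
}

#' Extract one color channel
#'
#' @param image a [calibrated_image()].
#' @param channel `"red"`, `"green"` or `"blue"`.
#' @return An `H x W` integer matrix of channel values.
#' @export
extract_channel <- function(image, channel) {
  stopifnot(inherits(image, "calibrated_image"))
  idx <- match(channel, c("red", "green", "blue"))
  if (is.na(idx))
    stop("unknown channel name: ", channel, call. = FALSE)
  image$pixels[, , idx]
}

#' Dual (band) thresholding
#'
#' A pixel is foreground iff `lower <= value <= upper`, both ends
#' inclusive -- the "double threshold" with user-selectable lower and
#' upper values.
#'
#' @param gray numeric matrix of values in `[0, 255]`.
#' @param spec a [threshold_spec()] (its `channel` field is ignored here).
#' @param microns_per_pixel scale to stamp on the returned mask.
#' @param semantics region label for the returned mask.
#' @return A [binary_mask()].
#' @export
dual_threshold <- function(gray, spec, microns_per_pixel = 1,
                           semantics = "sample") {
  stopifnot(is.matrix(gray), inherits(spec, "threshold_spec"))
  binary_mask(gray >= spec$lower & gray <= spec$upper, microns_per_pixel,
              semantics = semantics)
}

#' Label connected components and measure particles
#'
#' Components are taken under 8-connectivity (the particle-analyzer
#' convention; a fixed property of the package, not a knob). Per
#' particle the table reports calibrated area (pixel count x scale^2),
#' perimeter (outer Moore contour through pixel centers, axial steps
#' weighted 1 and diagonal steps sqrt(2), times scale) and circularity
#' `min(1, 4*pi*area/perimeter^2)`.
#'
#' @param mask a [binary_mask()].
#' @return A list with `labels` (`H x W` integer matrix, 0 = background)
#'   and `table` (a [particle_table()]).
#' @export
label_and_measure <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  labels <- label_components_8(mask$pixels)
  k <- max(labels)
  if (k == 0L)
    return(list(labels = labels, table = particle_table()))
  s <- mask$microns_per_pixel
  area_px <- tabulate(labels[labels > 0L], nbins = k)
  per_px <- measure_perimeters(labels, k)
  list(labels = labels,
       table = particle_table(seq_len(k), area_px * s^2, per_px * s))
}

# 8-connected labeling: EBImage's 4-connected pass, then diagonal
# label adjacencies merged through graph components.
label_components_8 <- function(px) {
  lab <- EBImage::bwlabel(px * 1L)
  lab <- matrix(as.integer(round(lab)), nrow(px), ncol(px))
  k <- max(lab)
  if (k <= 1L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  a1 <- lab[-H, -W]; b1 <- lab[-1, -1]   # down-right diagonal
  a2 <- lab[-H, -1]; b2 <- lab[-1, -W]   # down-left diagonal
  e <- rbind(cbind(as.vector(a1), as.vector(b1)),
             cbind(as.vector(a2), as.vector(b2)))
  e <- e[e[, 1] > 0L & e[, 2] > 0L & e[, 1] != e[, 2], , drop = FALSE]
  if (!nrow(e)) return(lab)
  g <- make_graph(edges = as.vector(t(unique(e))), n = k, directed = FALSE)
  # components() numbers merged labels in order of first vertex, so the
  # relabeling is deterministic; leading 0 maps background to background
  memb <- c(0L, as.integer(components(g)$membership))
  matrix(memb[lab + 1L], H, W)
}

# Outer-contour perimeter for every label, in pixel units.
measure_perimeters <- function(labels, k) {
  idx <- which(labels > 0L, arr.ind = TRUE)
  lb <- labels[labels > 0L]
  per <- numeric(k)
  ord <- order(lb)
  idx <- idx[ord, , drop = FALSE]; lb <- lb[ord]
  starts <- c(1L, which(diff(lb) != 0L) + 1L)
  ends <- c(starts[-1L] - 1L, length(lb))
  for (i in seq_len(k)) {
    rows <- idx[starts[i]:ends[i], 1L]
    cols <- idx[starts[i]:ends[i], 2L]
    r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
    sub <- matrix(0L, r1 - r0 + 3L, c1 - c0 + 3L)
    sub[cbind(rows - r0 + 2L, cols - c0 + 2L)] <- 1L
    per[i] <- trace_contour_length(sub)
  }
  per
}

# Moore boundary tracing through pixel centers on a padded binary
# matrix holding a single 8-connected component. Terminates when the
# initial boundary move (same origin pixel, same direction) repeats.
# Single pixels use the crack-length convention (perimeter 4).
trace_contour_length <- function(sub) {
  fg <- which(sub == 1L, arr.ind = TRUE)
  if (nrow(fg) == 1L) return(4)
  start <- fg[order(fg[, 1L], fg[, 2L])[1L], ]
  dy <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dx <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  steplen <- ifelse(seq(0L, 7L) %% 2L == 1L, sqrt(2), 1)
  W <- ncol(sub)
  cur_y <- start[1L]; cur_x <- start[2L]
  dir <- 7L                      # topmost-leftmost: N/NE/NW/W are background
  per <- 0
  first_key <- NA_real_
  max_steps <- 8L * nrow(fg) + 64L
  for (step in seq_len(max_steps)) {
    moved <- FALSE
    for (kk in 0:7) {
      nd <- (dir + kk) %% 8L
      ny <- cur_y + dy[nd + 1L]; nx <- cur_x + dx[nd + 1L]
      if (sub[ny, nx] == 1L) {
        key <- (cur_y * W + cur_x) * 8 + nd
        if (!is.na(first_key) && key == first_key) return(per)
        if (is.na(first_key)) first_key <- key
        per <- per + steplen[nd + 1L]
        cur_y <- ny; cur_x <- nx
        dir <- (nd + 6L) %% 8L
        moved <- TRUE
        break
      }
    }
    if (!moved) return(per)      # isolated pixel reached by pruning (defensive)
  }
  per
}

#' Detect the sample and remove the background
#'
#' Band thresholding of one channel of the slide image -- by default the
#' blue channel, where both eosinophilic and collagen-stained tissue
#' separate well from the white slide background.
#'
#' @param image a [calibrated_image()].
#' @param spec a [threshold_spec()]; default selects blue in `[0, 245]`.
#' @return A list with `mask` ([binary_mask()], semantics `"sample"`),
#'   `table` ([particle_table()]) and `ledger` ([stage_ledger()]
#'   recording input file name, scale, lower/upper threshold and the
#'   number of selected particles).
#' @export
detect_sample <- function(image, spec = threshold_spec("blue", 0L, 245L)) {
  stopifnot(inherits(image, "calibrated_image"))
  gray <- extract_channel(image, spec$channel)
  mask <- dual_threshold(gray, spec, image$microns_per_pixel, "sample")
  lm <- label_and_measure(mask)
  ledger <- stage_ledger(
    "sample_detection", image$name, image$microns_per_pixel,
    parameters = list(channel = spec$channel,
                      lower_threshold = spec$lower,
                      upper_threshold = spec$upper),
    particle_count = nrow(lm$table))
  list(mask = mask, table = lm$table, ledger = ledger)
}

#' Filter particles by size
#'
#' Keeps connected components whose calibrated area lies in
#' `[min_area, max_area]` (um^2). The ledger records the band in both
#' um^2 and the derived px^2 values.
#'
#' @param mask a [binary_mask()].
#' @param spec a [size_filter_spec()].
#' @param input_name text recorded in the ledger.
#' @return A list with `mask`, `table` (surviving particles, labels from
#'   the input labeling) and `ledger`.
#' @export
filter_by_size <- function(mask, spec, input_name = "mask") {
  stopifnot(inherits(mask, "binary_mask"), inherits(spec, "size_filter_spec"))
  lm <- label_and_measure(mask)
  keep <- lm$table$area >= spec$min_area & lm$table$area <= spec$max_area
  keep_labels <- lm$table$label[keep]
  out <- mask
  out$pixels <- matrix(lm$labels %in% keep_labels, nrow(lm$labels), ncol(lm$labels))
  s2 <- mask$microns_per_pixel^2
  ledger <- stage_ledger(
    "particle_filter_size", input_name, mask$microns_per_pixel,
    parameters = list(min_area_um2 = spec$min_area,
                      max_area_um2 = spec$max_area,
                      min_area_px2 = spec$min_area / s2,
                      max_area_px2 = spec$max_area / s2),
    particle_count = sum(keep))
  list(mask = out, table = lm$table[keep, , drop = FALSE], ledger = ledger)
}

#' Remove designated particles
#'
#' The declarative replacement for interactive object deletion: every
#' connected component intersecting an exclusion region or containing an
#' exclusion seed point is removed entirely. Exclusions touching no
#' foreground raise a ledger warning, not an error.
#'
#' @param mask a [binary_mask()].
#' @param exclusions a [roi_set()] of exclusion polygons, or an `n x 2`
#'   matrix of `(x, y)` seed points (0-based pixel coordinates).
#' @param input_name text recorded in the ledger.
#' @return A list with `mask`, `table` (remaining particles) and `ledger`.
#' @export
exclude_particles <- function(mask, exclusions, input_name = "mask") {
  stopifnot(inherits(mask, "binary_mask"))
  lm <- label_and_measure(mask)
  H <- nrow(mask$pixels); W <- ncol(mask$pixels)
  warnings <- character(0)
  hit_labels <- integer(0)
  if (inherits(exclusions, "roi_set")) {
    source_name <- sprintf("roi_set(%d regions)", length(exclusions$regions))
    for (r in exclusions$regions) {
      poly <- fill_polygon(r$vertices, H, W)
      labs <- unique(lm$labels[poly & lm$labels > 0L])
      if (!length(labs))
        warnings <- c(warnings,
                      sprintf("exclusion '%s' touches no foreground", r$name))
      hit_labels <- union(hit_labels, labs)
    }
  } else {
    pts <- matrix(as.numeric(exclusions), ncol = 2)
    source_name <- sprintf("seed_points(%d)", nrow(pts))
    for (i in seq_len(nrow(pts))) {
      x <- as.integer(round(pts[i, 1])); y <- as.integer(round(pts[i, 2]))
      lab <- 0L
      if (x >= 0L && x < W && y >= 0L && y < H) lab <- lm$labels[y + 1L, x + 1L]
      if (lab == 0L)
        warnings <- c(warnings,
                      sprintf("seed point (%d, %d) touches no foreground", x, y))
      else hit_labels <- union(hit_labels, lab)
    }
  }
  keep <- !(lm$table$label %in% hit_labels)
  out <- mask
  out$pixels <- matrix(lm$labels %in% lm$table$label[keep],
                       nrow(lm$labels), ncol(lm$labels))
  ledger <- stage_ledger(
    "particle_filter_manual", input_name, mask$microns_per_pixel,
    parameters = list(exclusion_source = source_name),
    particle_count = sum(keep), warnings = warnings)
  list(mask = out, table = lm$table[keep, , drop = FALSE], ledger = ledger)
}
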