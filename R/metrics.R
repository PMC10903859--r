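#' Composite overlay rendering
#'
#' Alpha-blends mask layers over the base image in list order:
#' `out = (1 - opacity) * base + opacity * color` under each mask,
#' rounded per channel. Pixels under no layer pass through bit-exactly.
#'
#' @param base a [calibrated_image()].
#' @param layers list of layers, each a list with `mask` (a
#'   [binary_mask()]), `color` (any value `grDevices::col2rgb()`
#'   accepts) and `opacity` in `[0, 1]`.
#' @return A [calibrated_image()] of the composite.
#' @export
render_overlay <- function(base, layers = list()) {
  stopifnot(inherits(base, "calibrated_image"))
  px <- array(as.numeric(base$pixels), dim(base$pixels))
  for (layer in layers) {
    stopifnot(inherits(layer$mask, "binary_mask"))
    check_aligned(base, layer$mask, "base image and overlay layer")
    alpha <- layer$opacity
    if (is.null(alpha)) alpha <- 0.5
    stopifnot(alpha >= 0, alpha <= 1)
    rgb <- as.numeric(col2rgb(layer$color))
    m <- layer$mask$pixels
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[m] <- (1 - alpha) * plane[m] + alpha * rgb[ch]
      px[, , ch] <- plane
    }
  }
  calibrated_image(array(as.integer(round(px)), dim(px)),
                   base$microns_per_pixel, paste0(base$name, "_overlay"))
}

#' Default overlay palette
#'
#' Pleura yellow, ducts cyan, duct walls blue, fibrosis red, airspace
#' green: distinguishable against pink/blue histology and from each
#' other under common color-vision deficiencies. Fully overridable.
#'
#' @return Named character vector of colors.
#' @export
default_palette <- function() {
  c(pleura = "#E6C700", ducts = "#00C8C8", duct_walls = "#2040D0",
    fibrosis = "#E02020", airspace = "#20B020")
}

#' Compile the per-sample summary
#'
#' The three critical areas and the headline ratios:
#' `fibrosis_fraction = fibrosis_area / parenchyma_area`,
#' `airspace_fraction = airspace_area / (parenchyma_area + airspace_area)`,
#' `tissue_density = parenchyma_area / (parenchyma_area + airspace_area)`.
#' Airspace fraction and tissue density share a denominator and sum to
#' one exactly; all three ratios are scale-invariant. Parenchyma area is
#' the extracted tissue-pixel area; the enclosing region area
#' (tissue + airspace) is reported as an auxiliary column.
#'
#' @param parenchyma a `parenchyma_result`.
#' @param fibrosis a `fibrosis_result`.
#' @param airspace an `airspace_result`.
#' @param sample_id text sample identifier.
#' @param group optional group label for cohort tables.
#' @return A one-row data frame of class
#'   `c("summary_record", "data.frame")`. A zero parenchyma area yields
#'   `NA` fractions and `flagged = TRUE`.
#' @export
compile_summary <- function(parenchyma, fibrosis, airspace,
                            sample_id = "sample", group = NA_character_) {
  stopifnot(inherits(parenchyma, "parenchyma_result"),
            inherits(fibrosis, "fibrosis_result"),
            inherits(airspace, "airspace_result"))
  pa <- parenchyma$parenchyma_area
  fa <- fibrosis$fibrosis_area
  aa <- airspace$airspace_area
  flagged <- pa <= 0
  rec <- data.frame(
    sample_id = as.character(sample_id),
    group = as.character(group),
    parenchyma_area_um2 = pa,
    fibrosis_area_um2 = fa,
    airspace_area_um2 = aa,
    region_area_um2 = pa + aa,
    fibrosis_fraction = if (flagged) NA_real_ else fa / pa,
    airspace_fraction = if (flagged) NA_real_ else aa / (pa + aa),
    tissue_density = if (flagged) NA_real_ else pa / (pa + aa),
    flagged = flagged,
    stringsAsFactors = FALSE)
  class(rec) <- c("summary_record", "data.frame")
  rec
}

#' Compile a cohort table
#'
#' Stacks per-sample summaries into one long table and, when group
#' labels are present, appends per-group mean and standard deviation of
#' the three ratios. The standard deviation of a single-record group is
#' reported as `NA` (the sample SD convention).
#'
#' @param records list of `summary_record` rows (or a prebound data
#'   frame of them).
#' @return A list with `samples` (the stacked table) and `groups`
#'   (per-group mean/sd table, or `NULL` when no group labels exist).
#' @export
compile_cohort <- function(records) {
  if (is.data.frame(records)) {
    samples <- records
  } else {
    if (!length(records)) stop("no records to compile", call. = FALSE)
    samples <- do.call(rbind, lapply(records, as.data.frame))
  }
  class(samples) <- "data.frame"
  groups <- NULL
  if (any(!is.na(samples$group))) {
    metrics <- c("fibrosis_fraction", "airspace_fraction", "tissue_density")
    gs <- split(samples, samples$group)
    groups <- do.call(rbind, lapply(names(gs), function(g) {
      d <- gs[[g]]
      out <- data.frame(group = g, n = nrow(d))
      for (m in metrics) {
        out[[paste0(m, "_mean")]] <- mean(d[[m]])
        out[[paste0(m, "_sd")]] <- if (nrow(d) > 1) sd(d[[m]]) else NA_real_
      }
      out
    }))
    rownames(groups) <- NULL
  }
  list(samples = samples, groups = groups)
}
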