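#' Airspace particle filter specification
#'
#' Area band (um^2) and circularity band for candidate alveolar
#' particles. Circularity is the same clamped `4*pi*A/P^2` used
#' throughout the particle tables, so tissue and airspace statistics
#' share one shape convention.
#'
#' @param min_area,max_area area band in um^2 (`max_area = Inf` allowed).
#' @param min_circularity,max_circularity circularity band in `[0, 1]`.
#' @return An object of class `airspace_spec`.
#' @export
airspace_spec <- function(min_area = 0, max_area = Inf,
                          min_circularity = 0, max_circularity = 1) {
  if (min_area < 0 || min_area > max_area)
    stop("invalid area band", call. = FALSE)
  if (min_circularity < 0 || max_circularity > 1 ||
      min_circularity > max_circularity)
    stop("invalid circularity band", call. = FALSE)
  structure(list(min_area = as.numeric(min_area),
                 max_area = as.numeric(max_area),
                 min_circularity = as.numeric(min_circularity),
                 max_circularity = as.numeric(max_circularity)),
            class = "airspace_spec")
}

#' Virtually close the parenchyma
#'
#' The union of tissue, pleura band and duct walls: the closed tissue
#' phase whose negative space (within the interior) is the alveolar
#' airspace. The pleura band seals the sample boundary so background
#' cannot leak in and be counted as alveoli.
#'
#' @param tissue_mask tissue [binary_mask()] (detected, cleaned sample).
#' @param pleura_band pleura [binary_mask()].
#' @param wall_mask duct-wall [binary_mask()].
#' @return The closed [binary_mask()] (semantics `"sample"`).
#' @export
close_parenchyma <- function(tissue_mask, pleura_band, wall_mask) {
  check_aligned(tissue_mask, pleura_band)
  check_aligned(tissue_mask, wall_mask)
  out <- tissue_mask
  out$pixels <- tissue_mask$pixels | pleura_band$pixels | wall_mask$pixels
  out$semantics <- "sample"
  out
}

#' Detect alveolar airspace as negative space
#'
#' Candidate airspace is the sample interior minus the closed tissue
#' phase. Components touching the frame border indicate background
#' leaking through an incompletely closed sample: they are discarded
#' and counted in the ledger as a QC flag, never as alveoli. Optionally
#' duct lumina are excluded (conducting airways are not alveoli).
#' Remaining components pass the area and circularity bands.
#'
#' @param closed the closed tissue [binary_mask()] from
#'   [close_parenchyma()].
#' @param sample_interior the filled sample minus the pleura band (the
#'   `interior` of [define_border()]).
#' @param spec an [airspace_spec()].
#' @param duct_mask optional duct-lumina [binary_mask()] to exclude from
#'   the candidate space; `NULL` skips the exclusion.
#' @return An object of class `airspace_result`: `airspace_mask`,
#'   `table`, `airspace_area` (um^2) and `ledger` (recording the four
#'   filter bounds, the particle count and the border-leak QC count).
#' @export
detect_airspace <- function(closed, sample_interior, spec = airspace_spec(),
                            duct_mask = NULL) {
  stopifnot(inherits(spec, "airspace_spec"))
  check_aligned(closed, sample_interior)
  cand <- sample_interior$pixels & !closed$pixels
  if (!is.null(duct_mask)) {
    check_aligned(closed, duct_mask)
    cand <- cand & !duct_mask$pixels
  }
  s <- closed$microns_per_pixel
  H <- nrow(cand); W <- ncol(cand)
  labels <- label_components_8(cand)
  border_labels <- unique(c(labels[1, ], labels[H, ], labels[, 1], labels[, W]))
  border_labels <- border_labels[border_labels > 0L]
  n_leaks <- length(border_labels)
  if (n_leaks) cand[labels %in% border_labels] <- FALSE
  mask <- binary_mask(cand, s, "airspace")
  lm <- label_and_measure(mask)
  keep <- lm$table$area >= spec$min_area & lm$table$area <= spec$max_area &
    lm$table$circularity >= spec$min_circularity &
    lm$table$circularity <= spec$max_circularity
  mask$pixels <- matrix(lm$labels %in% lm$table$label[keep], H, W)
  table <- lm$table[keep, , drop = FALSE]
  warnings <- if (n_leaks)
    sprintf("%d border-connected negative-space component(s) discarded (unclosed sample?)",
            n_leaks) else character(0)
  ledger <- stage_ledger(
    "airspace_detection", "parenchyma", s,
    parameters = list(min_area_um2 = spec$min_area,
                      max_area_um2 = spec$max_area,
                      min_circularity = spec$min_circularity,
                      max_circularity = spec$max_circularity,
                      duct_lumina_excluded = !is.null(duct_mask),
                      border_leak_components = n_leaks),
    particle_count = nrow(table), warnings = warnings)
  structure(list(airspace_mask = mask, table = table,
                 airspace_area = sum(table$area), ledger = ledger),
            class = "airspace_result")
}

#' @export
print.airspace_result <- function(x, ...) {
  cat(sprintf("<airspace_result> %d particle(s), %.4g mm^2\n",
              nrow(x$table), x$airspace_area / 1e6))
  invisible(x)
}
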