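#' Detect fibrosis in the parenchyma
#'
#' Pathological collagen suppresses the green channel under both
#' stains: red/magenta collagen in Sirius Red, and the connective-tissue
#' reconstruction of a Masson's-trichrome deconvolution. Detection is a
#' band threshold on that green channel, explicitly clipped to the
#' parenchyma mask -- the blanked-white surroundings (green 255) must
#' never enter a wide band.
#'
#' @param parenchyma a `parenchyma_result` from [extract_parenchyma()].
#' @param staining `"SR"` (threshold the parenchyma image directly) or
#'   `"MT"` (threshold the connective-tissue pseudo-RGB; `mt_result`
#'   required).
#' @param spec a [threshold_spec()]; the green channel is the default
#'   detection channel for both stains.
#' @param mt_result a `deconvolution_result` from [deconvolve()], for
#'   `staining = "MT"`.
#' @param mt_channel for MT, `"pseudo"` thresholds the green channel of
#'   the connective-tissue pseudo-RGB (default); `"concentration"`
#'   thresholds the collagen concentration raster mapped to 0--255 via
#'   the Beer--Lambert green response.
#' @return An object of class `fibrosis_result`: `fibrosis_mask`,
#'   `table`, `fibrosis_area` (um^2) and `ledger`.
#' @export
detect_fibrosis <- function(parenchyma, staining = c("SR", "MT"),
                            spec = threshold_spec("green", 0L, 90L),
                            mt_result = NULL,
                            mt_channel = c("pseudo", "concentration")) {
  stopifnot(inherits(parenchyma, "parenchyma_result"))
  staining <- match.arg(staining)
  mt_channel <- match.arg(mt_channel)
  img <- parenchyma$parenchyma_image
  if (staining == "SR") {
    gray <- extract_channel(img, if (spec$channel == "deconvolved_collagen")
      "green" else spec$channel)
  } else {
    if (is.null(mt_result) || !inherits(mt_result, "deconvolution_result"))
      stop("MT staining requires a `deconvolution_result` (run deconvolve())",
           call. = FALSE)
    if (mt_channel == "pseudo") {
      gray <- extract_channel(mt_result$pseudo_rgb$collagen, "green")
    } else {
      # concentration mapped through the collagen green response so the
      # 0-255 threshold scale keeps one meaning across both MT routes
      gvec <- mt_result$stains$vectors["collagen", "G"]
      cc <- mt_result$channels$collagen
      gray <- matrix(pmin(255, pmax(0, round(255 * 10^(-cc * gvec)))),
                     nrow(cc), ncol(cc))
    }
  }
  s <- img$microns_per_pixel
  raw <- dual_threshold(gray, spec, s, "fibrosis")
  raw$pixels <- raw$pixels & parenchyma$parenchyma_mask$pixels
  lm <- label_and_measure(raw)
  ledger <- stage_ledger(
    "fibrosis_detection", img$name, s,
    parameters = list(staining = staining,
                      channel = spec$channel,
                      mt_channel = if (staining == "MT") mt_channel else NULL,
                      lower_threshold = spec$lower,
                      upper_threshold = spec$upper),
    particle_count = nrow(lm$table))
  structure(list(fibrosis_mask = raw, table = lm$table,
                 fibrosis_area = sum(lm$table$area), ledger = ledger),
            class = "fibrosis_result")
}

#' Filter fibrosis particles by size
#'
#' Removes false-positive specks (nuclei edges, stain debris) from the
#' fibrosis selection by a calibrated area band; delegates to
#' [filter_by_size()] and recomputes the fibrosis area.
#'
#' @param result a `fibrosis_result` from [detect_fibrosis()].
#' @param spec a [size_filter_spec()].
#' @return A filtered `fibrosis_result`.
#' @export
filter_fibrosis <- function(result, spec) {
  stopifnot(inherits(result, "fibrosis_result"))
  f <- filter_by_size(result$fibrosis_mask, spec, input_name = "fibrosis")
  f$mask$semantics <- "fibrosis"
  f$ledger$stage <- "fibrosis_filter_size"
  structure(list(fibrosis_mask = f$mask, table = f$table,
                 fibrosis_area = sum(f$table$area), ledger = f$ledger),
            class = "fibrosis_result")
}

#' @export
print.fibrosis_result <- function(x, ...) {
  cat(sprintf("<fibrosis_result> %d particle(s), %.4g mm^2\n",
              nrow(x$table), x$fibrosis_area / 1e6))
  invisible(x)
}
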