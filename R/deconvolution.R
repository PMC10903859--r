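#' Stain matrix for color deconvolution
#'
#' Three unit vectors in optical-density (absorbance) space, one per
#' stain, rows ordered (collagen/connective, cytoplasm, nuclei). The
#' matrix must be invertible; vectors are unit-normalized on
#' construction.
#'
#' @param vectors numeric `3 x 3` matrix, one stain vector per row in
#'   `(R, G, B)` OD components.
#' @param source text provenance tag.
#' @return An object of class `stain_matrix`.
#' @export
stain_matrix <- function(vectors, source = "custom") {
  vectors <- matrix(as.numeric(vectors), 3, 3)
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms < 1e-12))
    stop("stain vectors must be nonzero", call. = FALSE)
  vectors <- vectors / norms
  if (abs(det(vectors)) < 1e-6) {
    # name the most collinear pair for the error message
    cors <- c(v12 = abs(sum(vectors[1, ] * vectors[2, ])),
              v13 = abs(sum(vectors[1, ] * vectors[3, ])),
              v23 = abs(sum(vectors[2, ] * vectors[3, ])))
    worst <- names(which.max(cors))
    stop("stain matrix is singular (collinear vectors: ",
         sub("v", "", worst), ")", call. = FALSE)
  }
  rownames(vectors) <- c("collagen", "cytoplasm", "nuclei")
  colnames(vectors) <- c("R", "G", "B")
  structure(list(vectors = vectors, source = as.character(source)),
            class = "stain_matrix")
}

#' @export
print.stain_matrix <- function(x, ...) {
  cat(sprintf("<stain_matrix> source: %s\n", x$source))
  print(round(x$vectors, 4))
  invisible(x)
}

#' Masson's trichrome stain vectors
#'
#' The measured Masson-trichrome vector pair published with the Fiji
#' colour-deconvolution plugin: methyl blue (collagen / connective
#' tissue) and ponceau-fuchsin (cytoplasm). The third vector is
#' completed as the normalized orthogonal complement of the two, which
#' makes the matrix invertible for the nuclei residual channel.
#'
#' @return A [stain_matrix()] with source
#'   `"colour-deconvolution plugin: Masson Trichrome"`.
#' @export
mt_default_stains <- function() {
  collagen <- c(0.7995107, 0.5913521, 0.10528667)   # methyl blue
  cytoplasm <- c(0.09997159, 0.73738605, 0.6694452) # ponceau-fuchsin
  third <- c(collagen[2] * cytoplasm[3] - collagen[3] * cytoplasm[2],
             collagen[3] * cytoplasm[1] - collagen[1] * cytoplasm[3],
             collagen[1] * cytoplasm[2] - collagen[2] * cytoplasm[1])
  stain_matrix(rbind(collagen, cytoplasm, third),
               source = "colour-deconvolution plugin: Masson Trichrome")
}

#' Load a stain matrix from a file
#'
#' Accepts a JSON 3x3 array or a whitespace-separated 3x3 numeric text
#' file; rows are unit-normalized on load.
#'
#' @param path file path.
#' @return A [stain_matrix()].
#' @export
load_stain_matrix <- function(path) {
  if (!file.exists(path)) stop("cannot read stain file: ", path, call. = FALSE)
  if (tolower(file_ext(path)) == "json") {
    m <- fromJSON(path)
    return(stain_matrix(matrix(as.numeric(t(m)), 3, 3, byrow = TRUE),
                        source = basename(path)))
  }
  m <- as.matrix(read.table(path))
  stain_matrix(matrix(as.numeric(m), 3, 3), source = basename(path))
}

# epsilon of one gray level in the Beer-Lambert log argument: bounds OD
# at ~2.4 decades for 8-bit data and makes results bit-reproducible
OD_EPS <- 1

#' RGB to optical density
#'
#' Beer--Lambert transform `OD_c = -log10((v_c + 1) / background_c)`
#' per channel; the one-gray-level offset avoids `log(0)`. White pixels
#' map to approximately zero OD.
#'
#' @param image a [calibrated_image()] or an `H x W x 3` numeric array.
#' @param background per-channel background (white) intensity,
#'   default 255.
#' @return An `H x W x 3` numeric array of optical densities.
#' @export
rgb_to_od <- function(image, background = c(255, 255, 255)) {
  px <- if (inherits(image, "calibrated_image")) image$pixels else image
  if (any(background <= 0))
    stop("`background` intensities must be positive", call. = FALSE)
  background <- rep_len(background, 3L)
  od <- array(0, dim(px))
  for (ch in 1:3) od[, , ch] <- -log10((px[, , ch] + OD_EPS) / background[ch])
  od
}

#' Optical density to RGB
#'
#' Inverse of [rgb_to_od()]: `v_c = background_c * 10^(-OD_c) - 1`,
#' rounded and clipped to `[0, 255]`.
#'
#' @param od `H x W x 3` optical-density array.
#' @param background per-channel background intensity, default 255.
#' @return An `H x W x 3` integer array.
#' @export
od_to_rgb <- function(od, background = c(255, 255, 255)) {
  background <- rep_len(background, 3L)
  px <- array(0L, dim(od))
  for (ch in 1:3) {
    v <- round(background[ch] * 10^(-od[, , ch]) - OD_EPS)
    px[, , ch] <- pmin(255, pmax(0, v))
  }
  storage.mode(px) <- "integer"
  px
}

#' Color deconvolution
#'
#' Per-pixel linear unmixing in OD space: concentrations are the OD
#' vector times the inverse stain matrix, clipped at zero (negative
#' values lie outside the stain gamut and are unphysical). Each stain
#' also gets a single-stain pseudo-RGB reconstruction
#' `background * 10^(-c_k * vector_k)` -- the rendering the green-channel
#' fibrosis thresholding consumes for Masson's trichrome.
#'
#' @param image a [calibrated_image()].
#' @param stains a [stain_matrix()], e.g. [mt_default_stains()].
#' @param background per-channel background intensity, default 255.
#' @return An object of class `deconvolution_result`: `channels` (list
#'   of three `H x W` concentration rasters named collagen, cytoplasm,
#'   nuclei) and `pseudo_rgb` (list of three [calibrated_image()]s).
#' @export
deconvolve <- function(image, stains, background = c(255, 255, 255)) {
  stopifnot(inherits(image, "calibrated_image"),
            inherits(stains, "stain_matrix"))
  d <- dim(image$pixels)
  od <- rgb_to_od(image, background)
  odm <- matrix(od, d[1] * d[2], 3)            # pixels x channels
  conc <- odm %*% solve(stains$vectors)        # pixels x stains
  conc[conc < 0] <- 0
  nm <- rownames(stains$vectors)
  channels <- setNames(lapply(1:3, function(k) matrix(conc[, k], d[1], d[2])),
                       nm)
  background <- rep_len(background, 3L)
  pseudo <- setNames(lapply(1:3, function(k) {
    od_k <- outer(conc[, k], stains$vectors[k, ])  # pixels x 3
    calibrated_image(od_to_rgb(array(od_k, c(d[1], d[2], 3)), background),
                     image$microns_per_pixel,
                     paste0(image$name, "_", nm[k]))
  }), nm)
  structure(list(channels = channels, pseudo_rgb = pseudo,
                 stains = stains, background = background),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat("<deconvolution_result> stains:",
      paste(names(x$channels), collapse = ", "),
      sprintf("(%s)\n", x$stains$source))
  invisible(x)
}

#' Synthesize an RGB image from stain concentrations
#'
#' Forward Beer--Lambert model: per-pixel OD is the concentration triple
#' times the stain matrix; transmitted RGB is
#' `background * 10^(-OD)`. The forward route for building synthetic
#' Masson's-trichrome imagery and the oracle for deconvolution
#' round-trip checks.
#'
#' @param concentrations `H x W x 3` array of per-stain concentrations
#'   (order: collagen, cytoplasm, nuclei).
#' @param stains a [stain_matrix()].
#' @param microns_per_pixel calibration for the returned image.
#' @param background per-channel background intensity, default 255.
#' @param name image name.
#' @return A [calibrated_image()].
#' @export
synthesize_stains <- function(concentrations, stains, microns_per_pixel = 1,
                              background = c(255, 255, 255),
                              name = "synthesized") {
  stopifnot(inherits(stains, "stain_matrix"))
  d <- dim(concentrations)
  cm <- matrix(concentrations, d[1] * d[2], 3)
  od <- cm %*% stains$vectors
  calibrated_image(od_to_rgb(array(od, c(d[1], d[2], 3)), background),
                   microns_per_pixel, name = name)
}
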