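#' Synthetic lung-slice parameters
#'
#' Conditions for the seeded generator that emulates a stained whole
#' lung-slice micrograph with pixel-exact ground truth: an elliptical
#' section with a collagen-rich pleural rim, user-identifiable air
#' ducts with collagen-rich walls, alveoli punched from the interior
#' tissue, and fibrotic patches painted until a target tissue fraction
#' is reached. Defaults describe a mouse lung slice at 2 um/px.
#'
#' @param staining `"SR"` (empirical red/pink palette) or `"MT"`
#'   (physical Beer--Lambert forward model from [mt_default_stains()]).
#' @param frame integer `c(H, W)` in pixels.
#' @param microns_per_pixel spatial calibration, um/px.
#' @param sample_axes ellipse semi-axes `c(x, y)` in um.
#' @param pleura_thickness pleural rim thickness, um.
#' @param n_ducts number of air ducts to place.
#' @param duct_radius_range duct radius range `c(min, max)`, um.
#' @param wall_thickness duct wall thickness, um.
#' @param alveolar_density expected alveoli per mm^2 of parenchyma.
#' @param alveolus_radius_range alveolus radius range `c(min, max)`, um.
#' @param fibrosis_fraction_target target fibrosis fraction of the
#'   parenchyma tissue, in `[0, 1]`; patches are added until the
#'   realized fraction is within 0.01 of this value.
#' @param noise_sd Gaussian pixel noise standard deviation, gray levels.
#' @param seed integer random seed; fixes the slice bit-exactly.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(staining = c("SR", "MT"), frame = c(512L, 512L),
                         microns_per_pixel = 2,
                         sample_axes = c(480, 400),
                         pleura_thickness = 30,
                         n_ducts = 3L,
                         duct_radius_range = c(40, 80),
                         wall_thickness = 40,
                         alveolar_density = 150,
                         alveolus_radius_range = c(15, 40),
                         fibrosis_fraction_target = 0.2,
                         noise_sd = 5,
                         seed = 1L) {
  staining <- match.arg(staining)
  check_scale(microns_per_pixel)
  if (fibrosis_fraction_target < 0 || fibrosis_fraction_target > 1)
    stop("`fibrosis_fraction_target` must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  p <- list(staining = staining, frame = as.integer(frame),
            microns_per_pixel = as.numeric(microns_per_pixel),
            sample_axes = as.numeric(sample_axes),
            pleura_thickness = as.numeric(pleura_thickness),
            n_ducts = as.integer(n_ducts),
            duct_radius_range = as.numeric(duct_radius_range),
            wall_thickness = as.numeric(wall_thickness),
            alveolar_density = as.numeric(alveolar_density),
            alveolus_radius_range = as.numeric(alveolus_radius_range),
            fibrosis_fraction_target = as.numeric(fibrosis_fraction_target),
            noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
  # geometric sanity: every distance must be representable at scale
  for (nm in c("pleura_thickness", "wall_thickness"))
    if (um_to_px(p[[nm]], p$microns_per_pixel) < 1L)
      stop(sprintf("`%s` is below one pixel at this scale", nm), call. = FALSE)
  structure(p, class = "synth_params")
}

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# SR palette (empirical): collagen is red-dominant / green-suppressed,
# other tissue pale pink, background white
SR_TISSUE <- c(235L, 150L, 160L)
SR_COLLAGEN <- c(190L, 40L, 60L)

# MT forward-model concentrations (methyl blue / ponceau-fuchsin)
MT_C_COLLAGEN <- 1.0
MT_C_CYTO_TISSUE <- 0.65
MT_C_CYTO_IN_COLLAGEN <- 0.15

#' Generate a synthetic lung slice with ground truth
#'
#' Deterministic for a fixed seed. Geometry: elliptical sample outline;
#' pleural rim of the requested thickness; non-overlapping random air
#' ducts (64-gon ROIs) with distance-transform walls; alveoli punched
#' as random disks from the interior tissue at the requested density
#' (disks may merge into realistic non-circular airspaces); fibrotic
#' patches painted as tissue-filled blobs until the fibrosis fraction
#' of the parenchyma tissue is within 0.01 of the target. Coloration is
#' an empirical palette for SR and the Beer--Lambert forward model from
#' [mt_default_stains()] for MT; Gaussian noise is added and clipped.
#'
#' @param params a [synth_params()].
#' @return A list with `image` (a [calibrated_image()]) and
#'   `ground_truth` (class `ground_truth`): `masks` (binary masks for
#'   sample_tissue, filled_outline, pleura, ducts, duct_walls,
#'   parenchyma, fibrosis, airspace), `duct_rois` (a [roi_set()] as the
#'   pipeline's duct input), `true_fibrosis_fraction`,
#'   `true_airspace_fraction` and `params`.
#' @export
generate_slice <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  with_seed(params$seed, generate_slice_impl(params))
}

generate_slice_impl <- function(p) {
  H <- p$frame[1]; W <- p$frame[2]; s <- p$microns_per_pixel
  Y <- matrix(rep(seq_len(H) - 1L, W), H, W)          # 0-based row (y)
  X <- matrix(rep(seq_len(W) - 1L, each = H), H, W)   # 0-based col (x)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  ax <- p$sample_axes[1] / s; ay <- p$sample_axes[2] / s
  outline <- ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 <= 1

  tpx <- um_to_px(p$pleura_thickness, s)
  d_out <- dist_to_background(outline)
  interior <- d_out > tpx
  pleura <- outline & !interior

  # --- air ducts: non-overlapping disks wholly inside the interior ---
  wallpx <- um_to_px(p$wall_thickness, s)
  d_int <- dist_to_background(interior)
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  for (i in seq_len(p$n_ducts)) {
    placed <- FALSE
    for (try in seq_len(200L)) {
      r_um <- runif(1, p$duct_radius_range[1], p$duct_radius_range[2])
      rpx <- r_um / s
      ok <- which(d_int > rpx + wallpx + 2)
      if (!length(ok)) next
      pick <- ok[sample.int(length(ok), 1L)]
      py <- (pick - 1L) %% H; px <- (pick - 1L) %/% H   # 0-based (y, x)
      if (nrow(centers)) {
        dd <- sqrt((centers[, 1] - px)^2 + (centers[, 2] - py)^2)
        if (any(dd < radii + rpx + 2 * wallpx + 2)) next
      }
      centers <- rbind(centers, c(px, py))
      radii <- c(radii, rpx)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("generation error: could not place duct ", i,
           " without overlap; relax the geometry", call. = FALSE)
  }
  th <- seq(0, 2 * pi, length.out = 65L)[-65L]
  duct_regions <- lapply(seq_len(nrow(centers)), function(i) {
    list(name = sprintf("duct_%d", i),
         vertices = cbind(centers[i, 1] + radii[i] * cos(th),
                          centers[i, 2] + radii[i] * sin(th)))
  })
  duct_rois <- roi_set(duct_regions, c(H, W))
  ducts <- rasterize(duct_rois, s, "ducts")$pixels
  if (any(ducts)) {
    walls <- (dist_to_background(!ducts) <= wallpx) & !ducts & outline
  } else {
    walls <- matrix(FALSE, H, W)
  }

  region <- interior & !ducts & !walls   # the parenchymal region

  # --- alveoli: random disks punched from the region ---
  d_reg <- dist_to_background(region)
  area_mm2 <- sum(region) * s^2 / 1e6
  n_alv <- round(p$alveolar_density * area_mm2)
  airspace0 <- matrix(FALSE, H, W)
  for (i in seq_len(n_alv)) {
    r_um <- runif(1, p$alveolus_radius_range[1], p$alveolus_radius_range[2])
    rpx <- r_um / s
    ok <- which(d_reg > rpx + 1)
    if (!length(ok)) next
    pick <- ok[sample.int(length(ok), 1L)]
    py <- (pick - 1L) %% H; px <- (pick - 1L) %/% H
    airspace0 <- airspace0 | ((X - px)^2 + (Y - py)^2 <= rpx^2)
  }

  # --- fibrotic patches: tissue-filled blobs painted to target ---
  tissue0 <- region & !airspace0
  fib <- matrix(FALSE, H, W)
  target <- p$fibrosis_fraction_target
  if (target > 0) {
    frac <- 0
    for (iter in seq_len(5000L)) {
      if (frac >= target) break
      r_um <- runif(1, 16, 36)
      ang <- runif(2, 0, 2 * pi)
      placed_blob <- NULL
      for (shrink in seq_len(8L)) {
        rpx <- r_um / s
        ok <- which(d_reg > rpx + 1)
        if (!length(ok)) { r_um <- r_um * 0.7; next }
        pick <- ok[sample.int(length(ok), 1L)]
        py <- (pick - 1L) %% H; px <- (pick - 1L) %/% H
        blob <- (X - px)^2 + (Y - py)^2 <= rpx^2
        for (k in 1:2) {                      # satellites for irregularity
          ox <- px + 0.8 * rpx * cos(ang[k]); oy <- py + 0.8 * rpx * sin(ang[k])
          blob <- blob | ((X - ox)^2 + (Y - oy)^2 <= (0.6 * rpx)^2)
        }
        blob <- blob & region
        f2 <- fib | blob
        frac2 <- sum(f2) / sum(tissue0 | f2)
        if (frac2 <= target + 0.01) { placed_blob <- f2; frac <- frac2; break }
        r_um <- r_um * 0.7                    # overshoot: shrink and retry
      }
      if (!is.null(placed_blob)) fib <- placed_blob
    }
  }
  airspace <- airspace0 & !fib
  parenchyma <- region & !airspace
  sample_tissue <- outline & !ducts & !airspace

  tf <- if (sum(parenchyma)) sum(fib) / sum(parenchyma) else 0
  ta_den <- sum(parenchyma) + sum(airspace)
  ta <- if (ta_den) sum(airspace) / ta_den else 0

  # --- coloration ---
  collagen_rich <- fib | pleura | walls
  if (p$staining == "SR") {
    px_arr <- array(255, c(H, W, 3))
    plain <- sample_tissue & !collagen_rich
    for (ch in 1:3) {
      plane <- px_arr[, , ch]
      plane[plain] <- SR_TISSUE[ch]
      plane[collagen_rich] <- SR_COLLAGEN[ch]
      px_arr[, , ch] <- plane
    }
  } else {
    conc <- array(0, c(H, W, 3))
    c1 <- matrix(0, H, W); c1[collagen_rich] <- MT_C_COLLAGEN
    c2 <- matrix(0, H, W)
    c2[sample_tissue & !collagen_rich] <- MT_C_CYTO_TISSUE
    c2[collagen_rich] <- MT_C_CYTO_IN_COLLAGEN
    conc[, , 1] <- c1; conc[, , 2] <- c2
    px_arr <- array(as.numeric(synthesize_stains(
      conc, mt_default_stains(), s)$pixels), c(H, W, 3))
  }
  if (p$noise_sd > 0)
    px_arr <- px_arr + array(rnorm(H * W * 3, 0, p$noise_sd), c(H, W, 3))
  px_arr <- array(as.integer(pmin(255, pmax(0, round(px_arr)))), c(H, W, 3))

  name <- sprintf("synth_%s_seed%d", p$staining, p$seed)
  msk <- function(m, sem) binary_mask(m, s, sem)
  gt <- structure(
    list(masks = list(sample_tissue = msk(sample_tissue, "sample"),
                      filled_outline = msk(outline, "sample"),
                      pleura = msk(pleura, "pleura"),
                      ducts = msk(ducts, "ducts"),
                      duct_walls = msk(walls, "duct_walls"),
                      parenchyma = msk(parenchyma, "parenchyma"),
                      fibrosis = msk(fib, "fibrosis"),
                      airspace = msk(airspace, "airspace")),
         duct_rois = duct_rois,
         true_fibrosis_fraction = tf,
         true_airspace_fraction = ta,
         params = p),
    class = "ground_truth")
  list(image = calibrated_image(px_arr, s, name), ground_truth = gt)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s: fibrosis fraction %.3f, airspace fraction %.3f\n",
              x$params$staining, x$true_fibrosis_fraction,
              x$true_airspace_fraction))
  invisible(x)
}

#' Summary record computed directly from ground truth
#'
#' The oracle for end-to-end recovery tests: the same areas and
#' fractions as [compile_summary()], but taken from the generator's
#' masks instead of the pipeline's detections.
#'
#' @param gt a `ground_truth` from [generate_slice()].
#' @return A one-row `summary_record` data frame.
#' @export
ground_truth_report <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  s <- gt$params$microns_per_pixel
  pa <- sum(gt$masks$parenchyma$pixels) * s^2
  fa <- sum(gt$masks$fibrosis$pixels) * s^2
  aa <- sum(gt$masks$airspace$pixels) * s^2
  rec <- data.frame(
    sample_id = sprintf("synth_%s_seed%d", gt$params$staining, gt$params$seed),
    group = NA_character_,
    parenchyma_area_um2 = pa, fibrosis_area_um2 = fa, airspace_area_um2 = aa,
    region_area_um2 = pa + aa,
    fibrosis_fraction = if (pa > 0) fa / pa else NA_real_,
    airspace_fraction = if (pa + aa > 0) aa / (pa + aa) else NA_real_,
    tissue_density = if (pa + aa > 0) pa / (pa + aa) else NA_real_,
    flagged = pa <= 0, stringsAsFactors = FALSE)
  class(rec) <- c("summary_record", "data.frame")
  rec
}
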