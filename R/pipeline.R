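#' Pipeline run configuration
#'
#' One declarative object drives a full run; every parameter any stage
#' consumes is representable here (no hidden defaults), which is what
#' makes runs replayable from their ledgers. Threshold defaults are the
#' package's synthetic-benchmark calibration; real-data thresholds are
#' study parameters, exactly as the interactive protocol leaves them to
#' the user.
#'
#' @param image path to the slide image, or a [calibrated_image()].
#' @param scale micrometers per pixel (ignored when `image` is already
#'   calibrated).
#' @param staining `"SR"` or `"MT"`.
#' @param out_dir output directory for masks, overlays, tables and the
#'   ledger; a fresh directory is derived when it already has contents.
#' @param sample_threshold [threshold_spec()] for sample detection.
#' @param sample_size_filter [size_filter_spec()] cleaning the sample.
#' @param fibrosis_threshold [threshold_spec()] for fibrosis detection;
#'   default `[0, 90]` on green for SR and `[0, 150]` on the
#'   connective pseudo-RGB green for MT.
#' @param fibrosis_size_filter [size_filter_spec()] cleaning fibrosis.
#' @param anatomy an [anatomy_spec()] (pleura/wall distances, um).
#' @param airspace an [airspace_spec()].
#' @param ducts_roi,exclusions_roi,repairs_roi ROI file paths (JSON or
#'   ImageJ `.roi`/`.zip`) or `NULL`; `NULL` ducts mean a section
#'   without visible ducts.
#' @param stains path to a custom stain-matrix file, or `NULL` for
#'   [mt_default_stains()].
#' @param mt_channel `"pseudo"` or `"concentration"` (see
#'   [detect_fibrosis()]).
#' @param palette named colors overriding [default_palette()] entries.
#' @param sample_id,group identifiers for the summary record.
#' @return An object of class `run_config`.
#' @export
run_config <- function(image, scale = NULL, staining = c("SR", "MT"),
                       out_dir = tempfile("alveoquant_run"),
                       sample_threshold = threshold_spec("blue", 0L, 245L),
                       sample_size_filter = size_filter_spec(500, Inf),
                       fibrosis_threshold = NULL,
                       fibrosis_size_filter = size_filter_spec(100, Inf),
                       anatomy = anatomy_spec(30, 40),
                       airspace = airspace_spec(min_area = 50),
                       ducts_roi = NULL, exclusions_roi = NULL,
                       repairs_roi = NULL, stains = NULL,
                       mt_channel = "pseudo",
                       palette = character(0),
                       sample_id = NULL, group = NA_character_) {
  staining <- match.arg(staining)
  if (is.null(fibrosis_threshold))
    fibrosis_threshold <- if (staining == "SR")
      threshold_spec("green", 0L, 90L) else threshold_spec("green", 0L, 150L)
  if (is.character(image)) {
    if (!file.exists(image)) stop("image path does not exist: ", image,
                                  call. = FALSE)
    if (is.null(scale)) stop("`scale` is required with an image path",
                             call. = FALSE)
    check_scale(scale)
  } else {
    stopifnot(inherits(image, "calibrated_image"))
    scale <- image$microns_per_pixel
  }
  for (p in c(ducts_roi, exclusions_roi, repairs_roi, stains))
    if (!is.null(p) && !file.exists(p))
      stop("referenced file does not exist: ", p, call. = FALSE)
  if (is.null(sample_id))
    sample_id <- if (is.character(image))
      file_path_sans_ext(basename(image)) else image$name
  structure(
    list(image = image, scale = as.numeric(scale), staining = staining,
         out_dir = out_dir, sample_threshold = sample_threshold,
         sample_size_filter = sample_size_filter,
         fibrosis_threshold = fibrosis_threshold,
         fibrosis_size_filter = fibrosis_size_filter,
         anatomy = anatomy, airspace = airspace,
         ducts_roi = ducts_roi, exclusions_roi = exclusions_roi,
         repairs_roi = repairs_roi, stains = stains,
         mt_channel = mt_channel, palette = palette,
         sample_id = sample_id, group = group),
    class = "run_config")
}

fresh_dir <- function(path) {
  if (dir.exists(path) && length(list.files(path, all.files = TRUE,
                                            no.. = TRUE))) {
    i <- 1L
    while (dir.exists(sprintf("%s-%d", path, i)) &&
           length(list.files(sprintf("%s-%d", path, i)))) i <- i + 1L
    path <- sprintf("%s-%d", path, i)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  path
}

#' Run the full quantification pipeline on one slide
#'
#' Stage order follows the protocol: sample detection, size and manual
#' particle filtration, break repair, border (pleura) definition, air
#' ducts and walls, parenchyma extraction, (MT only) color
#' deconvolution, fibrosis detection and filtration, tissue
#' visualization, airspace detection, tissue-and-airspace
#' visualization, summary compilation. Every intermediate mask, overlay
#' and particle table is persisted in the run directory and every stage
#' appends a ledger record; a failing stage aborts with its name after
#' marking the failure in the ledger, retaining earlier outputs.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return A list with `summary` (the `summary_record` row), `run_dir`,
#'   `ledgers` (stage records in pipeline order) and `results` (the
#'   stage result objects).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  run_dir <- fresh_dir(config$out_dir)
  ledger_path <- file.path(run_dir, "run.ledger.jsonl")
  ledgers <- list()
  note <- function(...) if (!quiet) message(sprintf(...))
  emit <- function(lg) {
    write_ledger(lg, ledger_path)
    ledgers[[length(ledgers) + 1L]] <<- lg
  }
  stage <- "load_image"
  fail <- function(e) {
    lg <- stage_ledger("pipeline_failure", config$sample_id,
                       if (is.null(config$scale)) 1 else config$scale,
                       parameters = list(failed_stage = stage,
                                         error = conditionMessage(e)))
    try(emit(lg), silent = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    image <- if (is.character(config$image))
      load_image(config$image, config$scale) else config$image
    s <- image$microns_per_pixel
    frame <- dim(image$pixels)[1:2]
    pal <- default_palette()
    pal[names(config$palette)] <- config$palette

    note("[1] sample detection")
    stage <- "sample_detection"
    det <- detect_sample(image, config$sample_threshold)
    emit(det$ledger)
    save_mask(det$mask, file.path(run_dir, "01_sample_mask.png"))
    write.csv(det$table, file.path(run_dir, "01_sample_particles.csv"),
              row.names = FALSE)

    note("[2a] particle size filter")
    stage <- "particle_filter_size"
    filt <- filter_by_size(det$mask, config$sample_size_filter, image$name)
    emit(filt$ledger)
    save_mask(filt$mask, file.path(run_dir, "02a_sample_clean_mask.png"))

    tissue <- filt$mask
    if (!is.null(config$exclusions_roi)) {
      note("[2b] manual particle filter")
      stage <- "particle_filter_manual"
      excl <- exclude_particles(tissue,
                                load_roiset(config$exclusions_roi, frame),
                                image$name)
      emit(excl$ledger)
      save_mask(excl$mask, file.path(run_dir, "02b_sample_manual_mask.png"))
      tissue <- excl$mask
    }

    note("[3] break repair and border definition")
    stage <- "break_repair"
    repairs <- if (is.null(config$repairs_roi)) NULL else
      load_roiset(config$repairs_roi, frame)
    repaired <- repair_breaks(tissue, repairs, config$anatomy$closing_radius)
    emit(stage_ledger("break_repair", image$name, s,
                      parameters = list(
                        repairs_used = !is.null(repairs),
                        closing_radius_um = config$anatomy$closing_radius)))
    stage <- "border_definition"
    border <- define_border(repaired, config$anatomy$pleura_thickness)
    emit(border$ledger)
    save_mask(border$pleura_band, file.path(run_dir, "03_pleura_mask.png"))

    note("[4-5] air ducts and walls")
    stage <- "air_duct_identification"
    duct_rois <- if (is.null(config$ducts_roi)) roi_set(list(), frame) else
      load_roiset(config$ducts_roi, frame)
    air <- load_air_ducts(duct_rois, s)
    emit(air$ledger)
    save_mask(air$duct_mask, file.path(run_dir, "04_ducts_mask.png"))
    stage <- "air_duct_walls"
    sample_filled <- binary_mask(fill_holes(repaired$pixels), s, "sample")
    walls <- define_duct_walls(air$duct_mask, config$anatomy$wall_thickness,
                               sample_filled)
    emit(walls$ledger)
    save_mask(walls$wall_mask, file.path(run_dir, "05_duct_walls_mask.png"))

    note("[6a] parenchyma extraction")
    stage <- "parenchyma_extraction"
    par <- extract_parenchyma(image, tissue, border$pleura_band,
                              air$duct_mask, walls$wall_mask)
    emit(par$ledger)
    save_mask(par$parenchyma_mask, file.path(run_dir, "06_parenchyma_mask.png"))
    save_image(par$parenchyma_image, file.path(run_dir, "06_parenchyma.png"))

    dec <- NULL
    if (config$staining == "MT") {
      note("[6b] MT color deconvolution")
      stage <- "mt_deconvolution"
      stains <- if (is.null(config$stains)) mt_default_stains() else
        load_stain_matrix(config$stains)
      dec <- deconvolve(par$parenchyma_image, stains)
      emit(stage_ledger("mt_deconvolution", par$parenchyma_image$name, s,
                        parameters = list(stain_source = stains$source)))
      save_image(dec$pseudo_rgb$collagen,
                 file.path(run_dir, "06b_connective.png"))
      save_image(dec$pseudo_rgb$cytoplasm,
                 file.path(run_dir, "06b_cytoplasm.png"))
      save_image(dec$pseudo_rgb$nuclei, file.path(run_dir, "06b_nuclei.png"))
    }

    note("[7-8] fibrosis detection and filtration")
    stage <- "fibrosis_detection"
    fib <- detect_fibrosis(par, config$staining, config$fibrosis_threshold,
                           dec, config$mt_channel)
    emit(fib$ledger)
    save_mask(fib$fibrosis_mask, file.path(run_dir, "07_fibrosis_mask.png"))
    stage <- "fibrosis_filter_size"
    ffib <- filter_fibrosis(fib, config$fibrosis_size_filter)
    emit(ffib$ledger)
    save_mask(ffib$fibrosis_mask,
              file.path(run_dir, "08_fibrosis_clean_mask.png"))
    write.csv(ffib$table, file.path(run_dir, "08_fibrosis_particles.csv"),
              row.names = FALSE)

    note("[9] tissue visualization")
    stage <- "tissue_visualization"
    tissue_layers <- list(
      list(mask = border$pleura_band, color = pal[["pleura"]], opacity = 0.5),
      list(mask = air$duct_mask, color = pal[["ducts"]], opacity = 0.5),
      list(mask = walls$wall_mask, color = pal[["duct_walls"]], opacity = 0.5),
      list(mask = ffib$fibrosis_mask, color = pal[["fibrosis"]],
           opacity = 0.5))
    viz_tissue <- render_overlay(image, tissue_layers)
    save_image(viz_tissue, file.path(run_dir, "09_tissue_overlay.png"))

    note("[10] airspace detection")
    stage <- "airspace_detection"
    closed <- close_parenchyma(tissue, border$pleura_band, walls$wall_mask)
    asp <- detect_airspace(closed, border$interior, config$airspace,
                           duct_mask = air$duct_mask)
    emit(asp$ledger)
    save_mask(asp$airspace_mask, file.path(run_dir, "10_airspace_mask.png"))
    write.csv(asp$table, file.path(run_dir, "10_airspace_particles.csv"),
              row.names = FALSE)

    note("[11] tissue and airspace visualization")
    stage <- "airspace_visualization"
    viz_both <- render_overlay(viz_tissue, list(
      list(mask = asp$airspace_mask, color = pal[["airspace"]],
           opacity = 0.5)))
    save_image(viz_both, file.path(run_dir, "11_tissue_airspace_overlay.png"))

    stage <- "summary"
    summary <- compile_summary(par, ffib, asp, config$sample_id,
                               config$group)
    write.csv(as.data.frame(summary), file.path(run_dir, "summary.csv"),
              row.names = FALSE)
    list(summary = summary, run_dir = run_dir, ledgers = ledgers,
         results = list(sample = det, cleaned = filt, border = border,
                        ducts = air, walls = walls, parenchyma = par,
                        deconvolution = dec, fibrosis = ffib,
                        airspace = asp))
  }, error = fail)
}

#' Run a batch of slides and compile the cohort
#'
#' Each configuration is run independently; per-sample failures are
#' recorded and the batch continues. Summaries are stacked through
#' [compile_cohort()].
#'
#' @param configs list of [run_config()] objects.
#' @param quiet suppress progress messages.
#' @return A list with `cohort` (see [compile_cohort()]), `runs` (the
#'   per-sample [run_pipeline()] returns) and `failures` (named
#'   character vector of error messages).
#' @export
run_batch <- function(configs, quiet = TRUE) {
  if (!length(configs)) stop("`configs` must hold at least one run_config",
                             call. = FALSE)
  runs <- list()
  failures <- character(0)
  records <- list()
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    stopifnot(inherits(cfg, "run_config"))
    res <- tryCatch(run_pipeline(cfg, quiet = quiet), error = identity)
    if (inherits(res, "error")) {
      failures[cfg$sample_id] <- conditionMessage(res)
    } else {
      runs[[cfg$sample_id]] <- res
      records[[length(records) + 1L]] <- res$summary
    }
  }
  if (!length(records))
    stop("all batch samples failed: ",
         paste(failures, collapse = "; "), call. = FALSE)
  list(cohort = compile_cohort(records), runs = runs, failures = failures)
}
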