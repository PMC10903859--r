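#' Stage settings record
#'
#' Every pipeline stage emits a ledger record naming its input, the
#' spatial calibration and every parameter that influenced its output,
#' plus the resulting particle count where one exists. Ledgers are the
#' reproducibility trail: a run can be replayed from them alone.
#'
#' @param stage stage name, e.g. `"sample_detection"`.
#' @param input_name name of the raster/mask the stage consumed.
#' @param scale micrometers per pixel.
#' @param parameters named list (flat) of stage parameters.
#' @param particle_count nonnegative integer, or `NULL` when the stage
#'   has no particle notion.
#' @param warnings character vector of stage warnings (QC flags).
#' @return An object of class `stage_ledger`.
#' @export
stage_ledger <- function(stage, input_name, scale, parameters = list(),
                         particle_count = NULL, warnings = character(0)) {
  check_scale(scale)
  parameters <- parameters[!vapply(parameters, is.null, logical(1))]
  if (length(parameters) && is.null(names(parameters)))
    stop("`parameters` must be a named list", call. = FALSE)
  if (!is.null(particle_count)) {
    particle_count <- as.integer(particle_count)
    stopifnot(particle_count >= 0L)
  }
  structure(
    list(stage = as.character(stage), input_name = as.character(input_name),
         scale = as.numeric(scale), parameters = parameters,
         particle_count = particle_count,
         warnings = as.character(warnings),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "stage_ledger")
}

#' @export
print.stage_ledger <- function(x, ...) {
  cat(sprintf("<stage_ledger> %s (input '%s', %.4g um/px)\n",
              x$stage, x$input_name, x$scale))
  for (nm in names(x$parameters))
    cat(sprintf("  %s = %s\n", nm, paste(format(x$parameters[[nm]]), collapse = ", ")))
  if (!is.null(x$particle_count))
    cat(sprintf("  particles = %d\n", x$particle_count))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Append a ledger record to a JSON-lines file
#'
#' One JSON object per line (`*.ledger.jsonl`): append-friendly and
#' diff-friendly. Rereading with [read_ledger()] reproduces every field.
#'
#' @param ledger a [stage_ledger()].
#' @param path output path; created if absent, appended to otherwise.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "stage_ledger"))
  rec <- unclass(ledger)
  line <- toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, open = "a", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(line, con)
  invisible(path)
}

#' Read a JSON-lines ledger file
#'
#' @param path a `*.ledger.jsonl` file written by [write_ledger()].
#' @return A list of [stage_ledger()] objects, in file order.
#' @export
read_ledger <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    rec <- fromJSON(l, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    lg <- stage_ledger(rec$stage, rec$input_name, rec$scale,
                       parameters = as.list(rec$parameters),
                       particle_count = rec$particle_count,
                       warnings = unlist(rec$warnings))
    lg$timestamp <- rec$timestamp
    lg
  })
}
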