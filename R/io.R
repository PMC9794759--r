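# Readers/writers for the package's on-disk formats. All writers are
# atomic (temp file in the target directory, then rename).

SCHEMA_VERSION <- "1.0"

write_atomic <- function(path, writer) {
  tmp <- file.path(dirname(path),
                   paste0(".", basename(path), ".tmp", Sys.getpid()))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    oct_stop(paste0("could not write ", path), "octplaq_io_error")
  invisible(path)
}

#' Write a pullback to disk (multi-page TIFF + JSON sidecar)
#'
#' Stores the intensity stack as a 16-bit multi-page grayscale TIFF
#' (`frames.tif`) and the annotation -- calibration plus per-frame lumen,
#' calcium and fibrous-cap geometry in 0-based (A-line, radial-pixel)
#' coordinates -- as a JSON sidecar (`pullback.json`) with a mandatory
#' schema version. Traced boundaries, if supplied, are stored under their
#' own `traces` key and never overwrite the planted annotation.
#'
#' @param pullback An `oct_pullback`.
#' @param dir Output directory (created if needed).
#' @param traces Optional list of traced boundaries (as produced by
#'   [extract_lesion_features()]'s `traces` attribute).
#' @return `dir`, invisibly.
#' @export
write_pullback <- function(pullback, dir, traces = NULL) {
  stopifnot(inherits(pullback, "oct_pullback"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nf <- dim(pullback$stack)[3L]
  pages <- lapply(seq_len(nf), function(f) pullback$stack[, , f])
  write_atomic(file.path(dir, "frames.tif"), function(p)
    tiff::writeTIFF(pages, p, bits.per.sample = 16L, compression = "none"))
  ann <- pullback$annotation
  ann$schema_version <- SCHEMA_VERSION
  if (!is.null(traces))
    ann$traces <- lapply(traces, function(tr)
      list(frame = tr$frame, a_lines = tr$trace$a_lines - 1L,
           radial_px = tr$trace$radial_px))
  if (!is.null(pullback$ground_truth))
    ann$ground_truth <- as.list(pullback$ground_truth)
  write_atomic(file.path(dir, "pullback.json"), function(p)
    jsonlite::write_json(ann, p, digits = NA, auto_unbox = TRUE,
                         na = "null", pretty = TRUE))
  invisible(dir)
}

#' Read a pullback written by [write_pullback()]
#'
#' @param dir Directory holding `frames.tif` and `pullback.json`.
#' @return An `oct_pullback` (stack, annotation, and ground truth when the
#'   sidecar carries one).
#' @export
read_pullback <- function(dir) {
  tif <- file.path(dir, "frames.tif"); js <- file.path(dir, "pullback.json")
  if (!file.exists(tif) || !file.exists(js))
    oct_schema_error(paste0("not a pullback directory: ", dir))
  ann <- jsonlite::fromJSON(js, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (is.null(ann$schema_version))
    oct_schema_error("pullback.json: missing schema_version")
  if (!identical(ann$schema_version, SCHEMA_VERSION))
    oct_schema_error(paste0("pullback.json: unsupported schema_version ",
                            ann$schema_version))
  for (f in c("pixel_size_radial", "frame_pitch", "a_lines_per_frame",
              "radial_samples"))
    if (is.null(ann$calibration[[f]]))
      oct_schema_error(paste0("pullback.json: missing calibration field ", f))
  # normalize parsed JSON types: boundary arrays are doubles, A-lines ints
  ann$frames <- lapply(ann$frames, function(fr) {
    fr$lumen <- as.numeric(fr$lumen)
    fr$calcium <- lapply(fr$calcium, function(d) {
      d$a_lines <- as.integer(d$a_lines)
      d$inner <- as.numeric(d$inner); d$outer <- as.numeric(d$outer)
      d
    })
    fr$fc <- lapply(fr$fc, function(d) {
      d$a_lines <- as.integer(d$a_lines)
      d$abluminal <- as.numeric(d$abluminal)
      d
    })
    fr
  })
  pages <- tiff::readTIFF(tif, all = TRUE)
  if (length(pages) != length(ann$frames))
    oct_schema_error(sprintf(
      "frame-count mismatch: %d TIFF pages, %d annotated frames",
      length(pages), length(ann$frames)))
  stack <- array(0, dim = c(nrow(pages[[1L]]), ncol(pages[[1L]]),
                            length(pages)))
  for (f in seq_along(pages)) stack[, , f] <- pages[[f]]
  gt <- NULL
  if (!is.null(ann$ground_truth)) {
    gt <- unlist(ann$ground_truth)
    ann$ground_truth <- NULL
  }
  structure(list(stack = stack, annotation = ann, ground_truth = gt),
            class = "oct_pullback")
}

#' Write a lesion cohort table to CSV
#'
#' Column contract: `lesion_id`, the 17 canonical features, and
#' `neoatherosclerosis` (0/1), in that order.
#'
#' @param cohort Cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  write_atomic(path, function(p)
    write.csv(cohort, p, row.names = FALSE, quote = TRUE))
  invisible(path)
}

#' Read a lesion cohort table from CSV
#'
#' Validates the exact column contract of [write_cohort()]: a misspelled,
#' missing, out-of-order or extra column is a schema error naming the
#' column; a non-numeric feature cell is a value error naming the column.
#' Lines starting with `#` (e.g. a units comment) are skipped.
#'
#' @param path CSV path.
#' @return Validated cohort data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) oct_schema_error(paste0("no such file: ", path))
  df <- read.csv(path, check.names = FALSE, comment.char = "#",
                 stringsAsFactors = FALSE)
  validate_cohort(df)
  df
}

validate_cohort <- function(df) {
  want <- oct_cohort_columns()
  have <- names(df)
  if (!identical(have, want)) {
    missing <- setdiff(want, have)
    extra <- setdiff(have, want)
    msg <- if (length(missing)) paste0("missing/misspelled column(s): ",
                                       paste(missing, collapse = ", "))
           else if (length(extra)) paste0("unexpected column(s): ",
                                          paste(extra, collapse = ", "))
           else "columns out of order"
    oct_schema_error(paste0("cohort table: ", msg))
  }
  for (f in oct_feature_names())
    if (!is.numeric(df[[f]]) && !all(is.na(df[[f]])))
      oct_value_error(paste0("cohort table: non-numeric values in column ", f))
  y <- df$neoatherosclerosis
  if (!all(y %in% c(0, 1)))
    oct_value_error("cohort table: neoatherosclerosis must be 0/1")
  invisible(df)
}

# Per-lesion extraction output: features CSV with a units comment line.
write_features_csv <- function(features_row, path) {
  units <- oct_feature_units()
  write_atomic(path, function(p) {
    con <- file(p, "w")
    on.exit(close(con), add = TRUE)
    writeLines(paste0("# units: ",
                      paste(names(units), units, sep = "=", collapse = ", "),
                      "; fc_burden_x1000 = fc_burden * 1000"), con)
    utils::write.table(features_row, con, sep = ",", row.names = FALSE,
                       quote = TRUE)
  })
  invisible(path)
}

#' Write / read an analysis report (JSON)
#'
#' The report JSON is written with fixed numeric precision so that
#' identical analyses produce byte-identical files.
#'
#' @param report An `oct_report` from [build_report()].
#' @param path JSON path.
#' @return `path` (write) or the parsed report list (read).
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "oct_report"))
  write_atomic(path, function(p)
    jsonlite::write_json(unclass(report), p, digits = 10, auto_unbox = TRUE,
                         na = "null", pretty = TRUE))
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) oct_schema_error(paste0("no such file: ", path))
  rep <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE, simplifyMatrix = TRUE)
  if (is.null(rep$schema_version))
    oct_schema_error("report: missing schema_version")
  rep
}
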