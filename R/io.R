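sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read and write fluorescence-trace CSV files
#'
#' A trace is stored as a two-column CSV with header `time_s,signal_au`, one
#' trace per file. Experimental metadata (mode, concentrations, variant
#' label, seed, generating parameters) goes in a sidecar JSON next to the CSV
#' (`<name>.json`). Reading a written trace returns the original arrays to
#' floating-point round-trip precision. Malformed rows (non-numeric fields)
#' are rejected with their line numbers; a non-monotone time column is a
#' format error. A missing sidecar yields a trace without metadata plus a
#' warning.
#'
#' @param path CSV path.
#' @param sidecar For [write_trace_csv()]: write the metadata JSON (default
#'   `TRUE`). For [read_trace_csv()]: require the sidecar (`TRUE`), ignore it
#'   (`FALSE`), or use it when present (`NA`, default).
#' @param trace A [fluor_trace].
#' @return [read_trace_csv()] returns a [fluor_trace]; [write_trace_csv()]
#'   invisibly returns the paths written.
#' @export
write_trace_csv <- function(trace, path, sidecar = TRUE) {
  if (!all(c("time_s", "signal_au") %in% names(trace))) {
    abort_input("`trace` needs `time_s` and `signal_au` columns.")
  }
  readr::write_csv(tibble(time_s = trace$time_s, signal_au = trace$signal_au),
                   path)
  paths <- path
  if (isTRUE(sidecar)) {
    meta <- list(mode = attr(trace, "mode"),
                 protein_conc_uM = attr(trace, "protein_conc_uM"),
                 reporter_conc_uM = attr(trace, "reporter_conc_uM"),
                 variant_label = attr(trace, "variant_label"),
                 seed = attr(trace, "seed"),
                 generating = attr(trace, "generating"))
    meta <- meta[!vapply(meta, is.null, logical(1))]
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
    paths <- c(paths, sidecar_path(path))
  }
  invisible(paths)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path, sidecar = NA) {
  if (!file.exists(path)) abort_input(sprintf("No such file: %s", path))
  raw <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  if (!identical(names(raw), c("time_s", "signal_au"))) {
    abort_format(sprintf(
      "Expected header 'time_s,signal_au', got '%s' in %s.",
      paste(names(raw), collapse = ","), path))
  }
  t <- suppressWarnings(as.numeric(raw$time_s))
  y <- suppressWarnings(as.numeric(raw$signal_au))
  bad <- which(is.na(t) | is.na(y))
  if (length(bad) > 0) {
    abort_format(sprintf(
      "Malformed numeric fields in %s at data line(s): %s.",
      path, paste(utils::head(bad, 10), collapse = ", ")))
  }
  if (any(diff(t) <= 0)) {
    abort_format(sprintf(
      "Time column not strictly increasing in %s (first violation at data line %d).",
      path, which(diff(t) <= 0)[1] + 1L))
  }
  sp <- sidecar_path(path)
  meta <- list(); mode <- NULL
  if (isTRUE(sidecar) && !file.exists(sp)) {
    abort_input(sprintf("Required sidecar JSON missing: %s", sp))
  }
  if (!isFALSE(sidecar) && file.exists(sp)) {
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    mode <- meta$mode
    meta$mode <- NULL
  } else if (!isFALSE(sidecar)) {
    warn(sprintf("No sidecar metadata found for %s; trace loaded without metadata.",
                 path))
  }
  if (is.null(mode)) {
    # infer from the dominant trend when metadata is absent
    mode <- if (trace_direction(y) >= 0) "association" else "dissociation"
  }
  fluor_trace(t, y, mode, meta = meta)
}

#' Read and write hydrolysis time-course CSV files
#'
#' Header `time_s,gtp_fraction`; same validation rules as trace CSVs,
#' plus the requirement that fractions lie in \[0, 1\].
#'
#' @param tc A tibble with `time_s`, `gtp_fraction`.
#' @param path CSV path.
#' @return [read_timecourse_csv()] returns a `hydrolysis_tc` tibble.
#' @export
write_timecourse_csv <- function(tc, path) {
  readr::write_csv(tibble(time_s = tc$time_s, gtp_fraction = tc$gtp_fraction),
                   path)
  invisible(path)
}

#' @rdname write_timecourse_csv
#' @export
read_timecourse_csv <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("No such file: %s", path))
  raw <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  if (!identical(names(raw), c("time_s", "gtp_fraction"))) {
    abort_format(sprintf("Expected header 'time_s,gtp_fraction' in %s.", path))
  }
  t <- suppressWarnings(as.numeric(raw$time_s))
  y <- suppressWarnings(as.numeric(raw$gtp_fraction))
  bad <- which(is.na(t) | is.na(y))
  if (length(bad) > 0) {
    abort_format(sprintf("Malformed numeric fields in %s at data line(s): %s.",
                         path, paste(utils::head(bad, 10), collapse = ", ")))
  }
  if (any(diff(t) <= 0)) abort_format("Time column not strictly increasing.")
  if (any(y < 0 | y > 1)) abort_format("GTP fractions must lie in [0, 1].")
  out <- tibble(time_s = t, gtp_fraction = y)
  class(out) <- c("hydrolysis_tc", class(out))
  out
}

#' Read and write single-plane grayscale TIFF images
#'
#' Images are written as single-plane 16-bit grayscale TIFF. TIFF samples live
#' on a \[0, 1\] scale, so when intensities exceed 1 the image is divided by
#' its maximum and the scale factor recorded in a sidecar JSON
#' (`<name>_scale.json`); the round trip then recovers the original values to
#' 16-bit quantization precision.
#'
#' @param img Numeric matrix of nonnegative intensities.
#' @param path TIFF path.
#' @return [read_image_tiff()] returns a numeric matrix.
#' @export
write_image_tiff <- function(img, path) {
  if (!is.matrix(img) || any(img < 0)) {
    abort_input("`img` must be a nonnegative numeric matrix.")
  }
  scale <- max(img, 1)
  tiff::writeTIFF(img / scale, path, bits.per.sample = 16L)
  sp <- image_scale_path(path)
  if (scale > 1) {
    jsonlite::write_json(list(scale = scale), sp, auto_unbox = TRUE,
                         digits = NA)
  } else if (file.exists(sp)) {
    file.remove(sp)
  }
  invisible(path)
}

image_scale_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_scale.json")
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("No such file: %s", path))
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  scale <- 1
  sp <- image_scale_path(path)
  if (file.exists(sp)) {
    scale <- jsonlite::read_json(sp, simplifyVector = TRUE)$scale
    if (!is.numeric(scale) || !is.finite(scale)) scale <- 1
  }
  unname(img * scale)
}
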