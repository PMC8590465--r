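#' Write and read event tables
#'
#' Event tables are CSV files with columns `cell_id`, `condition`, `t_s`,
#' `amp_pA`. Per-cell amplitude lists are flattened with `t_s = NA` when no
#' event times are available (amplitude-only populations).
#'
#' @param x a `cell_amplitudes` list, an `event_table` from
#'   [detect_events()], or a data frame with the required columns.
#' @param path output CSV path.
#' @param condition condition label used when `x` carries none.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(x, path, condition = NULL) {
  if (inherits(x, "cell_amplitudes") ||
      (is.list(x) && !is.data.frame(x) && all(vapply(x, is.numeric, TRUE)))) {
    condition <- condition %||% attr(x, "condition") %||% "unlabelled"
    ids <- names(x) %||% sprintf("cell%02d", seq_along(x))
    df <- data.frame(
      cell_id = rep(ids, lengths(x)),
      condition = condition,
      t_s = NA_real_,
      amp_pA = unlist(x, use.names = FALSE))
  } else {
    df <- as.data.frame(x)
    if ("amplitude" %in% names(df) && !"amp_pA" %in% names(df))
      names(df)[names(df) == "amplitude"] <- "amp_pA"
    if ("peak_t" %in% names(df) && !"t_s" %in% names(df))
      df$t_s <- df$peak_t
    if (!"condition" %in% names(df))
      df$condition <- condition %||% "unlabelled"
    if (!"t_s" %in% names(df)) df$t_s <- NA_real_
    df <- df[, c("cell_id", "condition", "t_s", "amp_pA")]
  }
  atomic_write(path, function(p) write.csv(df, p, row.names = FALSE))
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "amp_pA")
  if (!all(need %in% names(df)))
    stopf("event table must contain columns: %s", paste(need, collapse = ", "))
  df
}

#' Write and read traces as CSV with a JSON metadata sidecar
#'
#' The CSV holds one `value` column; `<path>.meta.json` records the
#' sampling rate and signal kind.
#'
#' @param tr a [trace()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(tr, path) {
  stopifnot(inherits(tr, "synscale_trace"))
  atomic_write(path, function(p)
    write.csv(data.frame(value = tr$samples), p, row.names = FALSE))
  meta <- list(sampling_rate_hz = tr$sampling_rate,
               signal_kind = tr$signal_kind,
               n_samples = length(tr$samples))
  atomic_write(paste0(path, ".meta.json"), function(p)
    jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) stopf("missing trace metadata: %s", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- read.csv(path)
  trace(df$value, sampling_rate = meta$sampling_rate_hz,
        signal_kind = meta$signal_kind)
}

#' Write and read images as TIFF
#'
#' Images are stored as 32-bit float TIFF on a `[0, 1]` scale: the written
#' value is `(x - offset) / scale`, and reading applies the inverse, so
#' arbitrary intensity units survive the round trip when the same offset
#' and scale are supplied (run records echo both). The pixel size is not
#' stored in the TIFF and must travel through run configuration (or the
#' `pixel_um` argument on read).
#'
#' @param image numeric matrix (or 3D array for a stack).
#' @param path output TIFF path.
#' @param scale divisor applied after offsetting; default 1.
#' @param offset value subtracted before scaling; default 0.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, scale = 1, offset = 0) {
  x <- (unclass(image) - offset) / scale
  storage.mode(x) <- "double"
  atomic_write(path, function(p)
    tiff::writeTIFF(x, p, bits.per.sample = 32L, reduce = FALSE))
  invisible(path)
}

#' @rdname write_image_tiff
#' @param pixel_um pixel size to attach to the image on read.
#' @export
read_image_tiff <- function(path, pixel_um = NULL, scale = 1, offset = 0) {
  x <- tiff::readTIFF(path, all = TRUE)
  if (is.list(x)) {
    if (length(x) == 1) {
      img <- x[[1]]
    } else {
      img <- array(unlist(x), dim = c(dim(x[[1]])[1:2], length(x)))
    }
  } else img <- x
  img <- img * scale + offset
  if (!is.null(pixel_um)) attr(img, "pixel_um") <- pixel_um
  img
}

#' @rdname write_events_csv
#' @export
write_punctum_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  atomic_write(path, function(p) write.csv(as.data.frame(x), p,
                                           row.names = FALSE))
  invisible(path)
}

# Write through a temporary file in the destination directory and rename,
# so partially written outputs are never observed.
atomic_write <- function(path, writer) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stopf("could not write %s", path)
  invisible(path)
}
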