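# Reading and writing images, masks, probability maps and metric tables.
# 8-bit images travel as PNG or TIFF; probability maps as 32-bit float
# single-channel TIFF so that ensembling stays lossless.

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop_waveseg("unsupported image format: .", ext, class = "waveseg_format_error")
}

#' Read an 8-bit PNG or TIFF image
#'
#' Returns an integer array on the 0..255 scale: `(h, w, 3)` for RGB (an alpha
#' channel, if present, is dropped) or a matrix for single-channel images.
#' Inputs with more than 8 bits per sample are rejected, not silently
#' rescaled.
#'
#' @param path File path.
#' @return Integer array or matrix of 0..255 values.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop_waveseg("file not found: ", path, class = "waveseg_io_error")
  }
  fmt <- img_format(path)
  if (fmt == "png") {
    x <- png::readPNG(path, info = TRUE)
    depth <- attr(x, "info")$bit.depth
  } else {
    x <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(x, "bits.per.sample")
  }
  if (!is.null(depth) && any(depth > 8)) {
    stop_waveseg(path, " has ", max(depth), " bits per sample; only 8-bit images are supported",
                 class = "waveseg_format_error")
  }
  if (length(dim(x)) == 3L && dim(x)[3L] >= 3L) {
    x <- x[, , 1:3, drop = FALSE]
  } else if (length(dim(x)) == 3L) {
    x <- x[, , 1L]
  }
  out <- round(x * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write an 8-bit image as PNG or TIFF
#'
#' @param image Matrix or `(h, w, 3)` array of 0..255 values.
#' @param path Output path; format follows the extension.
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path) {
  if (any(image < 0 | image > 255)) {
    stop_waveseg("image values must lie in [0, 255]", class = "waveseg_format_error")
  }
  x <- image / 255
  if (img_format(path) == "png") {
    png::writePNG(x, path)
  } else {
    tiff::writeTIFF(x, path, bits.per.sample = 8L, compression = "none")
  }
  invisible(path)
}

#' Read a binary mask from PNG or TIFF
#'
#' Accepts both the 0/1 and the 0/255 encodings and normalizes to 0/1.
#'
#' @param path File path.
#' @return Integer matrix with values in \{0, 1\}.
#' @export
read_mask <- function(path) {
  x <- read_image(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  u <- sort(unique(as.vector(x)))
  if (!all(u %in% c(0L, 1L)) && !all(u %in% c(0L, 255L))) {
    stop_waveseg(path, " is not a binary mask (values other than {0,1}/{0,255})",
                 class = "waveseg_format_error")
  }
  (x > 0) * 1L
}

#' Write a binary mask as a single-channel PNG/TIFF coded 0/255
#'
#' @param mask Binary matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  if (!is_binary(mask)) {
    stop_waveseg("mask must be binary", class = "waveseg_format_error")
  }
  write_image(mask * 255L, path)
}

#' Persist a probability map as 32-bit float single-channel TIFF
#'
#' Round trips preserve values to within 1e-6 (float32 precision) and are
#' byte-stable across repeated writes of the same map.
#'
#' @param map Numeric matrix with values in \[0, 1\].
#' @param path Output path (`.tif`).
#' @return Invisibly, `path`.
#' @export
write_prob_map <- function(map, path) {
  if (!is.matrix(map) || !is.numeric(map)) {
    stop_waveseg("probability map must be a numeric matrix", class = "waveseg_format_error")
  }
  if (any(!is.finite(map)) || any(map < 0 | map > 1)) {
    stop_waveseg("probability values must lie in [0, 1]", class = "waveseg_validation_error")
  }
  tiff::writeTIFF(map, path, bits.per.sample = 32L, compression = "none")
  invisible(path)
}

#' Read a probability map written by [write_prob_map()]
#'
#' @param path File path.
#' @return Numeric matrix in \[0, 1\].
#' @export
read_prob_map <- function(path) {
  if (!file.exists(path)) {
    stop_waveseg("file not found: ", path, class = "waveseg_io_error")
  }
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  x
}

#' Write evaluation records as CSV with a mean/sd summary JSON alongside
#'
#' The CSV holds one row per record with columns slide_id, class_label,
#' method, threshold, dice, acc, jac. The JSON (same path with extension
#' `.json` appended to the stem) holds the per-class and overall mean and
#' sample standard deviation of each metric, per method.
#'
#' @param records Non-empty data frame of evaluation records (as produced by
#'   [threshold_sweep()]).
#' @param path CSV output path.
#' @return Invisibly, a list with the `csv` and `json` paths.
#' @export
write_metrics <- function(records, path) {
  cols <- c("slide_id", "class_label", "method", "threshold", "dice", "acc", "jac")
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop_waveseg("records must be a non-empty data frame", class = "waveseg_validation_error")
  }
  if (!all(cols %in% names(records))) {
    stop_waveseg("records must have columns ", paste(cols, collapse = ", "),
                 class = "waveseg_format_error")
  }
  utils::write.csv(records[, cols], path, row.names = FALSE)
  summ <- aggregate_by_class(records)
  json_path <- paste0(tools::file_path_sans_ext(path), "_summary.json")
  jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(csv = path, json = json_path))
}

#' Render a probability map as a heat-map overlay on the slide image
#'
#' Visualization utility with a fixed blue-to-red colormap: the overlay is
#' `(1 - alpha) * image + alpha * colormap(p)`. Rendering is 8-bit and lossy;
#' quantitative work should use [write_prob_map()].
#'
#' @param image 8-bit RGB array.
#' @param map Probability map of matching height/width.
#' @param alpha Overlay opacity in \[0, 1\].
#' @return 8-bit integer RGB array.
#' @export
overlay_heatmap <- function(image, map, alpha = 0.4) {
  if (!identical(dim(image)[1:2], dim(map))) {
    stop_waveseg("map and image dimensions differ", class = "waveseg_shape_error")
  }
  heat_r <- 255 * clamp01(1.5 * map)
  heat_b <- 255 * clamp01(1.5 * (1 - map))
  heat_g <- 255 * clamp01(1 - 2 * abs(map - 0.5))
  out <- image
  out[, , 1L] <- as.integer(round((1 - alpha) * image[, , 1L] + alpha * heat_r))
  out[, , 2L] <- as.integer(round((1 - alpha) * image[, , 2L] + alpha * heat_g))
  out[, , 3L] <- as.integer(round((1 - alpha) * image[, , 3L] + alpha * heat_b))
  out
}
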