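# Sliding-window tile extraction and whole-image reassembly with overlap
# averaging. Coordinates are 0-based (row, col); tile windows are half-open
# [r, r + tile_size).

axis_origins <- function(extent, tile_size, stride) {
  if (extent <= tile_size) {
    list(origins = 0L, padded = tile_size)
  } else {
    n <- as.integer(ceiling((extent - tile_size) / stride)) + 1L
    list(origins = as.integer(seq(0L, by = stride, length.out = n)),
         padded = as.integer(tile_size + (n - 1L) * stride))
  }
}

#' Plan a sliding-window tile grid
#'
#' Origins along each axis are `0, stride, 2*stride, ...`. A canvas whose
#' extent is not reachable by that progression is logically padded (right and
#' bottom) up to the next valid origin, so the last tile abuts the padded
#' edge; a canvas smaller than the tile is padded up to one tile. Every canvas
#' pixel is covered by at least one window. Padding is filled with white at
#' extraction time and cropped away at assembly time.
#'
#' @param canvas_height,canvas_width Canvas dimensions in pixels.
#' @param tile_size Square tile side in pixels (default 1024, must be even).
#' @param stride Step between consecutive origins (default 256), in
#'   `(0, tile_size]`.
#' @return An object of class `"tile_grid"`: list with `tile_size`, `stride`,
#'   `canvas`, `padded`, and the row-major sorted `origins` matrix (0-based
#'   `(row, col)` pairs).
#' @export
plan_grid <- function(canvas_height, canvas_width, tile_size = 1024L, stride = 256L) {
  if (canvas_height <= 0 || canvas_width <= 0) {
    stop_waveseg("canvas dimensions must be positive", class = "waveseg_size_error")
  }
  if (tile_size %% 2L != 0L) {
    stop_waveseg("tile_size must be even", class = "waveseg_size_error")
  }
  if (stride <= 0 || stride > tile_size) {
    stop_waveseg("stride must lie in (0, tile_size]", class = "waveseg_size_error")
  }
  rows <- axis_origins(canvas_height, tile_size, stride)
  cols <- axis_origins(canvas_width, tile_size, stride)
  origins <- cbind(row = rep(rows$origins, each = length(cols$origins)),
                   col = rep(cols$origins, times = length(rows$origins)))
  structure(list(tile_size = as.integer(tile_size), stride = as.integer(stride),
                 canvas = c(as.integer(canvas_height), as.integer(canvas_width)),
                 padded = c(rows$padded, cols$padded),
                 origins = origins),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("tile grid: %d tiles of %d px, stride %d, canvas %d x %d (padded %d x %d)\n",
              nrow(x$origins), x$tile_size, x$stride,
              x$canvas[1L], x$canvas[2L], x$padded[1L], x$padded[2L]))
  invisible(x)
}

#' Extract sliding-window tiles from an image
#'
#' Each tile is the exact pixel window at its origin; window area beyond the
#' canvas (the logical padding) is filled with `pad`. Tiles are extracted
#' regardless of tissue content.
#'
#' @param image Matrix or `(h, w, 3)` array matching the grid's canvas.
#' @param grid A `"tile_grid"` planned for this image.
#' @param pad Fill value for out-of-canvas area (default 255, white; use 0 for
#'   masks).
#' @return List of tiles, each a list with `pixels` and 0-based `origin`.
#' @export
extract_tiles <- function(image, grid, pad = 255) {
  d <- dim(image)
  if (!identical(d[1:2], grid$canvas)) {
    stop_waveseg("grid was planned for a ", grid$canvas[1L], "x", grid$canvas[2L],
                 " canvas but the image is ", d[1L], "x", d[2L],
                 class = "waveseg_shape_error")
  }
  ts <- grid$tile_size
  nch <- if (length(d) == 3L) d[3L] else 1L
  padded <- array(pad, c(grid$padded[1L], grid$padded[2L], nch))
  padded[seq_len(d[1L]), seq_len(d[2L]), ] <- image
  lapply(seq_len(nrow(grid$origins)), function(i) {
    r <- unname(grid$origins[i, 1L])
    cc <- unname(grid$origins[i, 2L])
    px <- padded[r + seq_len(ts), cc + seq_len(ts), , drop = FALSE]
    if (nch == 1L) px <- px[, , 1L]
    list(pixels = px, origin = c(r, cc))
  })
}

#' Reassemble tile maps into a whole-image map by overlap averaging
#'
#' Each output pixel is the mean of the values of all tile windows covering
#' it. The padding region beyond the canvas is cropped away. Works at any
#' resolution: pass origins and canvas dimensions in the resolution of the
#' maps (e.g. halved for sub-band maps).
#'
#' @param tile_maps List of lists with fields `map` (square numeric matrix,
#'   all the same side) and 0-based `origin`.
#' @param canvas_height,canvas_width Output dimensions before padding.
#' @return Numeric matrix `(canvas_height, canvas_width)`.
#' @export
assemble_overlap_average <- function(tile_maps, canvas_height, canvas_width) {
  if (length(tile_maps) == 0L) {
    stop_waveseg("no tile maps to assemble", class = "waveseg_coverage_error")
  }
  side <- nrow(tile_maps[[1L]]$map)
  ph <- max(vapply(tile_maps, function(t) t$origin[1L], 0)) + side
  pw <- max(vapply(tile_maps, function(t) t$origin[2L], 0)) + side
  ph <- max(ph, canvas_height)
  pw <- max(pw, canvas_width)
  acc <- matrix(0, ph, pw)
  cnt <- matrix(0, ph, pw)
  for (t in tile_maps) {
    m <- t$map
    if (nrow(m) != side || ncol(m) != side) {
      stop_waveseg("tile maps must all be square with a common side",
                   class = "waveseg_shape_error")
    }
    ri <- t$origin[1L] + seq_len(side)
    ci <- t$origin[2L] + seq_len(side)
    acc[ri, ci] <- acc[ri, ci] + m
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  acc <- acc[seq_len(canvas_height), seq_len(canvas_width), drop = FALSE]
  cnt <- cnt[seq_len(canvas_height), seq_len(canvas_width), drop = FALSE]
  if (any(cnt == 0)) {
    stop_waveseg("some canvas pixels are covered by no tile",
                 class = "waveseg_coverage_error")
  }
  acc / cnt
}

# Per-pixel cover counts of a planned grid over its (unpadded) canvas.
coverage_counts <- function(grid) {
  ones <- lapply(seq_len(nrow(grid$origins)), function(i) {
    list(map = matrix(1, grid$tile_size, grid$tile_size),
         origin = grid$origins[i, ])
  })
  side <- grid$tile_size
  ph <- grid$padded[1L]
  pw <- grid$padded[2L]
  cnt <- matrix(0, ph, pw)
  for (t in ones) {
    ri <- t$origin[1L] + seq_len(side)
    ci <- t$origin[2L] + seq_len(side)
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  cnt[seq_len(grid$canvas[1L]), seq_len(grid$canvas[2L]), drop = FALSE]
}
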