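# Z-axis (channel) compression: Otsu tissue masking and PCA of the (R, B)
# tissue values, plus the plain grayscale alternative used by the GRAY-DWT
# pipeline variants.

#' Otsu threshold of an 8-bit intensity sample
#'
#' Builds a 256-bin histogram (unit-width bins on \[0, 255\]) and returns the
#' split maximizing the between-class variance. Ties are broken by the lowest
#' qualifying split. The returned scalar is placed half a bin above the upper
#' edge of the lower class, so `value < threshold` and `value <= threshold`
#' select the same pixels for integer-valued input.
#'
#' @param values Numeric vector of intensities in \[0, 255\].
#' @return Threshold scalar.
#' @export
otsu_threshold <- function(values) {
  if (length(values) == 0L) {
    stop_waveseg("empty intensity sample", class = "waveseg_degenerate_error")
  }
  if (any(values < 0 | values > 255)) {
    stop_waveseg("intensities must lie in [0, 255]", class = "waveseg_format_error")
  }
  bin <- pmin(floor(values), 255)
  counts <- tabulate(bin + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L) {
    stop_waveseg("degenerate sample: a single distinct intensity",
                 class = "waveseg_degenerate_error")
  }
  p <- counts / sum(counts)
  omega <- cumsum(p)                # P(class 0) for split at t = 0..255
  mu <- cumsum(p * (0:255))
  mu_total <- mu[256L]
  sigma_b <- (mu_total * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  t_best <- which.max(sigma_b[1:255]) - 1L   # which.max takes the first (lowest) maximum
  t_best + 0.5
}

#' Otsu tissue mask of an RGB image
#'
#' Computes the BT.601 luminance, thresholds it with [otsu_threshold()], and
#' marks pixels darker than the threshold as tissue (the H&E background is
#' near-white).
#'
#' @param rgb 8-bit RGB array `(h, w, 3)`.
#' @return An object of class `"tissue_mask"`: list with the binary `mask`
#'   (1 = tissue) and `threshold` used.
#' @export
tissue_mask <- function(rgb) {
  lum <- luminance(rgb)
  thr <- otsu_threshold(as.vector(lum))
  structure(list(mask = (lum < thr) * 1, threshold = thr),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("Otsu tissue mask: %d x %d, tissue fraction %.3f, threshold %.1f\n",
              nrow(x$mask), ncol(x$mask), mean(x$mask), x$threshold))
  invisible(x)
}

#' PCA channel compression of an RGB tile
#'
#' Projects the (R, B) values of tissue pixels onto the first principal
#' component of their 2x2 sample covariance (green is dropped: in H&E it is
#' the most redundant channel once the red-blue contrast between eosin and
#' hematoxylin is captured). The eigenvector is oriented so that its dot
#' product with (-1, +1) is nonnegative, making higher output consistently
#' more blue-dominant (hematoxylin, nuclei). Projections are min-max rescaled
#' to \[0, 1\] over tissue pixels; non-tissue pixels are set to 0.
#'
#' If all tissue pixels are identical the projection has zero variance; the
#' tile then comes back as constant 0 over tissue with `degenerate = TRUE`
#' rather than an error, so background-only tiles flow through the pipeline.
#'
#' @param rgb 8-bit RGB array `(h, w, 3)`.
#' @param mask Optional binary tissue mask matrix (1 = tissue); computed with
#'   [tissue_mask()] when omitted. Fit scope is per tile: the statistics come
#'   from this tile's own tissue pixels.
#' @param origin 0-based `(row, col)` origin carried through for bookkeeping.
#' @return An object of class `"compressed_tile"`: list with `values` (matrix
#'   in \[0,1\]), `origin`, `method = "pca"`, `degenerate`, and the fitted
#'   `center` and `rotation`.
#' @export
pca_compress <- function(rgb, mask = NULL, origin = c(0L, 0L)) {
  if (is.null(mask)) mask <- tissue_mask(rgb)$mask
  if (inherits(mask, "tissue_mask")) mask <- mask$mask
  if (!identical(dim(mask), dim(rgb)[1:2])) {
    stop_waveseg("mask is not registered to the tile", class = "waveseg_shape_error")
  }
  idx <- which(mask == 1)
  if (length(idx) < 2L) {
    stop_waveseg("fewer than 2 tissue pixels", class = "waveseg_degenerate_error")
  }
  rv <- rgb[, , 1L][idx]
  bv <- rgb[, , 3L][idx]
  ctr <- c(mean(rv), mean(bv))
  xr <- rv - ctr[1L]
  xb <- bv - ctr[2L]
  cv <- matrix(c(sum(xr * xr), sum(xr * xb), sum(xr * xb), sum(xb * xb)),
               2L, 2L) / (length(idx) - 1L)
  ev <- eigen(cv, symmetric = TRUE)
  v <- ev$vectors[, 1L]
  if (sum(v * c(-1, 1)) < 0) v <- -v
  proj <- xr * v[1L] + xb * v[2L]
  rng <- max(proj) - min(proj)
  out <- matrix(0, nrow(mask), ncol(mask))
  degenerate <- rng < 1e-9
  if (!degenerate) out[idx] <- (proj - min(proj)) / rng
  structure(list(values = out, origin = as.integer(origin), method = "pca",
                 degenerate = degenerate, center = ctr, rotation = v),
            class = "compressed_tile")
}

#' Grayscale channel compression of an RGB tile
#'
#' BT.601 luminance rescaled to \[0, 1\]; no tissue masking is applied.
#'
#' @inheritParams pca_compress
#' @return A `"compressed_tile"` with `method = "gray"`.
#' @export
grayscale_convert <- function(rgb, origin = c(0L, 0L)) {
  structure(list(values = luminance(rgb) / 255, origin = as.integer(origin),
                 method = "gray", degenerate = FALSE,
                 center = NULL, rotation = NULL),
            class = "compressed_tile")
}

#' @export
print.compressed_tile <- function(x, ...) {
  cat(sprintf("compressed tile (%s): %d x %d at origin (%d, %d)%s\n",
              x$method, nrow(x$values), ncol(x$values),
              x$origin[1L], x$origin[2L],
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
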