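#' Single-level 2-D Haar wavelet decomposition
#'
#' Decomposes a single-channel image with even height and width into the four
#' half-resolution Haar sub-bands: the approximation `ll` plus the vertical
#' (`lh`), horizontal (`hl`) and diagonal (`hh`) detail bands. With the
#' default `"mean"` convention each 2x2 block `[[a, b], [c, d]]` maps to
#'
#' \deqn{ll = (a+b+c+d)/4,\quad lh = (a-b+c-d)/4,}
#' \deqn{hl = (a+b-c-d)/4,\quad hh = (a-b-c+d)/4,}
#'
#' so `ll` is the block mean: a constant image is a fixed point of `ll`, the
#' `ll` band of a \[0,1\]-valued image stays in \[0,1\], and the detail bands of
#' a binary mask lie in \[-0.5, 0.5\]. These properties are what make the
#' mask-derived weight maps of [wavelet_weight_maps()] interpretable. The
#' `"orthonormal"` convention (divisor 2 instead of 4) is energy-preserving;
#' perfect reconstruction holds under both.
#'
#' @param x Numeric matrix with even `nrow` and `ncol`.
#' @param convention `"mean"` (default) or `"orthonormal"` normalization.
#' @return An object of class `"subband_set"`: a list with matrices `ll`,
#'   `lh`, `hl`, `hh` of shape `dim(x)/2`, plus `level`, `source_dims` and
#'   `convention`.
#' @seealso [idwt2_haar()] for the exact inverse.
#' @examples
#' sb <- dwt2_haar(matrix(c(1, 5, 3, 7), 2, 2))
#' c(sb$ll, sb$lh, sb$hl, sb$hh)  # 4 -1 -2 0
#' @export
dwt2_haar <- function(x, convention = c("mean", "orthonormal")) {
  convention <- match.arg(convention)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_waveseg("dwt2_haar() expects a numeric matrix", class = "waveseg_format_error")
  }
  check_even_dims(x, "dwt2_haar() input")
  k <- if (convention == "mean") 4 else 2
  b <- blocks2(x)
  new_subband_set(ll = (b$a + b$b + b$c + b$d) / k,
                  lh = (b$a - b$b + b$c - b$d) / k,
                  hl = (b$a + b$b - b$c - b$d) / k,
                  hh = (b$a - b$b - b$c + b$d) / k,
                  source_dims = dim(x),
                  convention = convention)
}

#' Single-level 2-D Haar reconstruction
#'
#' Exact inverse of [dwt2_haar()]: reconstructs the full-resolution image from
#' a sub-band set (to well below 1e-9 absolute error).
#'
#' @param bands A `"subband_set"` as returned by [dwt2_haar()] or
#'   [subband_set()].
#' @return Numeric matrix of shape `bands$source_dims`.
#' @export
idwt2_haar <- function(bands) {
  if (!inherits(bands, "subband_set")) {
    stop_waveseg("idwt2_haar() expects a subband_set", class = "waveseg_format_error")
  }
  g <- if (bands$convention == "mean") 1 else 0.5
  ll <- bands$ll; lh <- bands$lh; hl <- bands$hl; hh <- bands$hh
  a <- (ll + lh + hl + hh) * g
  b <- (ll - lh + hl - hh) * g
  c_ <- (ll + lh - hl - hh) * g
  d <- (ll - lh - hl + hh) * g
  m <- 2L * nrow(ll)
  n <- 2L * ncol(ll)
  out <- matrix(0, m, n)
  ro <- seq(1L, m, by = 2L)
  co <- seq(1L, n, by = 2L)
  out[ro, co] <- a
  out[ro, co + 1L] <- b
  out[ro + 1L, co] <- c_
  out[ro + 1L, co + 1L] <- d
  out
}

#' Construct a sub-band set from four band matrices
#'
#' @param ll,lh,hl,hh Equal-shape numeric matrices (approximation, vertical,
#'   horizontal, diagonal).
#' @param convention Normalization tag, see [dwt2_haar()].
#' @return A `"subband_set"` object.
#' @export
subband_set <- function(ll, lh, hl, hh, convention = c("mean", "orthonormal")) {
  convention <- match.arg(convention)
  new_subband_set(ll, lh, hl, hh,
                  source_dims = 2L * dim(ll), convention = convention)
}

new_subband_set <- function(ll, lh, hl, hh, source_dims, convention) {
  d <- dim(ll)
  for (band in list(lh, hl, hh)) {
    if (!identical(dim(band), d)) {
      stop_waveseg("sub-band shapes differ", class = "waveseg_shape_error")
    }
  }
  structure(list(ll = ll, lh = lh, hl = hl, hh = hh,
                 level = 1L, source_dims = as.integer(source_dims),
                 convention = convention),
            class = "subband_set")
}

#' @export
print.subband_set <- function(x, ...) {
  cat(sprintf("Haar sub-band set (%s convention): 4 bands of %d x %d from %d x %d\n",
              x$convention, nrow(x$ll), ncol(x$ll),
              x$source_dims[1L], x$source_dims[2L]))
  invisible(x)
}

#' Write the four sub-bands as float32 TIFF files
#'
#' Files are written next to `prefix` with suffixes `_LL`, `_LH`, `_HL`,
#' `_HH` and extension `.tif`. Detail bands may be negative, so bands are not
#' range-checked here (unlike [write_prob_map()]).
#'
#' @param bands A `"subband_set"`.
#' @param prefix Path prefix (without extension).
#' @return Invisibly, the four file paths.
#' @export
write_subbands <- function(bands, prefix) {
  paths <- paste0(prefix, "_", c("LL", "LH", "HL", "HH"), ".tif")
  for (i in seq_along(paths)) {
    tiff::writeTIFF(bands[[i]], paths[i], bits.per.sample = 32L, compression = "none")
  }
  invisible(paths)
}
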