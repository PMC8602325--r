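# Pluggable per-sub-band probability predictors and the DiceCE training loss.
# A deep segmentation model (the production choice for real slides) plugs in
# through the "external" adapter; the reference implementations here are
# desk-scale and deterministic so the full pipeline is testable.

#' Specify a probability predictor
#'
#' Three reference predictors are provided:
#' \describe{
#'   \item{oracle}{Returns the training target derived from the supplied
#'     ground-truth context mask (the half-resolution 2x2 majority-vote
#'     downsampling for sub-band predictors, the mask itself for the spatial
#'     band), plus optional clamped Gaussian noise. Used to probe the fusion
#'     stages with controlled error.}
#'   \item{classical}{A training-free baseline: logistic transform of the
#'     box-smoothed tile intensity, `plogis(gain * (smooth(x) - center))`.}
#'   \item{external}{Adapter around a user function `fun(tile, context)`
#'     returning a \[0,1\] map of the tile's shape (e.g. wrapping a trained
#'     CNN exchanging float32 TIFF tiles).}
#' }
#'
#' @param name Predictor type: `"oracle"`, `"classical"` or `"external"`.
#' @param band Which representation the predictor sees: one of `"LL"`,
#'   `"LH"`, `"HL"`, `"HH"` (half-resolution sub-bands) or `"spatial"`.
#' @param noise_sd Oracle noise standard deviation (>= 0).
#' @param seed Oracle noise seed.
#' @param radius,gain,center Classical predictor parameters: box-filter
#'   radius in pixels, logistic gain, and intensity centering point.
#' @param fun Prediction function for `"external"`.
#' @return An object of class `"predictor_spec"`.
#' @export
predictor_spec <- function(name = c("oracle", "classical", "external"),
                           band = c("LL", "LH", "HL", "HH", "spatial"),
                           noise_sd = 0, seed = 1L,
                           radius = 2L, gain = 8, center = 0.5,
                           fun = NULL) {
  name <- match.arg(name)
  band <- match.arg(band)
  if (noise_sd < 0) stop_waveseg("noise_sd must be >= 0", class = "waveseg_size_error")
  if (name == "external" && !is.function(fun)) {
    stop_waveseg("external predictor needs a function in `fun`",
                 class = "waveseg_config_error")
  }
  structure(list(name = name, band = band, noise_sd = noise_sd,
                 seed = as.integer(seed), radius = as.integer(radius),
                 gain = gain, center = center, fun = fun),
            class = "predictor_spec")
}

#' Predict a tumor probability map for one tile
#'
#' Output has the same shape as `tile` with values in \[0, 1\], and is
#' deterministic given (inputs, spec).
#'
#' @param tile Numeric matrix (a sub-band or compressed tile), or an 8-bit
#'   RGB array for the spatial band (converted to \[0,1\] luminance for the
#'   classical predictor).
#' @param spec A [predictor_spec()].
#' @param context Ground-truth mask required by the oracle: at twice the tile
#'   resolution for sub-band predictors, at tile resolution for the spatial
#'   band.
#' @return Numeric probability matrix.
#' @export
predict_tile <- function(tile, spec, context = NULL) {
  stopifnot(inherits(spec, "predictor_spec"))
  tile_dim <- dim(tile)[1:2]
  if (spec$name == "oracle") {
    if (is.null(context)) {
      stop_waveseg("oracle predictor needs the ground-truth context mask",
                   class = "waveseg_config_error")
    }
    if (spec$band == "spatial") {
      if (!identical(dim(context), tile_dim)) {
        stop_waveseg("spatial oracle context must match the tile shape",
                     class = "waveseg_shape_error")
      }
      target <- context * 1.0
    } else {
      if (!identical(dim(context), 2L * tile_dim)) {
        stop_waveseg("sub-band oracle context must be at twice the tile resolution",
                     class = "waveseg_shape_error")
      }
      target <- downsample_majority(context) * 1.0
    }
    if (spec$noise_sd > 0) {
      target <- with_seed(spec$seed, clamp01(
        target + matrix(stats::rnorm(length(target), sd = spec$noise_sd),
                        nrow(target))))
    }
    return(target)
  }
  if (spec$name == "classical") {
    x <- if (length(dim(tile)) == 3L) luminance(tile) / 255 else tile
    if (any(!is.finite(x))) {
      stop_waveseg("tile contains non-finite values", class = "waveseg_format_error")
    }
    return(stats::plogis(spec$gain * (box_mean(x, spec$radius) - spec$center)))
  }
  out <- spec$fun(tile, context)
  if (!identical(dim(out)[1:2], tile_dim) || any(out < 0 | out > 1)) {
    stop_waveseg("external predictor must return a [0,1] map of the tile's shape",
                 class = "waveseg_validation_error")
  }
  out
}

#' DiceCE loss: soft Dice plus binary cross-entropy
#'
#' `loss = (1 - softDice) + meanBCE` with
#' `softDice = (2 * sum(p*g) + s) / (sum(p) + sum(g) + s)`, smoothing
#' `s = 1e-6`, and probabilities clamped to `[1e-7, 1 - 1e-7]` inside the
#' cross-entropy. Nonnegative, and minimal exactly when the prediction equals
#' the binary target (up to the clamps).
#'
#' @param pred Probability array in \[0, 1\].
#' @param target Binary array of the same shape.
#' @return Scalar loss.
#' @export
dicece_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target)) {
    stop_waveseg("pred and target shapes differ", class = "waveseg_shape_error")
  }
  if (any(pred < 0 | pred > 1)) {
    stop_waveseg("pred must lie in [0, 1]", class = "waveseg_validation_error")
  }
  s <- 1e-6
  soft_dice <- (2 * sum(pred * target) + s) / (sum(pred) + sum(target) + s)
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  ce <- mean(-(target * log(p) + (1 - target) * log(1 - p)))
  (1 - soft_dice) + ce
}
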