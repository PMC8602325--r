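# The user-facing estimator: fit the wavelet-weighted ensemble band weights
# to an evaluation cohort by exhaustive grid search on mean Dice.

#' Fit wavelet-weighted ensemble band weights
#'
#' `wwe_fit()` estimates the four sub-band weights of the wavelet-weighted
#' ensemble by exhaustively maximizing mean Dice over an evaluation set
#' (see [optimize_weights()] for the search itself). The fitted object keeps
#' the full candidate table, so weight-sensitivity summaries and saturation
#' plots come for free.
#'
#' @param data Either a `"waveseg_cohort"` / list of slides (the
#'   compressed-domain stages are run with `config` to build the evaluation
#'   set) or a ready evaluation set (list of slides with `r_ll`..`r_hh`,
#'   `tissue`, `gt`), e.g. from [build_eval_set()].
#' @param grid Weight values tried on each band (default `0.3, 0.6, ..., 3.0`).
#' @param epsilon Offset added to the mask-derived wavelet weights.
#' @param threshold Binarization threshold for the Dice objective.
#' @param config [pipeline_config()] used when `data` is a cohort.
#' @return An object of class `"wwe"` with components `coefficients`
#'   (named `w1..w4`), `epsilon`, `score`, `table`, `grid`, `threshold`,
#'   `convention`, `n` and `call`. Methods: [print.wwe()], [summary.wwe()],
#'   [coef.wwe()], [predict.wwe()], [plot.wwe()].
#' @examples
#' \donttest{
#' cohort <- generate_cohort(4, slide_params(width = 256, height = 256), seed = 1)
#' cfg <- pipeline_config("pca_dwt_wwe", tile_size = 128, stride = 64,
#'                        noise_sd = c(LH = 0.2, HL = 0.2, HH = 0.2))
#' fit <- wwe_fit(cohort, grid = c(0.5, 1, 2), config = cfg)
#' coef(fit)
#' }
#' @export
wwe_fit <- function(data, grid = seq(0.3, 3.0, by = 0.3), epsilon = 0.1,
                    threshold = 0.5, config = pipeline_config("pca_dwt_wwe")) {
  eval_set <- if (is_eval_set(data)) data else build_eval_set(data, config)
  search <- optimize_weights(eval_set, grid = grid, epsilon = epsilon,
                             threshold = threshold,
                             convention = config$convention)
  w <- search$weights
  structure(list(coefficients = c(w1 = w$w1, w2 = w$w2, w3 = w$w3, w4 = w$w4),
                 epsilon = epsilon, score = search$score,
                 table = search$table, grid = sort(unique(grid)),
                 threshold = threshold, convention = config$convention,
                 n = length(eval_set), call = match.call()),
            class = "wwe")
}

is_eval_set <- function(x) {
  is.list(x) && length(x) > 0L && is.list(x[[1L]]) &&
    all(c("r_ll", "r_lh", "r_hl", "r_hh", "gt") %in% names(x[[1L]]))
}

#' @export
print.wwe <- function(x, ...) {
  cat("Wavelet-weighted ensemble fit\n\nCall:\n")
  print(x$call)
  cat("\nCoefficients (band weights):\n")
  print(x$coefficients)
  cat(sprintf("epsilon: %.2f\n", x$epsilon))
  cat(sprintf("\nMean Dice at threshold %.2f over %d slides: %.4f\n",
              x$threshold, x$n, x$score))
  invisible(x)
}

#' @export
coef.wwe <- function(object, ...) object$coefficients

#' Summarize a fitted wavelet-weighted ensemble
#'
#' Reports, for each band, the best achievable mean Dice as a function of
#' that band's weight (maximized over the other three), plus the LL-weight
#' saturation point: the smallest `w1` whose best score comes within `tol` of
#' the overall optimum.
#'
#' @param object A `"wwe"` fit.
#' @param tol Plateau tolerance on mean Dice (default 0.005).
#' @param ... Unused.
#' @return An object of class `"summary.wwe"`.
#' @export
summary.wwe <- function(object, tol = 0.005, ...) {
  tab <- object$table
  marginal <- lapply(c("w1", "w2", "w3", "w4"), function(wn) {
    best <- tapply(tab$mean_dice, tab[[wn]], max)
    data.frame(weight = as.numeric(names(best)), best_dice = as.numeric(best))
  })
  names(marginal) <- c("w1", "w2", "w3", "w4")
  m1 <- marginal$w1
  sat <- m1$weight[m1$best_dice >= max(m1$best_dice) - tol][1L]
  structure(list(fit = object, marginal = marginal, saturation_w1 = sat,
                 tol = tol),
            class = "summary.wwe")
}

#' @export
print.summary.wwe <- function(x, ...) {
  print(x$fit)
  cat("\nBest mean Dice by LL weight (w1), maximized over w2..w4:\n")
  print(x$marginal$w1, row.names = FALSE)
  cat(sprintf("\nw1 saturation point (within %.3f of optimum): %.2f\n",
              x$tol, x$saturation_w1))
  invisible(x)
}

#' Predict with a fitted wavelet-weighted ensemble
#'
#' Fuses a new slide's sub-band probability maps with the fitted weights.
#'
#' @param object A `"wwe"` fit.
#' @param newdata One evaluation slide (list with `r_ll`..`r_hh` and
#'   `tissue`) or a list of them.
#' @param type `"prob"` for the probability map, `"class"` for the mask
#'   binarized at the fitted threshold.
#' @param ... Unused.
#' @return A probability (or binary) matrix, or a list of them.
#' @export
predict.wwe <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  w <- object$coefficients
  weights <- ensemble_weights(w[["w1"]], w[["w2"]], w[["w3"]], w[["w4"]],
                              object$epsilon)
  fuse1 <- function(s) {
    maps <- wavelet_weight_maps(as_binary_mask(s$tissue), weights,
                                object$convention)
    out <- wwe_fuse(s$r_ll, s$r_lh, s$r_hl, s$r_hh, maps)
    if (type == "class") out <- (out >= object$threshold) * 1 else out
  }
  if (is_eval_set(newdata)) return(lapply(newdata, fuse1))
  fuse1(newdata)
}

#' Plot the Dice saturation curve of a fitted ensemble
#'
#' Draws the best achievable mean Dice against the weight of one band
#' (default the LL weight `w1`), maximized over the other bands -- the
#' weight-sensitivity view in which the LL weight rises steeply at small
#' values and saturates.
#'
#' @param x A `"wwe"` fit.
#' @param which Band weight to vary: `"w1"`, `"w2"`, `"w3"` or `"w4"`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the data frame plotted.
#' @export
plot.wwe <- function(x, which = "w1", ...) {
  which <- match.arg(which, c("w1", "w2", "w3", "w4"))
  m <- summary(x)$marginal[[which]]
  graphics::plot(m$weight, m$best_dice, type = "b", pch = 19,
                 xlab = paste("band weight", which),
                 ylab = "best mean Dice", ...)
  graphics::abline(h = max(m$best_dice), lty = 3)
  invisible(m)
}
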