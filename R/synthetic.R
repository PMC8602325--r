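# Synthetic pseudo-H&E slide generator. Every downstream stage of the package
# is testable against these slides and their exact ground-truth masks; no
# external cohort is required.

.waveseg_classes <- c("ADENOCA", "TAH", "TAL", "CARCINOID", "HYPERP")

# Tumor texture per lesion class, encoded purely as nucleus-speckle frequency
# content: smoothing radius of the latent field (larger = lower-frequency,
# blobbier chromatin) and nucleus density inside the lesion.
.class_texture <- list(
  ADENOCA   = list(radius = 1L, density = 0.38),
  TAH       = list(radius = 0L, density = 0.45),  # dense high-frequency speckle
  TAL       = list(radius = 2L, density = 0.32),
  CARCINOID = list(radius = 4L, density = 0.35),
  HYPERP    = list(radius = 8L, density = 0.50)   # smooth low-frequency blobs
)

#' Generator configuration for synthetic pseudo-H&E slides
#'
#' @param width,height Canvas size in pixels; must be multiples of 2 (the
#'   downstream wavelet transform needs even dimensions). Default 2048.
#' @param class_label Lesion class, one of `"ADENOCA"`, `"TAH"`, `"TAL"`,
#'   `"CARCINOID"`, `"HYPERP"`; controls only the texture frequency content of
#'   tumor regions.
#' @param n_tumor Number of tumor regions (elliptical, clipped to tissue).
#' @param tumor_frac Two-element range for the tumor-pixel fraction of the
#'   canvas; region radii are rescaled until the drawn fraction falls inside.
#' @param tumor_radius Two-element range of region semi-axes as fractions of
#'   `min(width, height)`.
#' @param background_level Mean background intensity (near-white; background
#'   pixels are clipped to stay at or above 232 on every channel).
#' @return An object of class `"slide_params"`.
#' @export
slide_params <- function(width = 2048L, height = 2048L,
                         class_label = "ADENOCA",
                         n_tumor = 3L,
                         tumor_frac = c(0.05, 0.25),
                         tumor_radius = c(0.04, 0.15),
                         background_level = 246) {
  if (width %% 2L != 0L || height %% 2L != 0L) {
    stop_waveseg("canvas width and height must be multiples of 2",
                 class = "waveseg_size_error")
  }
  class_label <- match.arg(class_label, .waveseg_classes)
  if (n_tumor < 0L) {
    stop_waveseg("n_tumor must be nonnegative", class = "waveseg_size_error")
  }
  if (length(tumor_frac) != 2L || tumor_frac[1L] > tumor_frac[2L] ||
      tumor_frac[1L] < 0 || tumor_frac[2L] >= 1) {
    stop_waveseg("tumor_frac must be an increasing range inside [0, 1)",
                 class = "waveseg_size_error")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 class_label = class_label, n_tumor = as.integer(n_tumor),
                 tumor_frac = tumor_frac, tumor_radius = tumor_radius,
                 background_level = background_level),
            class = "slide_params")
}

# Binary ellipse, axis-aligned, evaluated on an h x w grid.
ellipse_mask <- function(h, w, cy, cx, ry, rx) {
  yy <- ((seq_len(h) - cy) / ry)^2
  xx <- ((seq_len(w) - cx) / rx)^2
  outer(yy, xx, "+") <= 1
}

#' Generate one synthetic pseudo-H&E slide with ground truth
#'
#' Builds a slide at half resolution (tissue and tumor geometry) and
#' replicates 2x2 to full resolution, so annotation boundaries are aligned to
#' the wavelet blocks; texture and noise are drawn at full resolution. The
#' color model is a two-stain linear absorption: a hematoxylin density (high
#' at nuclei) and an eosin density (high in stroma) each subtract from white
#' with stain-specific channel coefficients, giving a near-white background,
#' pink stroma (R > G, B > G), blue-purple nuclei (B > R > G), and a red-blue
#' channel correlation over tissue that exceeds the red-green one (green
#' additionally carries independent eosin-intensity variation). Tumor regions
#' differ from normal tissue only in nucleus-speckle frequency and density,
#' set by the class label.
#'
#' Identical `(params, seed)` reproduce bit-identical output; the caller's RNG
#' state is left untouched.
#'
#' @param params A [slide_params()] configuration.
#' @param seed Integer seed.
#' @return An object of class `"waveseg_slide"`: list with `image` (8-bit
#'   integer array `(h, w, 3)`), `mask` (binary matrix, 1 = tumor), `tissue`
#'   (binary matrix of the painted tissue footprint), `class_label`, `seed`
#'   and `params`.
#' @export
generate_slide <- function(params = slide_params(), seed = 1L) {
  stopifnot(inherits(params, "slide_params"))
  with_seed(seed, {
    h <- params$height
    w <- params$width
    h2 <- h %/% 2L
    w2 <- w %/% 2L

    # --- geometry at half resolution -------------------------------------
    tissue2 <- matrix(FALSE, h2, w2)
    for (i in 1:3) {
      tissue2 <- tissue2 | ellipse_mask(
        h2, w2,
        cy = h2 * runif(1, 0.40, 0.60), cx = w2 * runif(1, 0.40, 0.60),
        ry = h2 * runif(1, 0.28, 0.40), rx = w2 * runif(1, 0.28, 0.40))
    }

    tumor2 <- matrix(FALSE, h2, w2)
    if (params$n_tumor > 0L) {
      t_idx <- which(tissue2)
      centers <- arrayInd(sample(t_idx, params$n_tumor, replace = TRUE),
                          dim(tissue2))
      rmin <- min(h, w)
      base_r <- runif(params$n_tumor, params$tumor_radius[1L],
                      params$tumor_radius[2L]) * rmin / 2
      aspect <- runif(params$n_tumor, 0.6, 1.4)
      target <- mean(params$tumor_frac)
      scale <- 1
      for (iter in 1:25) {
        tumor2 <- matrix(FALSE, h2, w2)
        for (k in seq_len(params$n_tumor)) {
          tumor2 <- tumor2 | ellipse_mask(h2, w2,
                                          cy = centers[k, 1L], cx = centers[k, 2L],
                                          ry = base_r[k] * scale,
                                          rx = base_r[k] * scale * aspect[k])
        }
        tumor2 <- tumor2 & tissue2
        frac <- sum(tumor2) / (h2 * w2)
        if (frac >= params$tumor_frac[1L] && frac <= params$tumor_frac[2L]) break
        scale <- scale * sqrt(target / max(frac, 1e-6))
      }
    }

    tissue <- upsample2(tissue2)
    tumor <- upsample2(tumor2)

    # --- texture and stain fields at full resolution ---------------------
    nucleus <- matrix(runif(h * w), h, w) < 0.22
    if (any(tumor)) {
      tex <- .class_texture[[params$class_label]]
      f <- matrix(runif(h * w), h, w)
      if (tex$radius > 0L) f <- box_mean(f, tex$radius)
      thr <- stats::quantile(f[tumor], 1 - tex$density)
      nucleus[tumor] <- (f > thr)[tumor]
    }

    # Stain densities: hematoxylin follows the nucleus speckle (with mild
    # per-nucleus intensity variation), eosin is a smooth stroma-wide field.
    # R and B load on both with similar ratios while G both absorbs more and
    # carries independent measurement noise, so the red-blue correlation over
    # tissue exceeds the red-green one.
    shade <- 1 + 0.3 * (box_mean(matrix(runif(h * w), h, w), 6L) - 0.5)
    eosin_var <- box_mean(matrix(runif(h * w), h, w), 10L)
    hd <- nucleus * matrix(runif(h * w, 0.8, 1), h, w)
    ed <- 0.7 * shade + 0.3 * (eosin_var - 0.5)

    rch <- 255 - 60 * hd - 42 * ed + matrix(rnorm(h * w, sd = 4), h, w)
    gch <- 255 - 60 * hd - 135 * ed + matrix(rnorm(h * w, sd = 18), h, w)
    bch <- 255 - 40 * hd - 64 * ed + matrix(rnorm(h * w, sd = 4), h, w)

    bg <- function() pmin(pmax(params$background_level +
                                 matrix(rnorm(h * w, sd = 3), h, w), 232), 255)
    rch <- ifelse(tissue, rch, bg())
    gch <- ifelse(tissue, gch, bg())
    bch <- ifelse(tissue, bch, bg())

    img <- array(0L, c(h, w, 3L))
    img[, , 1L] <- as.integer(round(pmin(pmax(rch, 0), 255)))
    img[, , 2L] <- as.integer(round(pmin(pmax(gch, 0), 255)))
    img[, , 3L] <- as.integer(round(pmin(pmax(bch, 0), 255)))

    structure(list(image = img, mask = tumor * 1L, tissue = tissue * 1L,
                   class_label = params$class_label,
                   seed = as.integer(seed), params = params),
              class = "waveseg_slide")
  })
}

#' @export
print.waveseg_slide <- function(x, ...) {
  cat(sprintf("synthetic slide: %d x %d, class %s, tumor fraction %.3f (seed %d)\n",
              nrow(x$mask), ncol(x$mask), x$class_label, mean(x$mask), x$seed))
  invisible(x)
}

#' Generate a cohort of synthetic slides
#'
#' Per-slide seeds are derived deterministically from `seed`. Class labels
#' cycle through the five lesion classes by default, or follow `proportions`
#' (largest-remainder allocation, so realized counts match the requested
#' proportions to within one slide).
#'
#' @param n Number of slides (>= 1).
#' @param params Shared [slide_params()]; the class label is overridden per
#'   slide.
#' @param seed Integer seed for the cohort.
#' @param proportions Optional named numeric vector of class proportions.
#' @return An object of class `"waveseg_cohort"`: list with `slides` and an
#'   `index` data frame (slide_id, class_label, seed).
#' @export
generate_cohort <- function(n, params = slide_params(), seed = 1L,
                            proportions = NULL) {
  if (n < 1L) stop_waveseg("n must be >= 1", class = "waveseg_size_error")
  if (is.null(proportions)) {
    labels <- rep(.waveseg_classes, length.out = n)
  } else {
    if (is.null(names(proportions)) ||
        !all(names(proportions) %in% .waveseg_classes)) {
      stop_waveseg("proportions must be named by class", class = "waveseg_format_error")
    }
    p <- proportions / sum(proportions)
    counts <- floor(p * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(p * n - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    labels <- rep(names(p), times = counts)
  }
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  slides <- lapply(seq_len(n), function(i) {
    p <- params
    p$class_label <- labels[i]
    generate_slide(p, seeds[i])
  })
  index <- data.frame(slide_id = sprintf("slide_%03d", seq_len(n)),
                      class_label = labels,
                      seed = seeds,
                      stringsAsFactors = FALSE)
  structure(list(slides = slides, index = index), class = "waveseg_cohort")
}

#' @export
print.waveseg_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d slides\n", nrow(x$index)))
  print(table(x$index$class_label))
  invisible(x)
}

#' Write a cohort to disk as PNG images and masks plus an index CSV
#'
#' Images are 8-bit RGB PNG, masks single-channel PNG coded 0/255. The index
#' CSV has columns slide_id, class_label, image_path, mask_path, seed.
#'
#' @param cohort A `"waveseg_cohort"`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the index data frame with file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- cohort$index
  idx$image_path <- file.path(dir, paste0(idx$slide_id, ".png"))
  idx$mask_path <- file.path(dir, paste0(idx$slide_id, "_mask.png"))
  for (i in seq_len(nrow(idx))) {
    write_image(cohort$slides[[i]]$image, idx$image_path[i])
    write_mask(cohort$slides[[i]]$mask, idx$mask_path[i])
  }
  idx <- idx[, c("slide_id", "class_label", "image_path", "mask_path", "seed")]
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(idx)
}

#' Noisy probability-map fixture from a binary mask
#'
#' Casts the mask to float and adds i.i.d. Gaussian noise, clamped to
#' \[0, 1\]. With `noise_sd = 0` the mask is returned exactly. Used as a
#' controlled stand-in for predictor output when testing the fusion stages.
#'
#' @param mask Binary matrix.
#' @param noise_sd Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Numeric matrix in \[0, 1\].
#' @export
make_probability_fixture <- function(mask, noise_sd = 0, seed = 1L) {
  if (!is_binary(mask)) {
    stop_waveseg("mask must be binary", class = "waveseg_format_error")
  }
  if (noise_sd < 0) {
    stop_waveseg("noise_sd must be >= 0", class = "waveseg_size_error")
  }
  m <- mask * 1.0
  if (noise_sd == 0) return(m)
  with_seed(seed, clamp01(m + matrix(rnorm(length(m), sd = noise_sd), nrow(m))))
}
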