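# Internal helpers shared across modules. Nothing here is exported.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so generators are pure functions of (params, seed).
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

is_binary <- function(x) {
  all(x == 0 | x == 1)
}

stop_waveseg <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "waveseg_error")))
}

check_even_dims <- function(x, what = "image") {
  d <- dim(x)
  if (d[1L] %% 2L != 0L || d[2L] %% 2L != 0L) {
    stop_waveseg(what, " dimensions must be multiples of 2, got ",
                 d[1L], "x", d[2L], class = "waveseg_size_error")
  }
  invisible(TRUE)
}

# The four corners of every 2x2 block: a=top-left, b=top-right, c=bottom-left,
# d=bottom-right, each as an (H/2, W/2) matrix.
blocks2 <- function(x) {
  ro <- seq(1L, nrow(x), by = 2L)
  co <- seq(1L, ncol(x), by = 2L)
  list(a = x[ro, co, drop = FALSE],
       b = x[ro, co + 1L, drop = FALSE],
       c = x[ro + 1L, co, drop = FALSE],
       d = x[ro + 1L, co + 1L, drop = FALSE])
}

# 2x nearest-neighbour (pixel replication) upsampling of a matrix.
upsample2 <- function(x) {
  x[rep(seq_len(nrow(x)), each = 2L), rep(seq_len(ncol(x)), each = 2L), drop = FALSE]
}

# 2x2 majority-vote downsampling of a binary matrix; ties (sum == 2) go to 1.
downsample_majority <- function(mask) {
  check_even_dims(mask, "mask")
  b <- blocks2(mask)
  (b$a + b$b + b$c + b$d >= 2) * 1
}

# Decimation by 2 with a 2x2 box anti-alias prefilter (matrix input).
decimate2 <- function(x) {
  check_even_dims(x, "image")
  b <- blocks2(x)
  (b$a + b$b + b$c + b$d) / 4
}

decimate2_rgb <- function(img) {
  out <- vapply(seq_len(dim(img)[3L]),
                function(k) decimate2(img[, , k]),
                matrix(0, nrow(img) / 2L, ncol(img) / 2L))
  round(out)
}

# Running 2-D box mean with window (2r+1)^2 and replicate padding, computed
# from an integral image so the cost is independent of r.
box_mean <- function(x, r) {
  r <- as.integer(r)
  if (r <= 0L) return(x)
  h <- nrow(x)
  w <- ncol(x)
  ri <- pmin(pmax(seq_len(h + 2L * r) - r, 1L), h)
  ci <- pmin(pmax(seq_len(w + 2L * r) - r, 1L), w)
  xp <- x[ri, ci, drop = FALSE]
  cs <- apply(xp, 2L, cumsum)
  cs <- t(apply(cs, 1L, cumsum))
  z <- matrix(0, h + 2L * r + 1L, w + 2L * r + 1L)
  z[-1L, -1L] <- cs
  n <- 2L * r + 1L
  i1 <- seq_len(h)
  j1 <- seq_len(w)
  (z[i1 + n, j1 + n] + z[i1, j1] - z[i1, j1 + n] - z[i1 + n, j1]) / (n * n)
}

# ITU-R BT.601 luminance of an 8-bit RGB array, as a matrix on the 0..255 scale.
luminance <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] < 3L) {
    stop_waveseg("expected an RGB array with 3 channels", class = "waveseg_format_error")
  }
  0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] + 0.114 * rgb[, , 3L]
}

#' Format a mean and standard deviation as "m ± s"
#'
#' @param mean,sd Numeric vectors.
#' @param digits Number of decimal places (default 3).
#' @return Character vector like `"0.804 ± 0.125"`.
#' @export
format_pm <- function(mean, sd, digits = 3) {
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
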