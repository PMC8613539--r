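#' Magnitude cine image series
#'
#' Container for a real-valued 2D+time magnitude image series. Frames are
#' stored as an `H x W x T` array; intensities are expected in \[0, 1\]
#' after [normalize_series()].
#'
#' @param frames Numeric array `H x W x T` (a single `H x W` matrix is
#'   promoted to one frame).
#' @param pixel_mm Pixel size in mm.
#' @param tr_ms Repetition time of the underlying sequence in ms.
#' @param view Orientation class label (e.g. "SAX", "FCH", ...).
#' @param subject Subject/series identifier.
#' @return An object of class `cine_series`.
#' @export
cine_series <- function(frames, pixel_mm = 1.67, tr_ms = 3.2,
                        view = NA_character_, subject = NA_character_) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be an H x W x T array", call. = FALSE)
  if (anyNA(frames) || !all(is.finite(frames)))
    stop("frames must be finite", call. = FALSE)
  structure(list(frames = frames, pixel_mm = pixel_mm, tr_ms = tr_ms,
                 view = view, subject = subject),
            class = "cine_series")
}

#' @export
dim.cine_series <- function(x) dim(x$frames)

#' Number of frames in a cine series
#' @param x A `cine_series`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) dim(x$frames)[3]

#' @export
print.cine_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cine_series> %d x %d, %d frames, view=%s, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$view, min(x$frames), max(x$frames)))
  invisible(x)
}

with_frames <- function(series, frames) {
  out <- series
  out$frames <- frames
  out
}

#' Normalize a series to the unit intensity range
#'
#' Min-max normalization over the whole series: `(x - min) / (max - min)`.
#' A constant series maps to all zeros.
#'
#' @param series A `cine_series` (or bare numeric array).
#' @return Series of the same class with intensities in \[0, 1\].
#' @export
normalize_series <- function(series) {
  x <- if (inherits(series, "cine_series")) series$frames else series
  if (anyNA(x)) stop("series contains NA/NaN", call. = FALSE)
  lo <- min(x); hi <- max(x)
  y <- if (hi > lo) (x - lo) / (hi - lo) else array(0, dim = dim(x))
  if (inherits(series, "cine_series")) with_frames(series, y) else y
}

#' Center-crop all frames of a series
#'
#' @param series A `cine_series` or `H x W x T` array.
#' @param size Output side length (default 128).
#' @return Cropped series, `size x size` spatially.
#' @export
center_crop <- function(series, size = 128L) {
  x <- if (inherits(series, "cine_series")) series$frames else series
  d <- dim(x)
  size <- as.integer(size)
  if (size > d[1] || size > d[2])
    stop("crop size exceeds input dimensions", call. = FALSE)
  r0 <- (d[1] - size) %/% 2L
  c0 <- (d[2] - size) %/% 2L
  y <- x[r0 + seq_len(size), c0 + seq_len(size), , drop = FALSE]
  if (inherits(series, "cine_series")) with_frames(series, y) else y
}

# Keys bicubic kernel (a = -0.5), the standard photographic bicubic.
cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  w <- numeric(length(t))
  i1 <- t <= 1
  w[i1] <- (a + 2) * t[i1]^3 - (a + 3) * t[i1]^2 + 1
  i2 <- t > 1 & t < 2
  w[i2] <- a * t[i2]^3 - 5 * a * t[i2]^2 + 8 * a * t[i2] - 4 * a
  w
}

# 1D bicubic interpolation matrix mapping n_src samples to n_dst samples,
# aligned on pixel centers; edge samples clamp-replicated.
cubic_matrix <- function(n_src, n_dst) {
  scale <- n_src / n_dst
  # pixel-center alignment: dst center j maps to src coordinate
  pos <- (seq_len(n_dst) - 0.5) * scale + 0.5 - 1  # zero-based src coord
  M <- matrix(0, n_dst, n_src)
  for (j in seq_len(n_dst)) {
    base <- floor(pos[j])
    idx <- base + (-1:2)
    w <- cubic_kernel(pos[j] - idx)
    idx <- pmin(pmax(idx, 0), n_src - 1) + 1
    for (m in 1:4) M[j, idx[m]] <- M[j, idx[m]] + w[m]
  }
  M
}

#' Resample a series between pixel sizes with bicubic interpolation
#'
#' The output grid size is `round_even(n * src_pixel_mm / dst_pixel_mm)`
#' per axis (rounded to the nearest even integer so the k-space DC
#' convention is preserved). Uses the separable Keys bicubic kernel.
#'
#' @param series A `cine_series` or array.
#' @param src_pixel_mm Source pixel size (defaults to the series metadata).
#' @param dst_pixel_mm Target pixel size.
#' @return Resampled series with updated `pixel_mm`.
#' @export
resample_bicubic <- function(series, src_pixel_mm = NULL, dst_pixel_mm) {
  is_cs <- inherits(series, "cine_series")
  x <- if (is_cs) series$frames else series
  if (is.null(src_pixel_mm)) {
    if (!is_cs) stop("src_pixel_mm required for bare arrays", call. = FALSE)
    src_pixel_mm <- series$pixel_mm
  }
  if (src_pixel_mm <= 0 || dst_pixel_mm <= 0)
    stop("pixel sizes must be positive", call. = FALSE)
  d <- dim(x)
  if (src_pixel_mm == dst_pixel_mm) return(series)
  round_even <- function(n) max(2L, 2L * as.integer(round(n / 2)))
  h2 <- round_even(d[1] * src_pixel_mm / dst_pixel_mm)
  w2 <- round_even(d[2] * src_pixel_mm / dst_pixel_mm)
  Mr <- cubic_matrix(d[1], h2)
  Mc <- cubic_matrix(d[2], w2)
  y <- array(0, dim = c(h2, w2, d[3]))
  for (t in seq_len(d[3])) y[, , t] <- Mr %*% x[, , t] %*% t(Mc)
  if (is_cs) {
    out <- with_frames(series, y)
    out$pixel_mm <- dst_pixel_mm
    out
  } else y
}
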