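gaussian_window <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  g / sum(g)
}

# Banded "valid" filtering matrix: (n - size + 1) x n.
filt_matrix <- function(n, g) {
  size <- length(g)
  m <- n - size + 1L
  if (m < 1L) stop("image smaller than the SSIM window", call. = FALSE)
  M <- matrix(0, m, n)
  for (i in seq_len(m)) M[i, i:(i + size - 1L)] <- g
  M
}

#' Structural similarity index of two frames
#'
#' The standard single-scale SSIM: 11x11 Gaussian window (sigma 1.5),
#' K1 = 0.01, K2 = 0.03, population (weighted) variances, and the map
#' averaged over the valid (fully overlapped) region.
#'
#' @param x,y Equal-size numeric matrices.
#' @param data_range Dynamic range L (1 for unit-normalized images).
#' @return SSIM value in \[-1, 1\].
#' @export
ssim <- function(x, y, data_range = 1) {
  stopifnot(all(dim(x) == dim(y)))
  g <- gaussian_window()
  Kr <- filt_matrix(nrow(x), g)
  Kc <- filt_matrix(ncol(x), g)
  filt <- function(z) Kr %*% z %*% t(Kc)
  mu1 <- filt(x); mu2 <- filt(y)
  s11 <- filt(x * x) - mu1^2
  s22 <- filt(y * y) - mu2^2
  s12 <- filt(x * y) - mu1 * mu2
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Image-quality metrics over a frame range
#'
#' MAE, MSE, PSNR and SSIM between a reconstructed and a ground-truth
#' series, computed over an inclusive 1-based frame range (default frames
#' 5-25, the window after recurrent image quality has stabilized).
#' PSNR is `10 log10(L^2 / MSE)` with unit dynamic range and reported as
#' `Inf` when MSE is 0. SSIM is computed per frame and averaged.
#'
#' @param pred,gt `cine_series` (or arrays) of identical shape.
#' @param frame_range `c(first, last)`, inclusive, within the series.
#' @param data_range Intensity dynamic range (default 1).
#' @return A `metric_report`: list with `mae`, `mse`, `psnr`, `ssim`,
#'   `frame_range`, and `per_frame` (data.frame of per-frame values).
#' @export
metrics <- function(pred, gt, frame_range = c(5L, 25L), data_range = 1) {
  p <- if (inherits(pred, "cine_series")) pred$frames else pred
  g <- if (inherits(gt, "cine_series")) gt$frames else gt
  stopifnot(all(dim(p) == dim(g)))
  Tn <- dim(p)[3]
  fr <- as.integer(frame_range)
  if (fr[1] < 1L || fr[2] > Tn || fr[1] > fr[2])
    stop(sprintf("frame range [%d, %d] outside series of %d frames",
                 fr[1], fr[2], Tn), call. = FALSE)
  idx <- fr[1]:fr[2]
  pf <- data.frame(frame = idx,
                   mae = vapply(idx, function(t) mean(abs(p[, , t] - g[, , t])), numeric(1)),
                   mse = vapply(idx, function(t) mean((p[, , t] - g[, , t])^2), numeric(1)),
                   ssim = vapply(idx, function(t) ssim(p[, , t], g[, , t], data_range), numeric(1)))
  mse <- mean(pf$mse)
  structure(list(mae = mean(pf$mae), mse = mse,
                 psnr = if (mse == 0) Inf else 10 * log10(data_range^2 / mse),
                 ssim = mean(pf$ssim), frame_range = fr, per_frame = pf),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> frames %d-%d: MAE %.4f  MSE %.5f  PSNR %.2f dB  SSIM %.4f\n",
              x$frame_range[1], x$frame_range[2], x$mae, x$mse, x$psnr, x$ssim))
  invisible(x)
}

# Frame range for evaluation clamped to a series length.
eval_range <- function(Tn, lo = 5L, hi = 25L) c(min(lo, Tn), min(hi, Tn))

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired test; zero differences are dropped. The exact null
#' distribution is used for n <= 25 (no ties), the normal approximation
#' with continuity correction beyond.
#'
#' @param a,b Paired numeric vectors of equal length (>= 5 after zero
#'   removal).
#' @return List with `statistic` (V), `p_value`, `n` (pairs used).
#' @export
paired_wilcoxon <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero (degenerate input)", call. = FALSE)
  exact <- n <= 25L && !any(duplicated(abs(d)))
  ht <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, n = n)
}

#' Shapiro-Wilk normality check
#'
#' @param x Numeric vector, 3 <= n <= 5000, non-constant.
#' @return List with `W` and `p_value`.
#' @export
normality_check <- function(x) {
  if (length(unique(x)) < 2L) stop("constant input (degenerate)", call. = FALSE)
  ht <- stats::shapiro.test(x)
  list(W = unname(ht$statistic), p_value = ht$p.value)
}

#' Simulate a continuous radial spoke stream from a ground-truth cine
#'
#' Emulates a continuous acquisition of a moving object: global spoke `j`
#' (zero-based) follows the tiny golden-angle schedule and samples the
#' ground-truth frame active at that time (`floor(j / spokes_per_frame)`,
#' clamped to the series).
#'
#' @param gt Ground-truth `cine_series`.
#' @param spokes_per_frame Spokes acquired per frame interval.
#' @param params [sequence_params()]; defaults to 2x readout oversampling.
#' @param n_spokes Total spokes to simulate (default: all frames).
#' @return A `spoke_stream`: complex sample matrix, params, frame size.
#' @export
simulate_spoke_stream <- function(gt, spokes_per_frame, params = NULL,
                                  n_spokes = NULL) {
  stopifnot(inherits(gt, "cine_series"))
  d <- dim(gt$frames)
  S <- as.integer(spokes_per_frame)
  if (is.null(params))
    params <- sequence_params(n_samples = 2L * d[1], spokes_per_frame = S)
  if (is.null(n_spokes)) n_spokes <- S * d[3]
  samples <- matrix(0 + 0i, params$n_samples, n_spokes)
  for (j in seq_len(n_spokes)) {
    frame <- min((j - 1L) %/% S + 1L, d[3])
    traj <- make_trajectory(params, 1L, start_index = j - 1L)
    samples[, j] <- nudft_forward(gt$frames[, , frame], traj)$samples
  }
  structure(list(samples = samples, params = params, H = d[1], W = d[2],
                 spokes_per_frame = S),
            class = "spoke_stream")
}

# Adjoint-grid a contiguous range of stream spokes into one frame.
grid_spoke_range <- function(stream, first, last) {
  params <- stream$params
  traj <- make_trajectory(params, last - first + 1L, start_index = first - 1L)
  ks <- structure(list(samples = stream$samples[, first:last, drop = FALSE],
                       traj = traj, H = stream$H, W = stream$W),
                  class = "kspace_data")
  Mod(nudft_adjoint(ks))
}

#' Spokes needed before the first sliding-window frame
#'
#' A window of `width` spokes centered on the center spoke of the first
#' `step`-spoke frame extends `(width - step) / 2` spokes beyond that
#' frame's data.
#'
#' @param width Window width in spokes.
#' @param step Frame step in spokes.
#' @return Integer spoke count.
#' @export
sliding_window_leadin <- function(width = 99L, step = 17L) {
  as.integer((width - step) / 2)
}

#' Sliding-window reconstruction of a radial spoke stream
#'
#' Frame k is reconstructed by adjoint gridding of a `width`-spoke window
#' centered on the center spoke of the k-th `step`-spoke frame (the same
#' center k-space line as the gridded reconstruction). A frame is emitted
#' only when the window's trailing edge is available; the leading edge is
#' clipped at the start of the stream. With `width == step` this reduces
#' exactly to the per-frame gridded reconstruction.
#'
#' @param stream A `spoke_stream`.
#' @param width Window width in spokes (default 99).
#' @param step Frame step in spokes (default 17).
#' @param normalize Normalize the emitted series to \[0, 1\].
#' @return A `cine_series` of the emitted frames.
#' @export
sliding_window_recon <- function(stream, width = 99L, step = 17L,
                                 normalize = TRUE) {
  stopifnot(inherits(stream, "spoke_stream"))
  width <- as.integer(width); step <- as.integer(step)
  if (width < step) stop("width must be >= step", call. = FALSE)
  N <- ncol(stream$samples)
  half <- (width - 1) / 2
  frames <- list()
  k <- 1L
  repeat {
    center <- (k - 1L) * step + (step + 1L) / 2    # 1-based center spoke
    first <- max(1L, as.integer(ceiling(center - half)))
    last <- as.integer(floor(center + half))
    if (last > N) break
    frames[[k]] <- grid_spoke_range(stream, first, last)
    k <- k + 1L
  }
  if (length(frames) == 0L)
    stop("stream shorter than one window", call. = FALSE)
  arr <- array(unlist(frames), dim = c(stream$H, stream$W, length(frames)))
  out <- cine_series(arr)
  if (normalize) out <- normalize_series(out)
  out
}

#' Per-frame gridded reconstruction of a spoke stream
#'
#' @param stream A `spoke_stream`.
#' @param step Spokes per frame (defaults to the stream's).
#' @param normalize Normalize output series to \[0, 1\] (`"series"`),
#'   per-frame (`"frame"`, the causal streaming variant), or not at all
#'   (`"none"`).
#' @return A `cine_series`.
#' @export
gridded_recon <- function(stream, step = stream$spokes_per_frame,
                          normalize = c("series", "frame", "none")) {
  normalize <- match.arg(normalize)
  N <- ncol(stream$samples)
  nf <- N %/% step
  if (nf < 1L) stop("stream shorter than one frame", call. = FALSE)
  arr <- array(0, dim = c(stream$H, stream$W, nf))
  for (k in seq_len(nf)) {
    img <- grid_spoke_range(stream, (k - 1L) * step + 1L, k * step)
    if (normalize == "frame") {
      lo <- min(img); hi <- max(img)
      img <- if (hi > lo) (img - lo) / (hi - lo) else img * 0
    }
    arr[, , k] <- img
  }
  out <- cine_series(arr)
  if (normalize == "series") out <- normalize_series(out)
  out
}

#' Device visibility contrast of a reconstruction
#'
#' For every frame, the attenuation depth at the device center (median of
#' a surrounding annulus minus the center intensity) is measured in both
#' the reconstruction and the ground truth; their ratio quantifies how
#' much of the device contrast survives reconstruction. A frame at full
#' device visibility counts as "visible" when the ratio is >= 0.5.
#'
#' @param pred Reconstructed `cine_series`.
#' @param gt Ground-truth `cine_series` containing the device.
#' @param path The [device_path()] used to imprint the device.
#' @param annulus Inner/outer annulus radii in units of the blob SD.
#' @return data.frame with per-frame `amplitude`, `depth_pred`,
#'   `depth_gt`, `ratio`, `visible`.
#' @export
catheter_visibility <- function(pred, gt, path, annulus = c(2.5, 4)) {
  p <- pred$frames; g <- gt$frames
  d <- dim(p)
  stopifnot(all(d == dim(g)), nrow(path$centers) == d[3])
  rin <- annulus[1] * path$sd_px; rout <- annulus[2] * path$sd_px
  rows <- matrix(seq_len(d[1]), d[1], d[2])
  cols <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  depth <- function(img, ctr) {
    r <- round(ctr[1]); c <- round(ctr[2])
    if (r < 1 || r > d[1] || c < 1 || c > d[2])
      stop("device path outside the image", call. = FALSE)
    rad <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
    ring <- img[rad >= rin & rad <= rout]
    stats::median(ring) - img[r, c]
  }
  out <- data.frame(frame = seq_len(d[3]), amplitude = path$amplitude,
                    depth_pred = NA_real_, depth_gt = NA_real_)
  for (t in seq_len(d[3])) {
    out$depth_pred[t] <- depth(p[, , t], path$centers[t, ])
    out$depth_gt[t] <- depth(g[, , t], path$centers[t, ])
  }
  out$ratio <- ifelse(abs(out$depth_gt) > 1e-6,
                      pmax(0, out$depth_pred) / out$depth_gt, NA_real_)
  out$visible <- !is.na(out$ratio) & out$ratio >= 0.5
  out
}
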