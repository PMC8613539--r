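#' @section Non-uniform Fourier operators:
#' The forward model evaluates the type-2 non-uniform discrete Fourier
#' transform exactly (no gridding kernel): for sample location k and
#' pixel-centered coordinates p,
#' `s(k) = sum_p I(p) exp(-2i pi k . p)`.
#' The adjoint applies the conjugate transpose with optional density
#' weights. Exactness (machine precision) keeps the operator pair testable
#' against brute-force summation and makes the adjoint identity
#' `<F x, y> = <x, F* y>` hold to rounding error.
#' @name gridding
#' @keywords internal
NULL

# Complex phase matrices for the separable NUDFT:
# A[s, x] = exp(-2i pi kx_s * px), B[s, y] = exp(-2i pi ky_s * py).
nudft_phase <- function(traj, H, W) {
  px <- (0:(H - 1L)) - H / 2
  py <- (0:(W - 1L)) - W / 2
  kx <- as.vector(traj$kx)
  ky <- as.vector(traj$ky)
  list(A = exp(-2i * pi * outer(kx, px)),
       B = exp(-2i * pi * outer(ky, py)))
}

#' Forward non-uniform Fourier transform onto a radial trajectory
#'
#' @param image A real or complex `H x W` matrix (H = W, even).
#' @param traj A `radial_trajectory` (see [make_trajectory()]).
#' @return A `kspace_data` object: complex `n_samples x n_spokes` matrix of
#'   k-space samples plus a reference to the trajectory.
#' @export
nudft_forward <- function(image, traj) {
  stopifnot(inherits(traj, "radial_trajectory"))
  d <- dim(image)
  if (is.null(d) || length(d) != 2L || d[1] != d[2] || d[1] %% 2L != 0L)
    stop("image must be a square matrix with even side", call. = FALSE)
  ph <- nudft_phase(traj, d[1], d[2])
  C <- image %*% t(ph$B)                 # H x S
  val <- colSums(t(ph$A) * C)            # S
  structure(list(samples = matrix(val, traj$n_samples, traj$n_spokes),
                 traj = traj, H = d[1], W = d[2]),
            class = "kspace_data")
}

#' Adjoint non-uniform Fourier transform (regridding reconstruction)
#'
#' Maps weighted k-space samples back to the image grid:
#' `I(p) = sum_s dcf_s * d_s * exp(+2i pi k_s . p)`. With the analytic ramp
#' density compensation this is the standard regridded reconstruction; with
#' `dcf = 1` it is the exact adjoint of [nudft_forward()].
#'
#' @param kspace A `kspace_data` object.
#' @param dcf Per-sample weights (matrix or vector matching the samples), or
#'   `NULL` to use the trajectory's ramp weights, or `1` for the plain
#'   adjoint.
#' @param H,W Output grid size (defaults to the size recorded at forward
#'   time).
#' @return Complex `H x W` image matrix.
#' @export
nudft_adjoint <- function(kspace, dcf = NULL, H = kspace$H, W = kspace$W) {
  stopifnot(inherits(kspace, "kspace_data"))
  traj <- kspace$traj
  if (is.null(dcf)) dcf <- traj$dcf
  wd <- as.vector(kspace$samples) * as.vector(dcf * array(1, dim = dim(kspace$samples)))
  ph <- nudft_phase(traj, H, W)
  Conj(t(ph$A)) %*% (wd * Conj(ph$B))    # (H x S) %*% (S x W)
}

#' Retrospectively degrade a cine series by radial undersampling
#'
#' The pair-synthesis pipeline: each ground-truth frame is Fourier
#' transformed onto the `spokes_per_frame` tiny golden-angle spokes falling
#' in its acquisition window (spokes accumulate continuously across frames
#' by default, as in an interactive acquisition), regridded back with ramp
#' density compensation, and the magnitude taken. The aliased series is
#' then renormalized to \[0, 1\].
#'
#' @param gt Ground-truth `cine_series`, intensities in \[0, 1\].
#' @param spokes_per_frame Spokes per simulated frame.
#' @param params A [sequence_params()]; `n_samples` sets the readout length.
#' @param start_spoke Global index of the first spoke.
#' @param continuous If `FALSE`, every frame restarts at `start_spoke`
#'   instead of continuing the golden-angle schedule.
#' @param normalize `"series"` (default) renormalizes the aliased series by
#'   its own global min/max; `"frame"` normalizes each frame independently
#'   (the causal variant used for streaming); `"none"` skips renormalization.
#' @return Aliased `cine_series`, same shape as `gt`.
#' @export
degrade_series <- function(gt, spokes_per_frame, params = NULL,
                           start_spoke = 0L, continuous = TRUE,
                           normalize = c("series", "frame", "none")) {
  stopifnot(inherits(gt, "cine_series"))
  normalize <- match.arg(normalize)
  d <- dim(gt$frames)
  if (d[3] < 1L) stop("empty series", call. = FALSE)
  spokes_per_frame <- as.integer(spokes_per_frame)
  if (spokes_per_frame < 1L) stop("spokes_per_frame must be >= 1", call. = FALSE)
  if (is.null(params))
    params <- sequence_params(n_samples = 2L * d[1],
                              spokes_per_frame = spokes_per_frame,
                              pixel_mm = gt$pixel_mm, tr_ms = gt$tr_ms)
  out <- array(0, dim = d)
  for (t in seq_len(d[3])) {
    s0 <- if (continuous) start_spoke + (t - 1L) * spokes_per_frame else start_spoke
    traj <- make_trajectory(params, spokes_per_frame, start_index = s0)
    ks <- nudft_forward(gt$frames[, , t], traj)
    img <- Mod(nudft_adjoint(ks))
    if (normalize == "frame") {
      lo <- min(img); hi <- max(img)
      img <- if (hi > lo) (img - lo) / (hi - lo) else img * 0
    }
    out[, , t] <- img
  }
  res <- with_frames(gt, out)
  if (normalize == "series") res <- normalize_series(res)
  res
}
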