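#' Sequence parameters for a radial real-time acquisition
#'
#' Bundles the timing and readout geometry of the simulated bSSFP radial
#' sequence: repetition time, samples per readout and spokes per frame,
#' plus field-of-view metadata used by resampling utilities.
#'
#' @param tr_ms Repetition time in milliseconds (one spoke per TR).
#' @param n_samples Readout samples per spoke; must be even so the DC sample
#'   falls on an FFT grid point.
#' @param spokes_per_frame Spokes grouped into one reconstructed frame.
#' @param fov_mm Field of view in mm (metadata only).
#' @param pixel_mm Pixel size in mm (metadata only).
#' @return An object of class `sequence_params`.
#' @examples
#' p <- sequence_params(spokes_per_frame = 17)
#' frame_duration_ms(p$spokes_per_frame, p$tr_ms)
#' @export
sequence_params <- function(tr_ms = 3.2, n_samples = 192L, spokes_per_frame = 17L,
                            fov_mm = 320, pixel_mm = 1.67) {
  if (!is.numeric(tr_ms) || length(tr_ms) != 1L || tr_ms <= 0)
    stop("tr_ms must be a single positive number", call. = FALSE)
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2L || n_samples %% 2L != 0L)
    stop("n_samples must be an even integer >= 2", call. = FALSE)
  spokes_per_frame <- as.integer(spokes_per_frame)
  if (is.na(spokes_per_frame) || spokes_per_frame < 1L)
    stop("spokes_per_frame must be a positive integer", call. = FALSE)
  structure(list(tr_ms = tr_ms, n_samples = n_samples,
                 spokes_per_frame = spokes_per_frame,
                 fov_mm = fov_mm, pixel_mm = pixel_mm),
            class = "sequence_params")
}

#' Tiny golden angle of a given order
#'
#' The generalized golden-angle increment 180 / (phi + order - 1) degrees,
#' with phi the golden ratio. Order 1 is the classic golden angle
#' (~111.25 deg); order 7 is the "tiny" golden angle (~23.63 deg) used for
#' real-time imaging, which keeps k-space coverage near-uniform for any
#' window of consecutive spokes while limiting eddy-current-inducing
#' gradient jumps.
#'
#' @param order Positive integer order of the generalized golden angle.
#' @return Angle increment in degrees.
#' @examples
#' tiny_golden_angle(7) # ~23.63
#' @export
tiny_golden_angle <- function(order = 7L) {
  order <- as.integer(order)
  if (is.na(order) || order < 1L)
    stop("order must be a positive integer", call. = FALSE)
  phi <- (1 + sqrt(5)) / 2
  180 / (phi + order - 1)
}

#' Spoke angles of a continuous tiny golden-angle acquisition
#'
#' Angle of spoke `i` (zero-based global index `start_index + i`) is
#' `index * increment mod 360`. The acquisition is continuous: restarting
#' the sequence at a later `start_index` reproduces the same angles as one
#' long run.
#'
#' @param n_spokes Number of spokes to return (may be 0).
#' @param start_index Global index of the first spoke in the continuous
#'   acquisition.
#' @param order Tiny golden-angle order (default 7).
#' @return Numeric vector of angles in degrees, in \[0, 360).
#' @export
spoke_angles <- function(n_spokes, start_index = 0L, order = 7L) {
  n_spokes <- as.integer(n_spokes)
  if (is.na(n_spokes) || n_spokes < 0L)
    stop("n_spokes must be a non-negative integer", call. = FALSE)
  if (n_spokes == 0L) return(numeric(0))
  idx <- as.numeric(start_index) + seq_len(n_spokes) - 1
  (idx * tiny_golden_angle(order)) %% 360
}

#' Build a radial trajectory
#'
#' Full-diameter spokes through the k-space origin. Sample `m`
#' (zero-based) of every spoke sits at signed radius
#' `(m - n_samples/2) / n_samples` cycles/pixel, so radii span
#' \[-0.5, 0.5 - 1/n\] and the DC sample aligns with an FFT grid point.
#' Coordinates are `(kx, ky) = r * (cos a, sin a)`.
#'
#' @param params A [sequence_params()] object.
#' @param n_spokes Number of spokes.
#' @param start_index Global index of the first spoke (angles continue the
#'   acquisition, see [spoke_angles()]).
#' @param order Tiny golden-angle order.
#' @return An object of class `radial_trajectory` with fields `angles_deg`,
#'   `kx`, `ky` (each `n_samples x n_spokes`), `radius` (per-sample signed
#'   radius), `dcf` (density weights, see [density_compensation()]),
#'   `n_samples`, `n_spokes`, `start_index`.
#' @export
make_trajectory <- function(params, n_spokes, start_index = 0L, order = 7L) {
  stopifnot(inherits(params, "sequence_params"))
  n_spokes <- as.integer(n_spokes)
  if (is.na(n_spokes) || n_spokes < 1L)
    stop("n_spokes must be a positive integer", call. = FALSE)
  n <- params$n_samples
  angles <- spoke_angles(n_spokes, start_index, order)
  r <- ((0:(n - 1L)) - n / 2) / n
  a <- angles * pi / 180
  kx <- outer(r, cos(a))
  ky <- outer(r, sin(a))
  traj <- structure(list(angles_deg = angles, kx = kx, ky = ky, radius = r,
                         n_samples = n, n_spokes = n_spokes,
                         start_index = as.integer(start_index),
                         dcf = NULL),
                    class = "radial_trajectory")
  traj$dcf <- density_compensation(traj)
  traj
}

#' Analytic ramp density compensation
#'
#' Radial sampling oversamples the k-space center; an adjoint gridding
#' without correction is dominated by low frequencies. The weights are the
#' analytic area element of the radial pattern: `|k| * dk * pi / n_spokes`
#' per sample, with the center (DC) sample assigned `dk/8` in place of
#' `|k|` (the half-width of its annulus collapses to a small disc shared by
#' all spokes). With these weights the adjoint approximates the continuous
#' inverse Fourier integral, so a fully sampled acquisition reconstructs
#' the image without further scaling.
#'
#' @param traj A `radial_trajectory`.
#' @return Matrix of nonnegative weights, `n_samples x n_spokes`.
#' @export
density_compensation <- function(traj) {
  stopifnot(inherits(traj, "radial_trajectory"))
  if (traj$n_spokes < 1L) stop("trajectory has no spokes", call. = FALSE)
  dk <- 1 / traj$n_samples
  ramp <- abs(traj$radius)
  ramp[traj$radius == 0] <- dk / 8
  w <- ramp * dk * pi / traj$n_spokes
  matrix(w, nrow = traj$n_samples, ncol = traj$n_spokes)
}

#' Radial acceleration factor
#'
#' Ratio of the Nyquist spoke count for a radial acquisition
#' (`pi/2 * n_samples`) to the spokes actually acquired per frame,
#' reported to one decimal.
#'
#' @param spokes_per_frame Spokes acquired per frame.
#' @param n_samples Readout samples per spoke.
#' @return Acceleration factor R, rounded to 1 decimal.
#' @examples
#' acceleration_factor(13, 192) # 23.2
#' acceleration_factor(33, 192) # 9.1
#' @export
acceleration_factor <- function(spokes_per_frame, n_samples = 192L) {
  if (!is.numeric(spokes_per_frame) || spokes_per_frame <= 0)
    stop("spokes_per_frame must be positive", call. = FALSE)
  if (!is.numeric(n_samples) || n_samples <= 0)
    stop("n_samples must be positive", call. = FALSE)
  round((pi / 2 * n_samples) / spokes_per_frame, 1)
}

#' Frame duration in milliseconds
#'
#' One spoke is acquired per TR, so a frame of `spokes_per_frame` spokes
#' takes `spokes_per_frame * tr_ms`, rounded to the nearest millisecond.
#'
#' @param spokes_per_frame Spokes per frame.
#' @param tr_ms Repetition time in ms.
#' @return Integer milliseconds.
#' @examples
#' frame_duration_ms(17, 3.2) # 54
#' @export
frame_duration_ms <- function(spokes_per_frame, tr_ms = 3.2) {
  if (spokes_per_frame <= 0 || tr_ms <= 0)
    stop("inputs must be positive", call. = FALSE)
  as.integer(round(spokes_per_frame * tr_ms))
}

#' Acceleration descriptor for one undersampling setting
#'
#' @param spokes_per_frame Spokes per frame.
#' @param params A [sequence_params()] (supplies `n_samples` and `tr_ms`).
#' @return List with `spokes_per_frame`, `r_factor`, `frame_ms`.
#' @export
acceleration_spec <- function(spokes_per_frame, params = sequence_params()) {
  list(spokes_per_frame = as.integer(spokes_per_frame),
       r_factor = acceleration_factor(spokes_per_frame, params$n_samples),
       frame_ms = frame_duration_ms(spokes_per_frame, params$tr_ms))
}

#' Export trajectory angles as CSV
#'
#' @param traj A `radial_trajectory`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "radial_trajectory"))
  df <- data.frame(spoke = traj$start_index + seq_len(traj$n_spokes) - 1L,
                   angle_deg = traj$angles_deg)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
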