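#' Configuration of a synthetic beating-heart cine phantom
#'
#' The generator emulates breath-hold bSSFP magnitude cines: bright blood
#' pools, a contracting myocardial ring, and static thoracic background,
#' arranged according to one of seven view-geometry classes analogous to
#' the standard cardiac imaging planes (short axis SAX, 4-chamber FCH,
#' left/right ventricular long axis LVLA/RVLA, left/right ventricular
#' outflow tract LVOT/RVOT, pulmonary artery PA).
#'
#' @param view_class One of `phantom_views()`.
#' @param n_frames Frames in the series (>= 8; default 32).
#' @param n_cycles Cardiac cycles spanned by the series (default 2), so the
#'   series is periodic with period `n_frames / n_cycles` frames.
#' @param matrix Square matrix size before any crop (default 160).
#' @param contraction_fraction Peak fractional radius reduction of the
#'   contracting structures, in (0, 0.5).
#' @param heart_rate_bpm Nominal heart rate (metadata; the temporal axis is
#'   phase-based so periodicity is exact).
#' @param noise_sd SD of the static spatial texture added to tissue
#'   (deterministic given `seed`; temporal noise is deliberately absent so
#'   the cycle is exactly periodic).
#' @param jitter Fractional random jitter of structure centers/axes across
#'   subjects (anatomy variability), drawn once per series from `seed`.
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   series.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(view_class = "SAX", n_frames = 32L, n_cycles = 2L,
                           matrix = 160L, contraction_fraction = 0.25,
                           heart_rate_bpm = 70, noise_sd = 0.02,
                           jitter = 0.08, seed = 1L) {
  view_class <- match.arg(view_class, phantom_views())
  n_frames <- as.integer(n_frames)
  if (n_frames < 8L) stop("n_frames must be >= 8", call. = FALSE)
  if (contraction_fraction <= 0 || contraction_fraction >= 0.5)
    stop("contraction_fraction must be in (0, 0.5)", call. = FALSE)
  structure(list(view_class = view_class, n_frames = n_frames,
                 n_cycles = as.integer(n_cycles), matrix = as.integer(matrix),
                 contraction_fraction = contraction_fraction,
                 heart_rate_bpm = heart_rate_bpm, noise_sd = noise_sd,
                 jitter = jitter, seed = as.integer(seed)),
            class = "phantom_config")
}

#' The seven phantom view-geometry classes
#' @return Character vector of class names.
#' @export
phantom_views <- function() c("SAX", "FCH", "LVLA", "RVLA", "LVOT", "RVOT", "PA")

# Additive soft-edged ellipse on normalized [-1,1]^2 coordinates.
# cx, cy: center; ax, ay: semi-axes; th: rotation (rad); val: intensity.
soft_ellipse <- function(X, Y, cx, cy, ax, ay, th, val, edge = 0.05) {
  ct <- cos(th); st <- sin(th)
  u <- ((X - cx) * ct + (Y - cy) * st) / ax
  v <- (-(X - cx) * st + (Y - cy) * ct) / ay
  r <- sqrt(u^2 + v^2)
  val * (1 / (1 + exp((r - 1) / edge)))
}

# Geometry preset for a view class: list of structures, each
# list(cx, cy, ax, ay, th, val, beats) where beats = TRUE structures
# contract with the cardiac phase. Values are layered additively and
# clipped; blood pools bright (~0.9), myocardium mid (~0.45),
# background low.
view_preset <- function(view_class) {
  switch(view_class,
    SAX = list(  # myocardial ring with bright LV pool + RV crescent
      list(0.05, 0.00, 0.42, 0.42, 0.0, 0.45, TRUE),     # myocardium disc
      list(0.05, 0.00, 0.26, 0.26, 0.0, 0.45, TRUE),     # pool overwrite
      list(-0.38, 0.12, 0.28, 0.16, 0.5, 0.75, TRUE)),   # RV crescent
    FCH = list(  # four elongated chambers
      list(-0.18, -0.22, 0.34, 0.20, 0.25, 0.85, TRUE),  # LV
      list(-0.18, 0.24, 0.30, 0.17, -0.20, 0.80, TRUE),  # RV
      list(0.30, -0.20, 0.20, 0.15, 0.15, 0.70, FALSE),  # LA
      list(0.30, 0.22, 0.18, 0.14, -0.10, 0.70, FALSE)), # RA
    LVLA = list(  # two-chamber long axis
      list(-0.10, -0.05, 0.45, 0.22, 0.45, 0.85, TRUE),  # LV
      list(0.35, 0.20, 0.20, 0.16, 0.30, 0.70, FALSE)),  # LA
    RVLA = list(
      list(-0.05, 0.10, 0.42, 0.24, -0.50, 0.80, TRUE),  # RV
      list(0.32, -0.22, 0.19, 0.15, -0.25, 0.70, FALSE)),# RA
    LVOT = list(  # LV plus aortic outflow channel
      list(-0.15, -0.10, 0.36, 0.24, 0.35, 0.85, TRUE),
      list(0.28, 0.18, 0.40, 0.10, 0.80, 0.75, FALSE)),  # aorta
    RVOT = list(
      list(-0.12, 0.12, 0.34, 0.22, -0.40, 0.80, TRUE),
      list(0.25, -0.15, 0.42, 0.11, -0.85, 0.75, FALSE)),# pulm. outflow
    PA = list(  # great-vessel view: bifurcating vessel, weak pulsation
      list(0.00, 0.00, 0.50, 0.13, 0.0, 0.80, TRUE),     # main PA
      list(0.38, 0.28, 0.26, 0.10, 0.9, 0.75, FALSE),    # right branch
      list(0.38, -0.28, 0.26, 0.10, -0.9, 0.75, FALSE))  # left branch
  )
}

#' Generate a synthetic beating-heart cine series
#'
#' Deterministic, periodic phantom: static thoracic background (body
#' ellipse, lung fields, spine), plus the view-specific chamber layout.
#' Structures flagged as beating scale their semi-axes by
#' `1 - cf * s(t)` with `s(t) = (1 - cos(2 pi phase)) / 2`, emulating
#' systolic contraction. A static, seeded spatial texture is added inside
#' the body. Output is normalized to \[0, 1\].
#'
#' @param config A [phantom_config()].
#' @return A `cine_series` of size `matrix x matrix x n_frames`.
#' @export
generate_cine <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$matrix
  Tn <- config$n_frames
  g <- seq(-1, 1, length.out = n)
  X <- outer(g, rep(1, n)); Y <- t(X)
  rng <- local({ set.seed(config$seed); list(
    jit = stats::rnorm(40, 0, config$jitter),
    tex = matrix(stats::rnorm(n * n, 0, 1), n, n)) })
  jit <- rng$jit
  # static background
  bg <- soft_ellipse(X, Y, 0, 0, 0.95, 0.88, 0, 0.30, edge = 0.03) +
    soft_ellipse(X, Y, -0.55, -0.45, 0.30, 0.35, 0.3, -0.18, edge = 0.06) +
    soft_ellipse(X, Y, -0.55, 0.50, 0.28, 0.33, -0.3, -0.18, edge = 0.06) +
    soft_ellipse(X, Y, 0.72, 0.00, 0.12, 0.12, 0, 0.25, edge = 0.04)
  body_mask <- soft_ellipse(X, Y, 0, 0, 0.95, 0.88, 0, 1, edge = 0.03)
  tex <- config$noise_sd * rng$tex * body_mask
  structs <- view_preset(config$view_class)
  frames <- array(0, dim = c(n, n, Tn))
  for (t in seq_len(Tn)) {
    phase <- config$n_cycles * (t - 1) / Tn
    s <- (1 - cos(2 * pi * phase)) / 2
    img <- bg
    for (i in seq_along(structs)) {
      st <- structs[[i]]
      scale <- if (isTRUE(st[[7]])) 1 - config$contraction_fraction * s else 1
      j <- 4 * (i - 1)
      img <- img + soft_ellipse(X, Y,
        st[[1]] * (1 + jit[j + 1]), st[[2]] * (1 + jit[j + 2]),
        st[[3]] * scale * (1 + jit[j + 3]), st[[4]] * scale * (1 + jit[j + 4]),
        st[[5]], st[[6]])
    }
    frames[, , t] <- img + tex
  }
  frames <- pmax(frames, 0)
  normalize_series(cine_series(frames, view = config$view_class,
                               subject = sprintf("%s-%04d", config$view_class,
                                                 config$seed)))
}

#' Interventional-device path through a cine series
#'
#' Describes a balloon catheter tip (one Gaussian) or a guidewire (five
#' Gaussians strung along a moving polyline) moving through the imaging
#' plane with a per-frame visibility amplitude ("vanishing": the device
#' moves in and out of plane).
#'
#' @param centers `T x 2` matrix of per-frame device (row, col) centers in
#'   pixels (for a guidewire, the leading blob; trailing blobs follow along
#'   the motion direction at `spacing_px`).
#' @param amplitude Per-frame visibility in \[0, 1\] (length T).
#' @param n_blobs 1 for a balloon, 5 for a guidewire.
#' @param sd_px Gaussian SD per blob in pixels.
#' @param spacing_px Blob spacing along the wire (guidewire only).
#' @param max_attenuation Peak fractional signal decrease (default 0.8).
#' @param direction Unit 2-vector along which trailing blobs are laid out;
#'   default follows the path's motion.
#' @return A `device_path` object.
#' @export
device_path <- function(centers, amplitude, n_blobs = 1L, sd_px = 4,
                        spacing_px = 6, max_attenuation = 0.8,
                        direction = NULL) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 2L) stop("centers must be T x 2", call. = FALSE)
  if (length(amplitude) != nrow(centers))
    stop("amplitude length must match path length", call. = FALSE)
  if (any(amplitude < 0 | amplitude > 1))
    stop("amplitude must be in [0, 1]", call. = FALSE)
  n_blobs <- as.integer(n_blobs)
  if (!n_blobs %in% c(1L, 5L))
    stop("n_blobs must be 1 (balloon) or 5 (guidewire)", call. = FALSE)
  structure(list(centers = centers, amplitude = as.numeric(amplitude),
                 n_blobs = n_blobs, sd_px = sd_px, spacing_px = spacing_px,
                 max_attenuation = max_attenuation, direction = direction),
            class = "device_path")
}

#' Raised-cosine visibility ramp
#'
#' Smooth in/out amplitude profile for a device that enters and leaves the
#' imaging plane: 0 outside \[`on`, `off`\], raised-cosine ramps of
#' `ramp` frames at both ends, 1 in between.
#'
#' @param n_frames Series length.
#' @param on,off First/last frame (1-based) with nonzero visibility.
#' @param ramp Ramp length in frames.
#' @return Numeric vector of length `n_frames` in \[0, 1\].
#' @export
visibility_ramp <- function(n_frames, on, off, ramp = 3L) {
  a <- numeric(n_frames)
  for (t in seq_len(n_frames)) {
    if (t < on || t > off) next
    up <- min(1, (t - on + 1) / (ramp + 1))
    dn <- min(1, (off - t + 1) / (ramp + 1))
    a[t] <- ((1 - cos(pi * up)) / 2) * ((1 - cos(pi * dn)) / 2)
  }
  a
}

# Multiplicative attenuation field of one frame of a device path.
device_field <- function(path, frame, H, W) {
  a <- path$amplitude[frame]
  field <- matrix(1, H, W)
  if (a <= 0) return(field)
  ctr <- path$centers[frame, ]
  if (is.null(path$direction)) {
    prev <- if (frame > 1) path$centers[frame - 1, ] else path$centers[min(frame + 1, nrow(path$centers)), ]
    dirv <- ctr - prev
    if (sqrt(sum(dirv^2)) < 1e-9) dirv <- c(1, 0)
  } else dirv <- path$direction
  dirv <- dirv / sqrt(sum(dirv^2))
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (b in seq_len(path$n_blobs)) {
    c_b <- ctr - (b - 1) * path$spacing_px * dirv
    g <- exp(-(((rows - c_b[1])^2 + (cols - c_b[2])^2) / (2 * path$sd_px^2)))
    field <- field * (1 - a * path$max_attenuation * g)
  }
  field
}

#' Simulate a balloon catheter tip in a cine series
#'
#' Multiplies each frame by `1 - a_t * 0.8 * G_t(x)` where `G_t` is a
#' unit-peak 2D Gaussian centered on the per-frame device position and
#' `a_t` the visibility amplitude: at full visibility the signal at the
#' balloon center drops by 80% of its device-free value.
#'
#' @param series A `cine_series`.
#' @param path A [device_path()] with `n_blobs = 1`.
#' @return Series with the device imprinted; intensities remain in \[0, 1\].
#' @export
apply_balloon <- function(series, path) {
  stopifnot(inherits(series, "cine_series"), inherits(path, "device_path"))
  if (path$n_blobs != 1L) stop("balloon path must have n_blobs = 1", call. = FALSE)
  apply_device(series, path)
}

#' Simulate a guidewire in a cine series
#'
#' Five moving and vanishing 2D Gaussians strung along the wire direction,
#' each applying the same multiplicative attenuation law as the balloon.
#'
#' @inheritParams apply_balloon
#' @export
apply_guidewire <- function(series, path) {
  stopifnot(inherits(series, "cine_series"), inherits(path, "device_path"))
  if (path$n_blobs != 5L) stop("guidewire path must have n_blobs = 5", call. = FALSE)
  apply_device(series, path)
}

apply_device <- function(series, path) {
  d <- dim(series$frames)
  if (nrow(path$centers) != d[3])
    stop("device path length must equal the number of frames", call. = FALSE)
  out <- series$frames
  for (t in seq_len(d[3]))
    out[, , t] <- out[, , t] * device_field(path, t, d[1], d[2])
  with_frames(series, out)
}
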