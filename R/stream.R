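#' Streaming frame-by-frame reconstruction
#'
#' Emulates the low-latency acquisition loop: spokes are consumed
#' incrementally from a [simulate_spoke_stream()] source; as soon as a
#' frame's `spokes_per_frame` spokes are available the frame is adjoint
#' gridded (with per-frame intensity normalization, the causal variant),
#' de-aliased by one stateful network step, clipped to \[0, 1\] and
#' emitted. Incomplete trailing frames are dropped. Per-frame stage
#' timestamps (spoke-complete, gridded, de-aliased) are recorded; they
#' describe this host only and are never quality surfaces.
#'
#' Streaming output is identical to running [reconstruct_series()] on the
#' offline per-frame gridded series with the same initial state.
#'
#' @param stream A `spoke_stream`.
#' @param model A `recurrent_unet` matching the gridded frame size.
#' @param spokes_per_frame Spokes per emitted frame (defaults to the
#'   stream's).
#' @param warmup_frames Gaussian-noise warm-up frames applied to the
#'   recurrent state before the first real frame (0 disables; default 2).
#' @param warmup_seed Seed for the warm-up noise.
#' @return List with `series` (emitted `cine_series`), `events`
#'   (data.frame of per-frame stage timestamps, seconds since stream
#'   start, and the state policy applied), and `state` (final model
#'   state).
#' @export
stream_reconstruct <- function(stream, model,
                               spokes_per_frame = stream$spokes_per_frame,
                               warmup_frames = 2L, warmup_seed = 1L) {
  stopifnot(inherits(stream, "spoke_stream"), inherits(model, "recurrent_unet"))
  S <- as.integer(spokes_per_frame)
  n <- stream$H
  t0 <- proc.time()[["elapsed"]]
  if (warmup_frames > 0L) {
    state <- warmup(model, warmup_frames, seed = warmup_seed, input_size = n)
    policy0 <- "warmup"
  } else {
    state <- reset_state(model, n)
    policy0 <- "reset"
  }
  N <- ncol(stream$samples)
  nf <- N %/% S
  frames <- array(0, dim = c(n, n, nf))
  events <- data.frame(frame = integer(), t_spokes = numeric(),
                       t_gridded = numeric(), t_dealiased = numeric(),
                       policy = character())
  for (k in seq_len(nf)) {
    t_sp <- proc.time()[["elapsed"]] - t0
    img <- grid_spoke_range(stream, (k - 1L) * S + 1L, k * S)
    lo <- min(img); hi <- max(img)
    img <- if (hi > lo) (img - lo) / (hi - lo) else img * 0
    t_gr <- proc.time()[["elapsed"]] - t0
    r <- unet_forward_frame(model, matrix(img, ncol = 1L), state)
    state <- r$state
    frames[, , k] <- matrix(pmin(pmax(r$y, 0), 1), n, n)
    t_de <- proc.time()[["elapsed"]] - t0
    events <- rbind(events, data.frame(
      frame = k, t_spokes = t_sp, t_gridded = t_gr, t_dealiased = t_de,
      policy = if (k == 1L) policy0 else "carry"))
  }
  list(series = cine_series(frames), events = events, state = state)
}
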