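#' Recurrent U-Net specification
#'
#' The de-aliasing network: a residual 2D U-Net with one ConvLSTM block at
#' every scale. Three scales by default with 32/64/128 hidden filters,
#' 2x2 max-pooling on the way down and 2x2 nearest-neighbor upsampling
#' followed by a 3x3 channel-halving convolution on the way up,
#' concatenated skip connections, a linear 1x1 output head, and the input
#' frame added back to the head output (the network learns the artifact
#' residual). With the defaults this instantiates 1,790,465 trainable
#' parameters.
#'
#' @param input_size Square input side length; must be divisible by
#'   `2^(scales-1)`.
#' @param hidden Hidden channel counts per scale (length = scales).
#' @return A `unet_spec`.
#' @export
unet_spec <- function(input_size = 128L, hidden = c(32L, 64L, 128L)) {
  input_size <- as.integer(input_size)
  hidden <- as.integer(hidden)
  if (length(hidden) != 3L) stop("exactly 3 scales are supported", call. = FALSE)
  if (input_size %% 4L != 0L)
    stop("input_size must be divisible by 4 (two pooling stages)", call. = FALSE)
  structure(list(input_size = input_size, hidden = hidden, scales = 3L),
            class = "unet_spec")
}

conv_layer <- function(cin, cout, k = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fan_in <- k * k * cin
  lim <- sqrt(6 / (fan_in + cout))
  list(W = matrix(stats::runif(fan_in * cout, -lim, lim), fan_in, cout),
       b = numeric(cout), cin = cin, cout = cout, k = k)
}

#' Build a recurrent U-Net model
#'
#' Layer graph (E = encoder, B = bottleneck, D = decoder; all ConvLSTM
#' blocks are 3x3):
#' `E1(1->h1) -> pool -> E2(h1->h2) -> pool -> B(h2->h3) -> up+conv(h3->h2)
#'  -> concat E2 -> D2(2h2->h2) -> up+conv(h2->h1) -> concat E1 ->
#'  D1(2h1->h1) -> 1x1 head(h1->1) -> + input`
#'
#' @param spec A [unet_spec()].
#' @param seed Seed for weight initialization.
#' @return A `recurrent_unet` model object.
#' @export
build_model <- function(spec = unet_spec(), seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  h <- spec$hidden
  set.seed(seed)
  model <- structure(list(
    spec = spec, seed = as.integer(seed),
    lstm1 = convlstm_layer(1L, h[1]),
    lstm2 = convlstm_layer(h[1], h[2]),
    lstm3 = convlstm_layer(h[2], h[3]),
    up2   = conv_layer(h[3], h[2]),
    lstm4 = convlstm_layer(2L * h[2], h[2]),
    up1   = conv_layer(h[2], h[1]),
    lstm5 = convlstm_layer(2L * h[1], h[1]),
    head  = conv_layer(h[1], 1L, k = 1L)),
    class = "recurrent_unet")
  model
}

#' @export
print.recurrent_unet <- function(x, ...) {
  cat(sprintf("<recurrent_unet> input %dx%d, hidden %s, %s trainable parameters\n",
              x$spec$input_size, x$spec$input_size,
              paste(x$spec$hidden, collapse = "/"),
              format(parameter_count(x), big.mark = ",")))
  invisible(x)
}

unet_layer_names <- function() c("lstm1", "lstm2", "lstm3", "up2", "lstm4", "up1", "lstm5", "head")

#' Count trainable parameters
#' @param model A `recurrent_unet` (or a single `convlstm_layer`).
#' @return Integer number of trainable scalars.
#' @export
parameter_count <- function(model) {
  if (inherits(model, "convlstm_layer")) return(layer_param_count(model))
  sum(vapply(unet_layer_names(), function(nm)
    length(model[[nm]]$W) + length(model[[nm]]$b), integer(1)))
}

#' Zero (cold-start) recurrent state
#'
#' @param model A `recurrent_unet`.
#' @param input_size Frame side length (defaults to the model's own
#'   `unet_spec` value).
#' @return A `model_state`: per-ConvLSTM-block `h`/`c` matrices, all zero.
#' @export
reset_state <- function(model, input_size = model$spec$input_size) {
  n <- as.integer(input_size)
  h <- model$spec$hidden
  zs <- function(side, ch) list(h = matrix(0, side * side, ch),
                                c = matrix(0, side * side, ch))
  structure(list(s1 = zs(n, h[1]), s2 = zs(n %/% 2L, h[2]),
                 s3 = zs(n %/% 4L, h[3]), s4 = zs(n %/% 2L, h[2]),
                 s5 = zs(n, h[1]), input_size = n),
            class = "model_state")
}

# Forward pass of one frame. x: (n*n) x 1 matrix. Returns y (residual
# output, unclipped), new state, and caches when training.
unet_forward_frame <- function(model, x, state, cache = FALSE) {
  n <- state$input_size
  n2 <- n %/% 2L; n4 <- n %/% 4L
  r1 <- convlstm_step(model$lstm1, x, state$s1, n, n, cache)
  mp1 <- maxpool_forward(r1$h, n, n)
  r2 <- convlstm_step(model$lstm2, mp1$y, state$s2, n2, n2, cache)
  mp2 <- maxpool_forward(r2$h, n2, n2)
  r3 <- convlstm_step(model$lstm3, mp2$y, state$s3, n4, n4, cache)
  us2 <- upsample_forward(r3$h, n4, n4)
  c2 <- conv3_forward(us2, n2, n2, model$up2$W, model$up2$b)
  d2in <- cbind(c2$y, r2$h)
  r4 <- convlstm_step(model$lstm4, d2in, state$s4, n2, n2, cache)
  us1 <- upsample_forward(r4$h, n2, n2)
  c1 <- conv3_forward(us1, n, n, model$up1$W, model$up1$b)
  d1in <- cbind(c1$y, r1$h)
  r5 <- convlstm_step(model$lstm5, d1in, state$s5, n, n, cache)
  y <- r5$h %*% model$head$W
  y <- y + model$head$b + x          # linear 1x1 head + residual input
  new_state <- structure(list(s1 = r1$state, s2 = r2$state, s3 = r3$state,
                              s4 = r4$state, s5 = r5$state, input_size = n),
                         class = "model_state")
  out <- list(y = y, state = new_state)
  if (cache)
    out$cache <- list(x = x, r1 = r1$cache, r2 = r2$cache, r3 = r3$cache,
                      r4 = r4$cache, r5 = r5$cache,
                      mp1_arg = mp1$arg, mp2_arg = mp2$arg,
                      P_up2 = c2$P, P_up1 = c1$P, h5 = r5$h)
  out
}

zero_grads <- function(model) {
  g <- list()
  for (nm in unet_layer_names())
    g[[nm]] <- list(dW = matrix(0, nrow(model[[nm]]$W), ncol(model[[nm]]$W)),
                    db = numeric(length(model[[nm]]$b)))
  g
}

# Backward pass of one frame within a BPTT chunk.
# dy: gradient of the loss w.r.t. the frame output (n*n x 1).
# dstate: recurrent gradients flowing back from frame t+1 (same layout as
# a model_state; zeros at the chunk's last frame).
# grads: accumulator from zero_grads(), modified copy returned.
unet_backward_frame <- function(model, cache, dy, dstate, grads) {
  n <- as.integer(sqrt(nrow(dy)))
  n2 <- n %/% 2L; n4 <- n %/% 4L
  acc <- function(nm, dW, db) {
    grads[[nm]]$dW <<- grads[[nm]]$dW + dW
    grads[[nm]]$db <<- grads[[nm]]$db + db
  }
  # head (1x1 conv) + residual
  dh5 <- dy %*% t(model$head$W) + dstate$s5$h
  acc("head", crossprod(cache$h5, dy), sum(dy))
  dx_res <- dy                                   # residual path to input
  b5 <- convlstm_step_backward(model$lstm5, cache$r5, dh5, dstate$s5$c, n, n)
  acc("lstm5", b5$dW, b5$db)
  h1w <- model$spec$hidden[1]
  dc1y <- b5$dx[, seq_len(h1w), drop = FALSE]
  dh1_skip <- b5$dx[, h1w + seq_len(h1w), drop = FALSE]
  bc1 <- conv3_backward(dc1y, cache$P_up1, model$up1$W, n, n, model$up1$cin)
  acc("up1", bc1$dW, bc1$db)
  dh4 <- upsample_backward(bc1$dx, n2, n2) + dstate$s4$h
  b4 <- convlstm_step_backward(model$lstm4, cache$r4, dh4, dstate$s4$c, n2, n2)
  acc("lstm4", b4$dW, b4$db)
  h2w <- model$spec$hidden[2]
  dc2y <- b4$dx[, seq_len(h2w), drop = FALSE]
  dh2_skip <- b4$dx[, h2w + seq_len(h2w), drop = FALSE]
  bc2 <- conv3_backward(dc2y, cache$P_up2, model$up2$W, n2, n2, model$up2$cin)
  acc("up2", bc2$dW, bc2$db)
  dh3 <- upsample_backward(bc2$dx, n4, n4) + dstate$s3$h
  b3 <- convlstm_step_backward(model$lstm3, cache$r3, dh3, dstate$s3$c, n4, n4)
  acc("lstm3", b3$dW, b3$db)
  dh2 <- maxpool_backward(b3$dx, cache$mp2_arg, n2, n2) + dh2_skip + dstate$s2$h
  b2 <- convlstm_step_backward(model$lstm2, cache$r2, dh2, dstate$s2$c, n2, n2)
  acc("lstm2", b2$dW, b2$db)
  dh1 <- maxpool_backward(b2$dx, cache$mp1_arg, n, n) + dh1_skip + dstate$s1$h
  b1 <- convlstm_step_backward(model$lstm1, cache$r1, dh1, dstate$s1$c, n, n)
  acc("lstm1", b1$dW, b1$db)
  dstate_prev <- list(s1 = list(h = b1$dh_prev, c = b1$dc_prev),
                      s2 = list(h = b2$dh_prev, c = b2$dc_prev),
                      s3 = list(h = b3$dh_prev, c = b3$dc_prev),
                      s4 = list(h = b4$dh_prev, c = b4$dc_prev),
                      s5 = list(h = b5$dh_prev, c = b5$dc_prev))
  list(grads = grads, dstate = dstate_prev, dx = b1$dx + dx_res)
}

zero_dstate <- function(model, n) {
  st <- reset_state(model, n)
  list(s1 = st$s1, s2 = st$s2, s3 = st$s3, s4 = st$s4, s5 = st$s5)
}

#' Warm up the recurrent state with Gaussian-noise frames
#'
#' Runs `n` inference steps on i.i.d. standard-normal frames (seeded)
#' starting from a zero state and returns the resulting state without
#' emitting images. Used at startup to avoid the cold-start quality loss
#' of the first real frames.
#'
#' @param model A `recurrent_unet`.
#' @param n Number of noise frames (default 2).
#' @param seed RNG seed for the noise frames.
#' @param input_size Frame side length.
#' @return A warmed-up `model_state`.
#' @export
warmup <- function(model, n = 2L, seed = 1L, input_size = model$spec$input_size) {
  state <- reset_state(model, input_size)
  set.seed(seed)
  for (k in seq_len(n)) {
    x <- matrix(stats::rnorm(input_size^2), ncol = 1L)
    state <- unet_forward_frame(model, x, state)$state
  }
  state
}

#' Reconstruct a cine series frame by frame
#'
#' Stateful application of the network: each frame is de-aliased using the
#' recurrent state accumulated over all previous frames. Streaming
#' (one-frame-at-a-time with carried state) and whole-series application
#' are identical by construction.
#'
#' @param model A `recurrent_unet`.
#' @param aliased Aliased `cine_series` (frames must match the state size).
#' @param state Initial `model_state`; `NULL` for a cold start, or the
#'   result of [warmup()] / a previous call's `state`.
#' @param clip Clip outputs to \[0, 1\] (inference default).
#' @param return_state Also return the final state (for continued
#'   streaming).
#' @return The reconstructed `cine_series`, or a list `(series, state)` if
#'   `return_state = TRUE`.
#' @export
reconstruct_series <- function(model, aliased, state = NULL, clip = TRUE,
                               return_state = FALSE) {
  stopifnot(inherits(model, "recurrent_unet"), inherits(aliased, "cine_series"))
  d <- dim(aliased$frames)
  if (d[1] != d[2]) stop("frames must be square", call. = FALSE)
  if (is.null(state)) state <- reset_state(model, d[1])
  if (state$input_size != d[1])
    stop("state size does not match frame size", call. = FALSE)
  out <- array(0, dim = d)
  for (t in seq_len(d[3])) {
    x <- matrix(aliased$frames[, , t], ncol = 1L)
    r <- unet_forward_frame(model, x, state)
    state <- r$state
    y <- r$y
    if (clip) y <- pmin(pmax(y, 0), 1)
    out[, , t] <- matrix(y, d[1], d[2])
  }
  res <- with_frames(aliased, out)
  if (return_state) list(series = res, state = state) else res
}

#' Save / load a model
#'
#' Weights are serialized with `saveRDS`; a JSON manifest (spec, seed,
#' parameter count) is written alongside for reproducibility bookkeeping.
#'
#' @param model A `recurrent_unet`.
#' @param path Output `.rds` path.
#' @return The path, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  manifest <- list(input_size = model$spec$input_size,
                   hidden = model$spec$hidden, seed = model$seed,
                   parameter_count = parameter_count(model))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
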