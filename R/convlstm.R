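#' Convolutional LSTM layer specification and parameters
#'
#' A 2D ConvLSTM cell whose four gates are computed by 3x3 "same"
#' convolutions over the concatenated current input `X_t` and previous
#' hidden state `H_{t-1}` (4 convolutions on each, i.e. 8 convolutions per
#' layer). Gate equations, without peephole terms:
#' \deqn{i,f,o = \sigma(W * [X_t, H_{t-1}] + b), \quad g = \tanh(\cdot)}
#' \deqn{C_t = f \circ C_{t-1} + i \circ g, \quad H_t = o \circ \tanh(C_t)}
#'
#' Parameter count: `4 * 3^2 * (C_in + C_h) * C_h + 4 * C_h`.
#'
#' @param in_channels,hidden_channels Channel counts.
#' @param seed Seed for Glorot-uniform initialization (`NULL` leaves the
#'   RNG state alone).
#' @return A `convlstm_layer`: weight matrix `(9*(C_in+C_h)) x (4*C_h)`
#'   with gate column blocks ordered (i, f, o, g), bias of length `4*C_h`.
#' @export
convlstm_layer <- function(in_channels, hidden_channels, seed = NULL) {
  cin <- as.integer(in_channels); ch <- as.integer(hidden_channels)
  if (!is.null(seed)) set.seed(seed)
  fan_in <- 9L * (cin + ch)
  lim <- sqrt(6 / (fan_in + ch))
  W <- matrix(stats::runif(fan_in * 4L * ch, -lim, lim), fan_in, 4L * ch)
  structure(list(W = W, b = numeric(4L * ch),
                 in_channels = cin, hidden_channels = ch),
            class = "convlstm_layer")
}

layer_param_count <- function(layer) length(layer$W) + length(layer$b)

#' One ConvLSTM time step
#'
#' @param layer A [convlstm_layer()].
#' @param x Input feature matrix `(H*W) x C_in`.
#' @param state List with `h`, `c` matrices `(H*W) x C_h` (zeros for a cold
#'   start).
#' @param H,W Spatial size of the feature map.
#' @param cache Keep forward intermediates for backpropagation.
#' @return List with `h` (emitted hidden state), `state` (new `h`, `c`),
#'   and if requested `cache`.
#' @export
convlstm_step <- function(layer, x, state, H, W, cache = FALSE) {
  ch <- layer$hidden_channels
  if (ncol(x) != layer$in_channels)
    stop("input channel mismatch", call. = FALSE)
  if (nrow(x) != H * W) stop("input spatial size mismatch", call. = FALSE)
  xh <- cbind(x, state$h)
  P <- im2col(xh, H, W)
  Z <- sweep(P %*% layer$W, 2L, layer$b, "+")
  gi <- seq_len(ch)
  i <- sigmoid(Z[, gi, drop = FALSE])
  f <- sigmoid(Z[, gi + ch, drop = FALSE])
  o <- sigmoid(Z[, gi + 2L * ch, drop = FALSE])
  g <- tanh(Z[, gi + 3L * ch, drop = FALSE])
  cnew <- f * state$c + i * g
  tc <- tanh(cnew)
  h <- o * tc
  out <- list(h = h, state = list(h = h, c = cnew))
  if (cache)
    out$cache <- list(P = P, i = i, f = f, o = o, g = g,
                      c_prev = state$c, tc = tc)
  out
}

# Backward through one ConvLSTM step.
# dh: gradient w.r.t. emitted H_t (including any recurrent contribution
# from t+1 already summed in); dc_next: gradient flowing into C_t from the
# t+1 forget path. Returns gradients for the layer parameters, the input,
# and the previous state.
convlstm_step_backward <- function(layer, cache, dh, dc_next, H, W) {
  ch <- layer$hidden_channels
  cin <- layer$in_channels
  tc <- cache$tc
  do_ <- dh * tc
  dc <- dc_next + dh * cache$o * (1 - tc^2)
  df <- dc * cache$c_prev
  dc_prev <- dc * cache$f
  di <- dc * cache$g
  dg <- dc * cache$i
  dZ <- cbind(di * cache$i * (1 - cache$i),
              df * cache$f * (1 - cache$f),
              do_ * cache$o * (1 - cache$o),
              dg * (1 - cache$g^2))
  dW <- crossprod(cache$P, dZ)
  db <- colSums(dZ)
  dxh <- col2im(dZ %*% t(layer$W), H, W, cin + ch)
  list(dW = dW, db = db,
       dx = dxh[, seq_len(cin), drop = FALSE],
       dh_prev = dxh[, cin + seq_len(ch), drop = FALSE],
       dc_prev = dc_prev)
}
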