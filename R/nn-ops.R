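# Low-level tensor primitives for the recurrent U-Net.
#
# Feature maps are stored as (H*W) x C matrices in column-major pixel
# order; 3x3 "same" convolutions are evaluated as one BLAS matrix product
# against an im2col patch matrix whose gather indices are cached per
# spatial size. All primitives have matching hand-written backward passes
# (verified against numerical differentiation in the test suite).

.nn_cache <- new.env(parent = emptyenv())

# Gather indices (HW x 9) into a zero-padded (H+2) x (W+2) image, column
# offset order: (dr, dc) for dc in -1:1, dr in -1:1 (column-major 3x3).
im2col_index <- function(H, W) {
  key <- paste0("i", H, "x", W)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Hp <- H + 2L
  rows <- rep(seq_len(H), W) + 1L      # padded row of each output pixel
  cols <- rep(seq_len(W), each = H) + 1L
  base <- rows + (cols - 1L) * Hp
  offs <- as.vector(outer(-1:1, (-1:1) * Hp, "+"))
  idx <- matrix(0L, H * W, 9L)
  for (j in 1:9) idx[, j] <- base + offs[j]
  .nn_cache[[key]] <- idx
  idx
}

# Full patch-matrix gather indices for C channels (HW x 9C), channel blocks
# of 9 columns each.
im2col_index_c <- function(H, W, C) {
  key <- paste0("c", H, "x", W, "x", C)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  idx <- im2col_index(H, W)
  npad <- (H + 2L) * (W + 2L)
  out <- matrix(0L, H * W, 9L * C)
  for (c in seq_len(C))
    out[, (c - 1L) * 9L + (1:9)] <- idx + (c - 1L) * npad
  .nn_cache[[key]] <- out
  out
}

# Embed an (HW x C) feature matrix into the zero-padded flat buffer.
pad_flat <- function(x, H, W) {
  C <- ncol(x)
  npad <- (H + 2L) * (W + 2L)
  key <- paste0("p", H, "x", W)
  interior <- .nn_cache[[key]]
  if (is.null(interior)) {
    rows <- rep(seq_len(H), W) + 1L
    cols <- rep(seq_len(W), each = H) + 1L
    interior <- rows + (cols - 1L) * (H + 2L)
    .nn_cache[[key]] <- interior
  }
  buf <- numeric(npad * C)
  buf[as.vector(outer(interior, (seq_len(C) - 1L) * npad, "+"))] <- as.vector(x)
  buf
}

# im2col: (HW x C) -> (HW x 9C) patch matrix.
im2col <- function(x, H, W) {
  C <- ncol(x)
  buf <- pad_flat(x, H, W)
  idx <- im2col_index_c(H, W, C)
  matrix(buf[idx], nrow = H * W)
}

# col2im: scatter-add patch gradients back to an (HW x C) gradient.
col2im <- function(dP, H, W, C) {
  npad <- (H + 2L) * (W + 2L)
  idx <- im2col_index(H, W)
  buf <- numeric(npad * C)
  choff <- (seq_len(C) - 1L) * npad
  for (j in 1:9) {
    ti <- as.vector(outer(idx[, j], choff, "+"))
    vals <- as.vector(dP[, (seq_len(C) - 1L) * 9L + j])
    buf[ti] <- buf[ti] + vals
  }
  key <- paste0("p", H, "x", W)
  interior <- .nn_cache[[key]]
  matrix(buf[as.vector(outer(interior, choff, "+"))], nrow = H * W)
}

# 3x3 same convolution: weights (9*Cin) x Cout, bias length Cout.
conv3_forward <- function(x, H, W, weight, bias) {
  P <- im2col(x, H, W)
  Y <- P %*% weight
  Y <- sweep(Y, 2L, bias, "+")
  list(y = Y, P = P)
}

conv3_backward <- function(dY, P, weight, H, W, Cin) {
  list(dW = crossprod(P, dY),
       db = colSums(dY),
       dx = col2im(dY %*% t(weight), H, W, Cin))
}

# 2x2 max-pool (stride 2). Returns pooled (HW/4 x C) matrix and the flat
# argmax indices used by the backward pass.
maxpool_index <- function(H, W) {
  key <- paste0("m", H, "x", W)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Ho <- H %/% 2L; Wo <- W %/% 2L
  r0 <- rep(seq(1L, H, by = 2L), Wo)
  c0 <- rep(seq(1L, W, by = 2L), each = Ho)
  base <- r0 + (c0 - 1L) * H
  idx <- cbind(base, base + 1L, base + H, base + H + 1L)
  .nn_cache[[key]] <- idx
  idx
}

maxpool_forward <- function(x, H, W) {
  idx <- maxpool_index(H, W)
  C <- ncol(x)
  n <- nrow(idx)
  y <- matrix(-Inf, n, C)
  arg <- matrix(1L, n, C)
  for (j in 1:4) {
    v <- x[idx[, j], , drop = FALSE]
    better <- v > y
    y[better] <- v[better]
    arg[better] <- j
  }
  list(y = y, arg = arg)
}

maxpool_backward <- function(dy, arg, H, W) {
  idx <- maxpool_index(H, W)
  C <- ncol(dy)
  choff <- (seq_len(C) - 1L) * (H * W)
  dxf <- numeric(H * W * C)
  dyf <- as.vector(dy)
  for (j in 1:4) {
    sel <- as.vector(arg == j)
    if (!any(sel)) next
    tgt <- as.vector(outer(idx[, j], choff, "+"))[sel]
    dxf[tgt] <- dxf[tgt] + dyf[sel]
  }
  matrix(dxf, ncol = C)
}

# 2x2 nearest-neighbor upsampling (H,W -> 2H,2W) via a cached gather map.
upsample_index <- function(H, W) {
  key <- paste0("u", H, "x", W)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Ho <- 2L * H
  ro <- rep(seq_len(Ho), 2L * W)
  co <- rep(seq_len(2L * W), each = Ho)
  src <- ((ro + 1L) %/% 2L) + (((co + 1L) %/% 2L) - 1L) * H
  .nn_cache[[key]] <- src
  src
}

upsample_forward <- function(x, H, W) {
  x[upsample_index(H, W), , drop = FALSE]
}

upsample_backward <- function(dy, H, W) {
  src <- upsample_index(H, W)
  unname(rowsum(dy, src, reorder = TRUE))
}

sigmoid <- function(x) 1 / (1 + exp(-x))
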