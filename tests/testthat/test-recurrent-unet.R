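test_that("convlstm cell obeys its gate algebra in limiting cases", {
  layer <- convlstm_layer(1L, 2L, seed = 1L)
  n <- 6L
  zero_state <- list(h = matrix(0, n * n, 2), c = matrix(0, n * n, 2))
  x <- matrix(rnorm(n * n), ncol = 1)
  # all-zero parameters: C_t = 0.5 * tanh(0) ... = 0, H_t = 0
  layer0 <- layer; layer0$W[] <- 0; layer0$b[] <- 0
  r <- convlstm_step(layer0, x, zero_state, n, n)
  expect_equal(max(abs(r$state$c)), 0)
  expect_equal(max(abs(r$h)), 0)
  # forget bias -> +inf, input bias -> -inf: perfect memory C_t = C_{t-1}
  layerm <- layer0
  ch <- 2L
  layerm$b[(ch + 1):(2 * ch)] <- 50     # f ~ 1
  layerm$b[1:ch] <- -50                 # i ~ 0
  cprev <- matrix(rnorm(n * n * 2), n * n, 2)
  rm_ <- convlstm_step(layerm, x, list(h = zero_state$h, c = cprev), n, n)
  expect_equal(rm_$state$c, cprev, tolerance = 1e-10)
})

test_that("single-pixel convlstm step matches a scalar gate-equation oracle", {
  # 1x1 image: only the kernel center taps a nonzero value (zero padding),
  # so the step reduces to a scalar LSTM whose gates we evaluate by hand.
  layer <- convlstm_layer(1L, 1L, seed = 3L)
  x <- matrix(0.7, 1, 1)
  state <- list(h = matrix(0.3, 1, 1), c = matrix(-0.2, 1, 1))
  r <- convlstm_step(layer, x, state, 1L, 1L)
  # center tap of a column-major 3x3 kernel is row 5; input channel block
  # rows 1:9, hidden channel block rows 10:18
  wx <- layer$W[5, ]; wh <- layer$W[14, ]
  z <- wx * 0.7 + wh * 0.3 + layer$b
  i <- 1 / (1 + exp(-z[1])); f <- 1 / (1 + exp(-z[2]))
  o <- 1 / (1 + exp(-z[3])); g <- tanh(z[4])
  cnew <- f * (-0.2) + i * g
  expect_equal(r$state$c[1, 1], cnew, tolerance = 1e-12)
  expect_equal(r$h[1, 1], o * tanh(cnew), tolerance = 1e-12)
})

test_that("parameter counts match closed forms at several widths", {
  expect_identical(parameter_count(convlstm_layer(1L, 2L)), 224L)
  expect_identical(parameter_count(convlstm_layer(3L, 5L)),
                   4L * 9L * (3L + 5L) * 5L + 4L * 5L)
  full <- build_model(unet_spec(128L, c(32L, 64L, 128L)), seed = 1L)
  expect_identical(parameter_count(full), 1790465L)
  half <- build_model(unet_spec(128L, c(16L, 32L, 64L)), seed = 1L)
  ratio <- parameter_count(full) / parameter_count(half)
  expect_gt(ratio, 3.5); expect_lt(ratio, 4.1)
})

test_that("model output shape, residual identity and block count", {
  for (n in c(16L, 32L)) {
    m <- tiny_model(n)
    al <- cine_series(array(runif(n * n * 2), dim = c(n, n, 2)))
    rec <- reconstruct_series(m, al)
    expect_identical(dim(rec$frames), dim(al$frames))
  }
  # zero weights: head outputs 0, so output = clipped input
  m0 <- tiny_model(16L)
  for (nm in radcine:::unet_layer_names()) { m0[[nm]]$W[] <- 0; m0[[nm]]$b[] <- 0 }
  al <- cine_series(array(runif(16 * 16 * 3), dim = c(16, 16, 3)))
  expect_equal(reconstruct_series(m0, al)$frames, al$frames, tolerance = 1e-12)
  # exactly 5 ConvLSTM blocks (2 encoder, 1 bottleneck, 2 decoder)
  m <- tiny_model()
  lstm_blocks <- Filter(function(nm) inherits(m[[nm]], "convlstm_layer"),
                        radcine:::unet_layer_names())
  expect_identical(length(lstm_blocks), 5L)
  expect_error(unet_spec(18L), "divisible")
})

test_that("backpropagation matches numerical gradients through the recurrence", {
  set.seed(42)
  n <- 8L
  model <- build_model(unet_spec(n, c(2L, 2L, 3L)), seed = 3L)
  Tn <- 2L
  X <- lapply(1:Tn, function(t) matrix(rnorm(n * n), ncol = 1))
  Yt <- lapply(1:Tn, function(t) matrix(rnorm(n * n), ncol = 1))
  loss_fn <- function(m) {
    st <- reset_state(m, n); L <- 0
    for (t in 1:Tn) {
      r <- radcine:::unet_forward_frame(m, X[[t]], st)
      st <- r$state
      L <- L + 0.5 * sum((r$y - Yt[[t]])^2)
    }
    L
  }
  st <- reset_state(model, n); caches <- list(); ys <- list()
  for (t in 1:Tn) {
    r <- radcine:::unet_forward_frame(model, X[[t]], st, cache = TRUE)
    st <- r$state; caches[[t]] <- r$cache; ys[[t]] <- r$y
  }
  grads <- radcine:::zero_grads(model)
  dst <- radcine:::zero_dstate(model, n)
  for (t in Tn:1) {
    b <- radcine:::unet_backward_frame(model, caches[[t]], ys[[t]] - Yt[[t]],
                                       dst, grads)
    grads <- b$grads; dst <- b$dstate
  }
  eps <- 1e-5
  for (nm in radcine:::unet_layer_names()) {
    set.seed(match(nm, radcine:::unet_layer_names()))
    for (i in sample(length(model[[nm]]$W), min(2L, length(model[[nm]]$W)))) {
      mp <- model; mp[[nm]]$W[i] <- mp[[nm]]$W[i] + eps
      mm <- model; mm[[nm]]$W[i] <- mm[[nm]]$W[i] - eps
      num <- (loss_fn(mp) - loss_fn(mm)) / (2 * eps)
      expect_equal(grads[[nm]]$dW[i], num, tolerance = 1e-4)
    }
  }
})

test_that("state semantics: reset zeros, Markov chunking, warm-up determinism", {
  n <- 16L
  m <- tiny_model(n)
  st <- reset_state(m)
  expect_true(all(vapply(c("s1", "s2", "s3", "s4", "s5"), function(k)
    max(abs(st[[k]]$h)) == 0 && max(abs(st[[k]]$c)) == 0, logical(1))))
  al <- cine_series(array(runif(n * n * 6), dim = c(n, n, 6)))
  # one pass vs two passes with carried state
  full <- reconstruct_series(m, al, clip = FALSE)
  p1 <- reconstruct_series(m, cine_series(al$frames[, , 1:3]),
                           clip = FALSE, return_state = TRUE)
  p2 <- reconstruct_series(m, cine_series(al$frames[, , 4:6]),
                           state = p1$state, clip = FALSE)
  expect_equal(p2$frames, full$frames[, , 4:6], tolerance = 1e-12)
  # reset restores cold-start behavior bitwise
  again <- reconstruct_series(m, al, state = reset_state(m, n), clip = FALSE)
  expect_identical(full$frames, again$frames)
  # warm-up: deterministic given seed, different across seeds
  w1 <- warmup(m, n = 2L, seed = 5L, input_size = n)
  w2 <- warmup(m, n = 2L, seed = 5L, input_size = n)
  w3 <- warmup(m, n = 2L, seed = 6L, input_size = n)
  expect_identical(w1, w2)
  expect_gt(max(abs(w1$s1$h - w3$s1$h)), 0)
})

test_that("streaming and batched reconstruction are identical", {
  n <- 16L
  m <- tiny_model(n)
  al <- cine_series(array(runif(n * n * 5), dim = c(n, n, 5)))
  batched <- reconstruct_series(m, al)
  st <- reset_state(m, n)
  for (t in 1:5) {
    r <- reconstruct_series(m, cine_series(al$frames[, , t, drop = FALSE]),
                            state = st, return_state = TRUE)
    st <- r$state
    expect_equal(r$series$frames[, , 1], batched$frames[, , t],
                 tolerance = 1e-12)
  }
})

test_that("model round-trips through serialization with its manifest", {
  m <- tiny_model()
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m$lstm3$W, m2$lstm3$W)
  manifest <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(as.integer(manifest$parameter_count), parameter_count(m))
  unlink(c(path, paste0(path, ".json")))
})
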