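# Helper: tiny paired dataset on which de-aliasing is learnable fast.
toy_dataset <- function(n = 16L, frames = 10L, n_train = 2L, n_val = 1L,
                        seed = 2L) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(n_train + n_val)) {
    gt <- array(runif(n * n * frames), dim = c(n, n, frames))
    # input = target plus a fixed structured bias the network can remove
    bias <- matrix(0.2 * sin(seq_len(n * n) / 7), n, n)
    inp <- gt * 0.8 + array(rep(bias, frames), dim = dim(gt))
    out[[i]] <- structure(list(input = cine_series(inp),
                               target = cine_series(gt),
                               split = if (i <= n_train) "train" else "val",
                               view = "SAX"),
                          class = "paired_sample")
  }
  out
}

test_that("chunk_series produces carry-annotated windows that tile the series", {
  ch <- chunk_series(25L, 8L)
  expect_identical(lapply(ch, `[[`, "frames"),
                   list(1:8, 9:16, 17:24, 25L))
  expect_identical(vapply(ch, `[[`, logical(1), "carry"),
                   c(TRUE, TRUE, TRUE, FALSE))
  # exact multiple: single full chunks, last never carries
  ch8 <- chunk_series(8L, 8L)
  expect_identical(length(ch8), 1L)
  expect_identical(ch8[[1]]$frames, 1:8)
  expect_false(ch8[[1]]$carry)
  ch16 <- chunk_series(16L, 8L)
  expect_identical(vapply(ch16, `[[`, logical(1), "carry"), c(TRUE, FALSE))
  # concatenating the windows restores the frame sequence exactly
  for (Tn in c(5L, 8L, 9L, 23L))
    expect_identical(unlist(lapply(chunk_series(Tn, 8L), `[[`, "frames")),
                     1:Tn)
  # accepts a cine_series directly
  s <- cine_series(array(0, dim = c(4, 4, 11)))
  expect_identical(length(chunk_series(s, 4L)), 3L)
  expect_error(train_config(chunk_len = 1L), ">= 2")
  expect_error(chunk_series(0L), "at least one")
})

test_that("loss functions return correct values and gradients", {
  y <- matrix(c(0.2, 0.8, 0.5), ncol = 1)
  t <- matrix(c(0.5, 0.3, 0.5), ncol = 1)
  mae <- radcine:::loss_grad(y, t, "mae")
  expect_equal(mae$loss, mean(abs(y - t)))
  expect_equal(mae$dy, sign(y - t) / 3)
  mse <- radcine:::loss_grad(y, t, "mse")
  expect_equal(mse$loss, mean((y - t)^2))
  expect_equal(mse$dy, 2 * (y - t) / 3)
})

test_that("evaluate_loss equals the analytic residual for a zero network", {
  n <- 16L
  m0 <- tiny_model(n)
  for (nm in radcine:::unet_layer_names()) { m0[[nm]]$W[] <- 0; m0[[nm]]$b[] <- 0 }
  ds <- toy_dataset(n, frames = 4L, n_train = 1L, n_val = 1L)
  # zero head => prediction == input, so loss is mean |input - target|
  expected <- mean(abs(ds[[1]]$input$frames - ds[[1]]$target$frames))
  expect_equal(radcine:::evaluate_loss(m0, ds[1], "mae"), expected,
               tolerance = 1e-12)
  expect_true(is.na(radcine:::evaluate_loss(m0, list(), "mae")))
})

test_that("a few epochs of training reduce train and validation loss", {
  n <- 16L
  ds <- toy_dataset(n)
  m <- build_model(unet_spec(n, c(2L, 3L, 4L)), seed = 5L)
  cfg <- train_config(epochs = 6L, lr = 5e-3, batch_size = 1L,
                      chunk_len = 5L, seed = 3L)
  fit <- train(m, ds, cfg)
  h <- fit$history
  expect_identical(nrow(h), 6L)
  expect_lt(h$train_loss[6], h$train_loss[1])
  expect_lt(min(h$val_loss), h$val_loss[1])
  # returned model attains the best recorded validation loss
  best_vl <- radcine:::evaluate_loss(fit$model, dataset_split(ds, "val"), "mae")
  expect_equal(best_vl, min(h$val_loss), tolerance = 1e-12)
})

test_that("training is deterministic under a fixed seed", {
  n <- 16L
  ds <- toy_dataset(n, frames = 6L)
  m <- build_model(unet_spec(n, c(2L, 2L, 2L)), seed = 9L)
  cfg <- train_config(epochs = 2L, lr = 1e-3, batch_size = 2L, seed = 4L)
  f1 <- train(m, ds, cfg)
  f2 <- train(m, ds, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$lstm1$W, f2$model$lstm1$W)
  expect_error(train(m, dataset_split(ds, "val"), cfg), "no training")
})

test_that("one optimizer step matches a hand-computed Adam update", {
  n <- 8L
  m <- build_model(unet_spec(n, c(2L, 2L, 2L)), seed = 1L)
  g <- radcine:::zero_grads(m)
  for (nm in radcine:::unet_layer_names()) {
    g[[nm]]$dW[] <- 0.5
    g[[nm]]$db[] <- -0.25
  }
  opt <- radcine:::adam_init(m)
  up <- radcine:::adam_step(m, g, opt, lr = 0.01)
  # at t = 1 the bias-corrected update is lr * g / (|g| + eps)
  expect_equal(up$model$lstm1$W,
               m$lstm1$W - 0.01 * 0.5 / (0.5 + 1e-7), tolerance = 1e-12)
  expect_equal(up$model$head$b,
               m$head$b + 0.01 * 0.25 / (0.25 + 1e-7), tolerance = 1e-12)
  expect_identical(up$opt$t, 1L)
})
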