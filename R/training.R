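#' Training configuration
#'
#' Defaults follow the full-scale protocol: 100 epochs, Adam with initial
#' learning rate 0.001, batch size 4, series split into 8-frame chunks
#' with the recurrent state carried (gradient-detached) across chunks and
#' reset only at the end of each complete series (truncated
#' backpropagation through time with window 8). Loss is the mean absolute
#' error.
#'
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param batch_size Series processed chunk-synchronously per optimizer
#'   step.
#' @param chunk_len BPTT chunk length in frames (>= 2).
#' @param loss `"mae"` (default) or `"mse"`.
#' @param seed RNG seed controlling shuffling (weight initialization is
#'   seeded separately in [build_model()]).
#' @param shuffle Shuffle series order every epoch.
#' @param verbose Print per-epoch losses.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 100L, lr = 0.001, batch_size = 4L,
                         chunk_len = 8L, loss = c("mae", "mse"), seed = 1L,
                         shuffle = TRUE, verbose = FALSE) {
  loss <- match.arg(loss)
  chunk_len <- as.integer(chunk_len)
  if (chunk_len < 2L) stop("chunk_len must be >= 2", call. = FALSE)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), chunk_len = chunk_len,
                 loss = loss, seed = as.integer(seed), shuffle = shuffle,
                 verbose = verbose),
            class = "train_config")
}

#' Split a series into BPTT chunks
#'
#' Consecutive chunks of `chunk_len` frames; every chunk except the last
#' carries the recurrent state forward (`carry = TRUE`); after the final
#' (possibly short) chunk the state is reset.
#'
#' @param series A `cine_series`, or an integer frame count.
#' @param chunk_len Chunk length (default 8).
#' @return List of `list(frames = <indices>, carry = <logical>)`.
#' @export
chunk_series <- function(series, chunk_len = 8L) {
  Tn <- if (inherits(series, "cine_series")) n_frames(series) else as.integer(series)
  if (Tn < 1L) stop("series must have at least one frame", call. = FALSE)
  starts <- seq(1L, Tn, by = chunk_len)
  lapply(seq_along(starts), function(k) {
    idx <- starts[k]:min(starts[k] + chunk_len - 1L, Tn)
    list(frames = idx, carry = k < length(starts))
  })
}

adam_init <- function(model) {
  opt <- list(t = 0L)
  for (nm in unet_layer_names())
    opt[[nm]] <- list(mW = model[[nm]]$W * 0, vW = model[[nm]]$W * 0,
                      mb = model[[nm]]$b * 0, vb = model[[nm]]$b * 0)
  opt
}

adam_step <- function(model, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in unet_layer_names()) {
    o <- opt[[nm]]
    o$mW <- beta1 * o$mW + (1 - beta1) * grads[[nm]]$dW
    o$vW <- beta2 * o$vW + (1 - beta2) * grads[[nm]]$dW^2
    o$mb <- beta1 * o$mb + (1 - beta1) * grads[[nm]]$db
    o$vb <- beta2 * o$vb + (1 - beta2) * grads[[nm]]$db^2
    model[[nm]]$W <- model[[nm]]$W - lr * (o$mW / bc1) / (sqrt(o$vW / bc2) + eps)
    model[[nm]]$b <- model[[nm]]$b - lr * (o$mb / bc1) / (sqrt(o$vb / bc2) + eps)
    opt[[nm]] <- o
  }
  list(model = model, opt = opt)
}

loss_grad <- function(y, target, kind) {
  diff <- y - target
  if (kind == "mae") list(loss = mean(abs(diff)), dy = sign(diff) / length(diff))
  else list(loss = mean(diff^2), dy = 2 * diff / length(diff))
}

# Forward-only loss of a model on a list of paired samples.
evaluate_loss <- function(model, samples, kind = "mae") {
  if (length(samples) == 0L) return(NA_real_)
  tot <- 0; npx <- 0
  for (s in samples) {
    rec <- reconstruct_series(model, s$input, clip = FALSE)
    d <- rec$frames - s$target$frames
    tot <- tot + if (kind == "mae") sum(abs(d)) else sum(d^2)
    npx <- npx + length(d)
  }
  tot / npx
}

#' Train a recurrent U-Net on a paired dataset
#'
#' Truncated backpropagation through time: every series is processed in
#' [chunk_series()] chunks; within a chunk gradients flow across frames,
#' between chunks only the state values are carried (gradients are
#' detached), and the state is reset at the end of each series. Up to
#' `batch_size` series are advanced chunk-synchronously, with one Adam
#' update per chunk position averaged over the group.
#'
#' @param model A `recurrent_unet`.
#' @param dataset List of `paired_sample`s; `split == "train"` members are
#'   trained on, `split == "val"` members give the validation loss.
#' @param config A [train_config()].
#' @return List with `model` (best-validation weights if a validation set
#'   exists, else final weights), `final_model`, and `history`
#'   (data.frame epoch/train_loss/val_loss).
#' @export
train <- function(model, dataset, config = train_config()) {
  train_set <- dataset_split(dataset, "train")
  val_set <- dataset_split(dataset, "val")
  if (length(train_set) == 0L) stop("no training samples", call. = FALSE)
  n <- dim(train_set[[1]]$input$frames)[1]
  opt <- adam_init(model)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, model = model)
  set.seed(config$seed)
  for (ep in seq_len(config$epochs)) {
    order_idx <- if (config$shuffle) sample(length(train_set)) else seq_along(train_set)
    ep_loss <- 0; ep_frames <- 0
    for (g0 in seq(1L, length(order_idx), by = config$batch_size)) {
      group <- train_set[order_idx[g0:min(g0 + config$batch_size - 1L,
                                          length(order_idx))]]
      chunks <- lapply(group, function(s) chunk_series(s$input, config$chunk_len))
      states <- lapply(group, function(s) reset_state(model, n))
      max_chunks <- max(vapply(chunks, length, integer(1)))
      for (k in seq_len(max_chunks)) {
        grads <- zero_grads(model)
        active <- 0L; chunk_loss <- 0
        for (si in seq_along(group)) {
          if (k > length(chunks[[si]])) next
          active <- active + 1L
          idx <- chunks[[si]][[k]]$frames
          s <- group[[si]]
          caches <- vector("list", length(idx)); ys <- vector("list", length(idx))
          st <- states[[si]]
          for (j in seq_along(idx)) {
            x <- matrix(s$input$frames[, , idx[j]], ncol = 1L)
            r <- unet_forward_frame(model, x, st, cache = TRUE)
            st <- r$state; caches[[j]] <- r$cache; ys[[j]] <- r$y
          }
          states[[si]] <- st                     # detached carry
          targ <- lapply(idx, function(t) matrix(s$target$frames[, , t], ncol = 1L))
          dst <- zero_dstate(model, n)
          for (j in rev(seq_along(idx))) {
            lg <- loss_grad(ys[[j]], targ[[j]], config$loss)
            chunk_loss <- chunk_loss + lg$loss
            b <- unet_backward_frame(model, caches[[j]],
                                     lg$dy / length(idx), dst, grads)
            grads <- b$grads; dst <- b$dstate
          }
          ep_frames <- ep_frames + length(idx)
        }
        if (active == 0L) next
        if (!is.finite(chunk_loss))
          stop(sprintf("non-finite loss at epoch %d; reduce the learning rate", ep),
               call. = FALSE)
        if (active > 1L)
          for (nm in unet_layer_names()) {
            grads[[nm]]$dW <- grads[[nm]]$dW / active
            grads[[nm]]$db <- grads[[nm]]$db / active
          }
        ad <- adam_step(model, grads, opt, config$lr)
        model <- ad$model; opt <- ad$opt
        ep_loss <- ep_loss + chunk_loss
      }
    }
    vl <- evaluate_loss(model, val_set, config$loss)
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = ep_loss / ep_frames,
                                         val_loss = vl))
    if (config$verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep,
                      ep_loss / ep_frames, vl))
    if (!is.na(vl) && vl < best$loss) best <- list(loss = vl, model = model)
  }
  list(model = if (is.finite(best$loss)) best$model else model,
       final_model = model, history = history)
}
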