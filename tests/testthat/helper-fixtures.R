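# Shared fixtures: all synthetic, generated in code at test time.

# Smooth 2D test image (sum of Gaussian bumps), deterministic.
smooth_phantom <- function(n = 32L) {
  g <- seq(-1, 1, length.out = n)
  X <- outer(g, rep(1, n)); Y <- t(X)
  exp(-((X^2 + Y^2) / 0.3)) + 0.3 * exp(-(((X - 0.3)^2 + Y^2) / 0.1))
}

# Brute-force type-2 NUDFT, intentionally independent of the package
# implementation (explicit per-sample summation).
nudft_oracle <- function(image, kx, ky) {
  H <- nrow(image); W <- ncol(image)
  px <- (0:(H - 1)) - H / 2
  py <- (0:(W - 1)) - W / 2
  vapply(seq_along(kx), function(s) {
    ph <- exp(-2i * pi * (outer(px, rep(1, W)) * kx[s] +
                          outer(rep(1, H), py) * ky[s]))
    sum(image * ph)
  }, complex(1))
}

# Small phantom cine for pipeline tests.
small_cine <- function(view = "SAX", n = 48L, frames = 12L, seed = 11L) {
  generate_cine(phantom_config(view, n_frames = frames, matrix = n,
                               seed = seed))
}

# Tiny network for semantics tests (fast, same topology).
tiny_model <- function(n = 16L, hidden = c(2L, 3L, 4L), seed = 7L) {
  build_model(unet_spec(n, hidden), seed = seed)
}

# Micro paired dataset: per_view series per view at a small matrix size.
micro_corpus <- function(per_view = 2L, n = 16L, frames = 8L, seed = 1L,
                         split = c("train", "val")) {
  configs <- list()
  views <- phantom_views()
  for (v in seq_along(views)) for (i in seq_len(per_view)) {
    cfg <- phantom_config(views[v], n_frames = frames, matrix = n,
                          seed = seed + 100L * v + i)
    cfg$split <- split[(i - 1L) %% length(split) + 1L]
    configs[[length(configs) + 1L]] <- cfg
  }
  configs
}
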