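ssim_fixture <- function() {
  I <- matrix(1:40, 40, 40)
  J <- t(I)
  x <- 0.5 + 0.5 * sin(0.3 * I + 0.1 * J * I / 10) * cos(0.2 * J)
  y <- pmin(pmax(x + 0.1 * sin(1.7 * I * J / 7), 0), 1)
  list(x = x, y = y)
}

test_that("metrics recover analytic values for trivial perturbations", {
  set.seed(8)
  g <- array(runif(40 * 40 * 6, 0.2, 0.8), dim = c(40, 40, 6))
  m0 <- metrics(g, g, frame_range = c(1L, 6L))
  expect_equal(m0$mae, 0)
  expect_equal(m0$mse, 0)
  expect_identical(m0$psnr, Inf)
  expect_equal(m0$ssim, 1, tolerance = 1e-12)
  # uniform +0.1 shift: MAE 0.1, MSE 0.01, PSNR exactly 20 dB
  m1 <- metrics(g + 0.1, g, frame_range = c(2L, 5L))
  expect_equal(m1$mae, 0.1, tolerance = 1e-12)
  expect_equal(m1$mse, 0.01, tolerance = 1e-12)
  expect_equal(m1$psnr, 20, tolerance = 1e-10)
  expect_identical(nrow(m1$per_frame), 4L)
  expect_error(metrics(g, g, frame_range = c(1L, 7L)), "outside")
  expect_identical(radcine:::eval_range(3L), c(3L, 3L))
  expect_identical(radcine:::eval_range(40L), c(5L, 25L))
})

test_that("ssim matches frozen reference-implementation values", {
  f <- ssim_fixture()
  # reference values from scikit-image structural_similarity
  # (gaussian_weights = TRUE, sigma = 1.5, win_size = 11,
  #  use_sample_covariance = FALSE, data_range = 1)
  expect_equal(ssim(f$x, f$y), 0.9094355315059026, tolerance = 1e-10)
  expect_equal(ssim(f$x, 0.8 * f$x + 0.1), 0.9718557285563563,
               tolerance = 1e-10)
  # symmetry and perfect-match limit
  expect_equal(ssim(f$x, f$y), ssim(f$y, f$x), tolerance = 1e-14)
  expect_equal(ssim(f$x, f$x), 1, tolerance = 1e-12)
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "window")
})

test_that("paired Wilcoxon agrees with brute-force sign-flip enumeration", {
  enum_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    Vs <- vapply(0:(2^n - 1), function(mask) {
      signs <- as.integer(intToBits(mask))[1:n]
      sum(r[signs == 1])
    }, numeric(1))
    mu <- n * (n + 1) / 4
    min(1, mean(abs(Vs - mu) >= abs(V - mu) - 1e-12))
  }
  set.seed(13)
  for (rep in 1:4) {
    d <- round(rnorm(8), 3)
    d <- d[!duplicated(abs(d))]
    w <- paired_wilcoxon(d, rep(0, length(d)))
    expect_equal(w$p_value, enum_p(d), tolerance = 1e-12)
  }
  # five concordant pairs: the classic exact two-sided floor 2 * 2^-5
  w5 <- paired_wilcoxon(c(1.1, 2.3, 0.7, 1.9, 3.2), rep(0, 5))
  expect_equal(w5$p_value, 0.0625, tolerance = 1e-12)
  expect_identical(w5$n, 5L)
  # antisymmetry under swapping the arms
  a <- c(0.5, 1.2, -0.3, 2.2, 0.9, -1.4)
  b <- c(0.1, 0.8, 0.4, 1.0, 1.3, -0.2)
  expect_equal(paired_wilcoxon(a, b)$p_value, paired_wilcoxon(b, a)$p_value,
               tolerance = 1e-12)
  expect_error(paired_wilcoxon(1:4 / 10, 1:4 / 10), "zero")
})

test_that("normality check separates normal from exponential samples", {
  set.seed(99)
  gn <- normality_check(rnorm(500))
  ge <- normality_check(rexp(500))
  expect_gt(gn$p_value, 0.01)
  expect_lt(ge$p_value, 1e-6)
  expect_gt(gn$W, ge$W)
  expect_error(normality_check(rep(1, 10)), "constant")
})

test_that("sliding window with width == step reduces to the gridded series", {
  gt <- small_cine("SAX", n = 24L, frames = 8L)
  st <- simulate_spoke_stream(gt, 9L)
  sw <- sliding_window_recon(st, width = 9L, step = 9L, normalize = FALSE)
  gr <- gridded_recon(st, 9L, normalize = "none")
  expect_equal(sw$frames, gr$frames, tolerance = 1e-12)
  expect_identical(n_frames(gr), 8L)
})

test_that("sliding window needs the documented lead-in and smooths motion", {
  expect_identical(sliding_window_leadin(99L, 17L), 41L)
  expect_identical(sliding_window_leadin(9L, 9L), 0L)
  gt <- small_cine("FCH", n = 24L, frames = 8L)
  st <- simulate_spoke_stream(gt, 9L)
  # width 27 centered on frame k's center spoke: the last frame's window
  # needs spokes beyond the stream, so one fewer frame is emitted
  sw <- sliding_window_recon(st, width = 27L, step = 9L)
  expect_identical(n_frames(sw), 7L)
  # pooling spokes across frames damps frame-to-frame variation
  gr <- gridded_recon(st, 9L)
  tv <- function(s) mean(abs(s$frames[, , 2:7] - s$frames[, , 1:6]))
  expect_lt(tv(sw), tv(gr))
  expect_error(sliding_window_recon(st, width = 5L, step = 9L), "width")
})

test_that("catheter visibility ratio is 1 for perfect and 0 for erased devices", {
  flat <- cine_series(array(0.8, dim = c(32, 32, 4)))
  ctr <- matrix(rep(c(16, 16), each = 4), ncol = 2)
  path <- device_path(ctr, amplitude = rep(1, 4), n_blobs = 1L, sd_px = 1.5)
  gt <- apply_balloon(flat, path)
  perfect <- catheter_visibility(gt, gt, path)
  expect_true(all(abs(perfect$ratio - 1) < 1e-12))
  expect_true(all(perfect$visible))
  erased <- catheter_visibility(flat, gt, path)
  expect_true(all(erased$ratio == 0))
  expect_false(any(erased$visible))
  # zero-amplitude frames give no ground-truth depth -> ratio is NA
  path0 <- device_path(ctr, amplitude = c(0, 1, 1, 0), n_blobs = 1L,
                       sd_px = 1.5)
  gt0 <- apply_balloon(flat, path0)
  v0 <- catheter_visibility(gt0, gt0, path0)
  expect_true(all(is.na(v0$ratio[c(1, 4)])))
  expect_true(all(v0$visible[2:3]))
})
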