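test_that("phantom generation is deterministic and periodic", {
  cfg <- phantom_config("SAX", n_frames = 16L, n_cycles = 2L, matrix = 48L,
                        seed = 9L)
  a <- generate_cine(cfg)
  b <- generate_cine(cfg)
  expect_identical(a$frames, b$frames)
  expect_equal(range(a$frames), c(0, 1))
  # period = n_frames / n_cycles = 8 frames: frame 9 repeats frame 1
  expect_equal(a$frames[, , 9], a$frames[, , 1], tolerance = 1e-12)
  expect_equal(a$frames[, , 12], a$frames[, , 4], tolerance = 1e-12)
  # contraction actually moves tissue between end-diastole and end-systole
  expect_gt(mean(abs(a$frames[, , 5] - a$frames[, , 1])), 0.005)
})

test_that("the seven view classes are geometrically distinguishable", {
  frames <- lapply(phantom_views(), function(v)
    generate_cine(phantom_config(v, n_frames = 8L, matrix = 48L,
                                 seed = 3L))$frames[, , 1])
  pairs <- utils::combn(length(frames), 2)
  ss <- apply(pairs, 2, function(p) ssim(frames[[p[1]]], frames[[p[2]]]))
  expect_true(all(ss < 0.9))
})

test_that("balloon attenuation: exact 80% center decrease, identity at zero visibility", {
  s <- small_cine("FCH", n = 48L, frames = 8L)
  ctr <- matrix(rep(c(20, 26), each = 8), ncol = 2)
  path_on <- device_path(ctr, amplitude = rep(1, 8), n_blobs = 1L)
  out <- apply_balloon(s, path_on)
  expect_equal(out$frames[20, 26, 3], 0.2 * s$frames[20, 26, 3],
               tolerance = 1e-12)
  path_off <- device_path(ctr, amplitude = rep(0, 8), n_blobs = 1L)
  expect_equal(apply_balloon(s, path_off)$frames, s$frames)
  # attenuation never increases intensity and keeps the series nonnegative
  expect_true(all(out$frames <= s$frames + 1e-15))
  expect_true(all(out$frames >= 0))
  ramp <- visibility_ramp(6, 2, 5, ramp = 1L)
  expect_true(all(ramp >= 0 & ramp <= 1) && ramp[1] == 0 && max(ramp) == 1)
})

test_that("guidewire produces five attenuation minima along the wire", {
  flat <- cine_series(array(0.8, dim = c(64, 64, 3)))
  ctr <- matrix(rep(c(32, 48), each = 3), ncol = 2)
  path <- device_path(ctr, amplitude = c(1, 1, 1), n_blobs = 5L,
                      sd_px = 1.5, spacing_px = 6, direction = c(0, 1))
  out <- apply_guidewire(flat, path)
  profile <- out$frames[32, , 2]
  interior <- 2:63
  minima <- interior[vapply(interior, function(j)
    profile[j] < profile[j - 1] & profile[j] < profile[j + 1], logical(1))]
  expect_identical(length(minima), 5L)
  expect_equal(minima, c(48 - 4 * 6, 48 - 3 * 6, 48 - 2 * 6, 48 - 6, 48))
  # balloon and guidewire on disjoint supports commute
  s <- small_cine("SAX", n = 64L, frames = 8L)
  wpath <- device_path(matrix(rep(c(32, 48), each = 8), ncol = 2),
                       amplitude = rep(1, 8), n_blobs = 5L, sd_px = 1.5,
                       spacing_px = 6, direction = c(0, 1))
  bpath <- device_path(matrix(rep(c(12, 12), each = 8), ncol = 2),
                       amplitude = rep(1, 8), n_blobs = 1L, sd_px = 2)
  ab <- apply_guidewire(apply_balloon(s, bpath), wpath)
  ba <- apply_balloon(apply_guidewire(s, wpath), bpath)
  expect_equal(ab$frames, ba$frames, tolerance = 1e-12)
})

test_that("generic-mode rate assignment is uniform, seeded, and specific mode is constant", {
  configs <- micro_corpus(per_view = 2L, n = 16L, frames = 8L)
  ds1 <- build_dataset(configs, "generic", seed = 5L)
  ds2 <- build_dataset(configs, "generic", seed = 5L)
  r1 <- vapply(ds1, function(s) s$accel$spokes_per_frame, integer(1))
  r2 <- vapply(ds2, function(s) s$accel$spokes_per_frame, integer(1))
  expect_identical(r1, r2)
  expect_true(all(r1 %in% c(13L, 17L, 21L, 25L, 29L, 33L)))
  # uniformity at scale: 600 draws over 6 rates within a binomial 99% band
  set.seed(5)
  draws <- sample(c(13L, 17L, 21L, 25L, 29L, 33L), 600, replace = TRUE)
  counts <- table(draws)
  expect_true(all(counts >= 70 & counts <= 130))
  ds_s <- build_dataset(configs[1:3], "specific", spokes = 17L)
  expect_true(all(vapply(ds_s, function(s) s$accel$r_factor, numeric(1)) ==
                    acceleration_factor(17, 32)))
  expect_error(build_dataset(list(), "specific"), "empty")
})

test_that("leave-one-out split partitions the corpus and isolates the held-out view", {
  configs <- micro_corpus(per_view = 3L, n = 16L, frames = 8L,
                          split = c("train", "val", "test"))
  ds <- build_dataset(configs, "specific", spokes = 9L)
  for (v in c("PA", "SAX")) {
    sp <- loo_split(ds, v)
    expect_false(v %in% vapply(sp$train, function(s) s$view, character(1)))
    expect_false(v %in% vapply(sp$val, function(s) s$view, character(1)))
    expect_true(all(vapply(sp$test, function(s) s$view, character(1)) == v))
    expect_identical(length(sp$train) + length(sp$val) + length(sp$test) +
                       length(sp$unused), length(ds))
    # leaving one out keeps 6 training classes
    expect_identical(length(unique(vapply(sp$train, function(s) s$view,
                                          character(1)))), 6L)
  }
  # the 7 splits cover each view as test exactly once
  tested <- vapply(phantom_views(), function(v)
    unique(vapply(loo_split(ds, v)$test, function(s) s$view, character(1))),
    character(1))
  expect_identical(sort(unname(tested)), sort(phantom_views()))
  expect_error(loo_split(ds, "APICAL"), "unknown view")
})
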