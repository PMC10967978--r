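test_that("wave_speed and delay_samples follow the printed conventions", {
  expect_equal(wave_speed(medium(1)), 299.792458)
  expect_equal(wave_speed(medium(4)), 299.792458 / 2)
  expect_equal(wave_speed(medium(9)), 299.792458 / 3)

  expect_identical(delay_samples(0, 299.792458, 6), 0L)
  expect_identical(delay_samples(300, 299.792458, 6), 6L)
  # direct arithmetic oracle: (149.9 / 299.792458) * 100 = 50.002 -> 50
  expect_identical(delay_samples(149.9, 299.792458, 100), 50L)
  expect_error(delay_samples(-1, 1, 1), "d >= 0")
})

test_that("das_image and coherence_factor match the naive oracle", {
  arr <- tiny_array()
  grid <- build_grid(c(300, 300), 75, 150)  # 5 x 5 grid
  set.seed(21)
  fs <- 4
  signals <- lapply(1:4, function(m) time_signal(rnorm(64), fs))
  t_win <- 3

  ref <- naive_das(signals, arr, grid, t_win)
  cfg <- beamform_config(t_win = t_win)
  img <- das_image(signals, arr, grid, cfg)
  expect_rel_error(as.numeric(img$values), ref$I, 1e-9)

  cf <- coherence_factor(signals, arr, grid, cfg)
  expect_rel_error(as.numeric(cf$values), ref$CF, 1e-9)

  idas <- idas_image(signals, arr, grid, cfg)
  expect_rel_error(as.numeric(idas$values), ref$I * ref$CF, 1e-9)
  expect_rel_error(as.numeric(idas$cf), ref$CF, 1e-9)
})

test_that("das_image degenerate and error cases", {
  arr <- tiny_array()
  grid <- build_grid(c(300, 300), 100, 150)
  zero <- lapply(1:4, function(m) time_signal(rep(0, 32), 4))
  img <- das_image(zero, arr, grid)
  expect_true(all(img$values == 0))

  # fs mismatch rejected
  bad <- zero; bad[[2]] <- time_signal(rep(0, 32), 8)
  expect_error(das_image(bad, arr, grid), "fs")
  expect_error(das_image(zero[1:3], arr, grid), "one signal per antenna")

  # M = 1: image equals the channel's windowed squared energy per pixel
  one <- antenna_array(list(antenna_element(1, c(150, 150, 0))))
  set.seed(3)
  sig <- time_signal(rnorm(128), 4)
  cfg <- beamform_config(t_win = 2)
  img1 <- das_image(list(sig), one, grid, cfg)
  ref <- naive_das(list(sig), one, grid, 2)
  expect_rel_error(as.numeric(img1$values), ref$I, 1e-9)
})

test_that("coherence factor hits its closed-form values", {
  # the closed forms hold when the channels agree at the *delayed* samples;
  # constant traces make that true for every pixel regardless of geometry
  arr <- tiny_array()
  grid <- build_grid(c(300, 300), 150, 100)
  fs <- 4
  base <- rep(0.8, 96)
  cfg <- beamform_config(t_win = 4)

  # all channels equal at the delayed samples -> CF = 1 (Cauchy-Schwarz)
  same <- lapply(1:4, function(m) time_signal(base, fs))
  cf1 <- coherence_factor(same, arr, grid, cfg)
  expect_equal(as.numeric(cf1$values), rep(1, 9), tolerance = 1e-12)

  # exactly one active channel of M = 4 -> CF = 1/4
  solo <- lapply(1:4, function(m) {
    time_signal(if (m == 1) base else rep(0, 96), fs)
  })
  cf2 <- coherence_factor(solo, arr, grid, cfg)
  expect_equal(as.numeric(cf2$values), rep(1 / 4, 9), tolerance = 1e-12)

  # un-normalized form reaches M for identical channels
  cfgu <- beamform_config(t_win = 4, cf_normalized = FALSE)
  cfu <- coherence_factor(same, arr, grid, cfgu)
  expect_equal(as.numeric(cfu$values), rep(4, 9), tolerance = 1e-12)

  # two channels +a and -a -> CF = 0
  two <- antenna_array(list(antenna_element(1, c(100, 150, 0)),
                            antenna_element(2, c(200, 150, 0))))
  pm <- list(time_signal(base, fs), time_signal(-base, fs))
  cf3 <- coherence_factor(pm, two, grid, beamform_config(t_win = 4))
  expect_equal(as.numeric(cf3$values), rep(0, 9), tolerance = 1e-12)
})

test_that("IDAS relates to DAS as CF dictates", {
  arr <- tiny_array()
  grid <- build_grid(c(300, 300), 50, 150)
  fs <- 4
  cfg <- beamform_config(t_win = 4)

  # channels equal at the delayed samples: CF == 1 so IDAS == DAS exactly
  same <- lapply(1:4, function(m) time_signal(rep(1.3, 128), fs))
  expect_equal(idas_image(same, arr, grid, cfg)$values,
               das_image(same, arr, grid, cfg)$values, tolerance = 1e-12)

  # normalized CF <= 1 implies IDAS <= DAS pointwise
  set.seed(9)
  mixed <- lapply(1:4, function(m) time_signal(rnorm(128), fs))
  d <- das_image(mixed, arr, grid, cfg)
  i <- idas_image(mixed, arr, grid, cfg)
  expect_true(all(i$values <= d$values + 1e-12))
  expect_true(all(i$cf >= 0 & i$cf <= 1))
  expect_true(all(d$values >= 0))
})

test_that("DAS is permutation invariant and scales quadratically", {
  arr <- tiny_array()
  grid <- build_grid(c(300, 300), 100, 120)
  fs <- 4
  set.seed(5)
  sigs <- lapply(1:4, function(m) time_signal(rnorm(96), fs))
  cfg <- beamform_config(t_win = 3)
  img <- das_image(sigs, arr, grid, cfg)

  perm <- c(3, 1, 4, 2)
  arr_p <- antenna_array(lapply(seq_along(perm), function(i) {
    e <- arr$elements[[perm[i]]]
    antenna_element(i, e$position, e$orientation)
  }), extent = arr$extent)
  img_p <- das_image(sigs[perm], arr_p, grid, cfg)
  expect_equal(img_p$values, img$values, tolerance = 1e-12)

  k <- 2.7
  scaled <- lapply(sigs, function(s) time_signal(k * s$samples, fs))
  img_k <- das_image(scaled, arr, grid, cfg)
  expect_equal(img_k$values, k^2 * img$values, tolerance = 1e-9)
  cf <- coherence_factor(sigs, arr, grid, cfg)
  cf_k <- coherence_factor(scaled, arr, grid, cfg)
  expect_equal(cf_k$values, cf$values, tolerance = 1e-9)
})

test_that("a point scatterer is recovered at its grid position", {
  # target on a grid point; image argmax must land within one spacing
  arr <- tiny_array()
  target <- c(150, 150, 150)
  sigs <- point_target_signals(arr, target, spec = short_spec(601),
                               t_stop = 6, n_t = 1201)
  grid <- build_grid(c(300, 300), 15, 150)
  img <- das_image(sigs, arr, grid, beamform_config(t_win = 0.5))
  pk <- which(img$values == max(img$values), arr.ind = TRUE)
  expect_lte(abs(img$grid$x[pk[1, 1]] - target[1]), 15)
  expect_lte(abs(img$grid$y[pk[1, 2]] - target[2]), 15)

  # IDAS suppresses sidelobes at least as well as DAS
  idas <- idas_image(sigs, arr, grid, beamform_config(t_win = 0.5))
  psr <- function(im) {
    v <- as.numeric(im$values) / max(im$values)
    pk_i <- which.max(v)
    max(v[-pk_i] / v[pk_i])^-1
  }
  expect_gte(psr(idas), psr(img))
})

test_that("planar imaging detects loaded scenes and stays silent on empty", {
  arr <- build_default_array()
  sp <- sweep_spec()
  grid <- build_grid(c(300, 300), 10, 210)
  cfg <- beamform_config(variant = "das")

  # aorta on the right side: suprathreshold ridge under the right columns
  scene <- mwi_scene(list(
    scatterer("cylinder", c(225, 150, 210), dims = c(600, 30),
              reflectivity = 0.8, axis = c(0, 1, 0))),
    clutter = default_clutter())
  pair <- synth_sweeps(scene, arr, sp, echo_snr_db = Inf, seed = 4)
  img <- planar_image(pair, arr, grid, cfg)
  mask <- threshold_image(img, 0.6)
  expect_true(any(mask))
  hit <- which(mask, arr.ind = TRUE)
  xs <- img$grid$x[hit[, 1]]
  ys <- img$grid$y[hit[, 2]]
  # ridge sits on the aorta side and is elongated along the tube axis
  cen <- centroid(img, mask)
  expect_gt(cen["x"], 180)
  expect_gt(diff(range(ys)), diff(range(xs)))

  # empty scene: reference-plane amplitudes are pure noise, far below the
  # loaded scene's
  empty_pair <- synth_sweeps(mwi_scene(clutter = default_clutter()), arr,
                             sp, echo_snr_db = Inf, seed = 4)
  img0 <- planar_image(empty_pair, arr, grid, cfg)
  expect_lt(max(attr(img0, "amplitudes")),
            0.01 * max(attr(img, "amplitudes")))

  # missing reference rejected
  expect_error(planar_image(list(loaded = pair$loaded), arr, grid, cfg),
               "empty reference")
})
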