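make_image <- function(values, spacing = 10, depth = 0) {
  nx <- nrow(values)
  ny <- ncol(values)
  grid <- build_grid(c((nx - 1) * spacing, (ny - 1) * spacing),
                     spacing, depth)
  planarmwi:::mwi_image(grid, values, normalization = "raw")
}

test_that("threshold_image masks as documented and is monotone in thr", {
  u <- make_image(matrix(0.5, 5, 5))
  expect_false(any(threshold_image(u, 0.6) &
                     !threshold_image(normalize_image(u), 0.6)))
  # uniform image normalizes to 1 everywhere -> full mask; at raw 0.5 the
  # normalized value is 1, so test the unnormalized semantics explicitly
  half <- planarmwi:::mwi_image(build_grid(c(40, 40), 10, 0),
                                matrix(0.5, 5, 5), normalization = "max1")
  expect_false(any(threshold_image(half, 0.6)))

  m <- matrix(0, 5, 5); m[3, 4] <- 1
  img <- make_image(m)
  mask <- threshold_image(img, 0.6)
  expect_identical(which(mask), which(m == 1))
  expect_true(all(threshold_image(img, 0)))

  # monotone: higher threshold gives a subset mask
  set.seed(8)
  r <- make_image(matrix(runif(36), 6, 6))
  m4 <- threshold_image(r, 0.4); m7 <- threshold_image(r, 0.7)
  expect_true(all(!m7 | m4))
  expect_error(threshold_image(r, 1.5), "thr")
})

test_that("centroid extracts weighted positions in mm", {
  # symmetric Gaussian blob centered on a grid point
  xs <- seq(0, 100, 10)
  blob <- outer(xs, xs, function(x, y) exp(-((x - 50)^2 + (y - 50)^2) / 400))
  img <- make_image(blob)
  cen <- centroid(img, threshold_image(img, 0.3))
  expect_equal(unname(cen), c(50, 50), tolerance = 5)

  m <- matrix(0, 5, 5); m[2, 3] <- 1
  img1 <- make_image(m)
  cen1 <- centroid(img1, threshold_image(img1, 0.5))
  expect_equal(unname(cen1), c(10, 20))

  # two equal pixels at (0,0) and (10,0) -> midpoint (5,0)
  m2 <- matrix(0, 5, 5); m2[1, 1] <- 1; m2[2, 1] <- 1
  img2 <- make_image(m2)
  cen2 <- centroid(img2, threshold_image(img2, 0.5))
  expect_equal(unname(cen2), c(5, 0))

  expect_error(centroid(img2, matrix(FALSE, 5, 5)), "empty mask")
})

test_that("positioning_error reproduces every printed evaluation cell", {
  # frozen reference: the nine cases with their printed absolute and
  # relative errors (one decimal, percentages)
  printed <- rbind(
    c(4.7, 2.1, 0.8, 0.3), c(14.1, 6.6, 13.3, 7.2), c(1.6, 0.7, 3.2, 2.3),
    c(4.5, 2.6, 11.0, 4.2), c(8.6, 4.8, 1.6, 0.8), c(4.7, 2.7, 6.1, 4.4),
    c(4.8, 3.4, 2.3, 0.9), c(3.9, 2.8, 4.7, 2.5), c(3.9, 2.8, 1.3, 1.0)
  )
  cases <- poc_reference_cases()
  expect_identical(nrow(cases), 9L)
  for (i in seq_len(9)) {
    row <- positioning_error(c(cases$real_x[i], cases$real_y[i]),
                             c(cases$obt_x[i], cases$obt_y[i]),
                             case_id = cases$case[i])
    expect_equal(c(row$err_x, row$rel_err_x, row$err_y, row$rel_err_y),
                 printed[i, ], tolerance = 1e-12)
  }

  same <- positioning_error(c(100, 200), c(100, 200))
  expect_equal(c(same$err_x, same$rel_err_x, same$err_y, same$rel_err_y),
               c(0, 0, 0, 0))
  expect_warning(zero <- positioning_error(c(0, 100), c(1, 99)),
                 "relative error undefined")
  expect_true(is.na(zero$rel_err_x))
})

test_that("error_table stacks rows and writes CSV", {
  rows <- list(positioning_error(c(100, 100), c(98, 103), 1),
               positioning_error(c(200, 150), c(201, 149), 2))
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- error_table(rows, path)
  expect_identical(nrow(tab), 2L)
  expect_true(file.exists(path))
  back <- read.csv(path)
  expect_equal(back$err_x, tab$err_x)
})

test_that("sff is a bounded, delay- and scale-invariant similarity", {
  sp <- short_spec(301)
  tx <- transmit_pulse(sp, -2, 2, 401)
  expect_equal(sff(tx, tx), 100, tolerance = 1e-9)

  # scaled and delayed copy: still 100
  delayed <- time_signal(c(rep(0, 37), 0.5 * tx$samples), tx$fs)
  expect_equal(sff(tx, delayed), 100, tolerance = 1e-9)

  # long incommensurate tones: near-orthogonal at every lag
  fs <- 20
  tt <- seq(0, 50, by = 1 / fs)
  t1 <- time_signal(sin(2 * pi * 1 * tt), fs)
  t2 <- time_signal(sin(2 * pi * 2.5 * tt), fs)
  expect_lt(sff(t1, t2), 5)

  expect_error(sff(tx, time_signal(rep(0, 10), 1)), "nonzero")
  set.seed(1)
  for (k in 1:5) {
    a <- time_signal(rnorm(64), 4); b <- time_signal(rnorm(64), 4)
    s <- sff(a, b)
    expect_gte(s, 0); expect_lte(s, 100)
  }
})

test_that("snr_estimate recovers the injected echo-to-noise ratio", {
  arr <- antenna_array(list(antenna_element(1, c(150, 150, 0))))
  sp <- sweep_spec(0.01, 6, 1001)
  scene <- mwi_scene(list(scatterer("point", c(150, 150, 150))))
  reps <- lapply(1:6, function(k) {
    synth_sweeps(scene, arr, sp, echo_snr_db = 28, seed = 40 + k)
  })
  empties <- do.call(rbind, lapply(reps, function(p) p$empty$s11))
  est <- snr_estimate(empties, reps[[1]]$loaded$s11[1, ], sp)
  expect_lt(abs(est - 28), 2)

  # noise off: zero variance -> Inf sentinel
  clean <- synth_sweeps(scene, arr, sp, echo_snr_db = Inf, seed = 1)
  empties0 <- rbind(clean$empty$s11, clean$empty$s11)
  expect_identical(snr_estimate(empties0, clean$loaded$s11[1, ], sp), Inf)

  # no echo in the loaded sweep: estimate collapses far below the echo case
  est0 <- snr_estimate(empties, reps[[2]]$empty$s11[1, ], sp)
  expect_lt(est0, est - 10)
  expect_error(snr_estimate(empties[1, , drop = FALSE],
                            reps[[1]]$loaded$s11[1, ], sp), "repetitions")
})

test_that("penetration depth follows the plane-wave attenuation law", {
  expect_identical(penetration_depth(medium(2, 0), 1), Inf)

  # low-loss limit: PD ~ lambda0 / (pi tan_d sqrt(eps_r)) within 1%
  f <- 1; tan_d <- 0.01; eps_r <- 1
  eps0 <- 8.8541878128e-12
  sigma <- tan_d * 2 * pi * f * 1e9 * eps0 * eps_r
  pd <- penetration_depth(medium(eps_r, sigma), f)
  lambda0_mm <- 299.792458 / f
  pd_lowloss <- lambda0_mm / (pi * tan_d * sqrt(eps_r))
  expect_lt(abs(pd - pd_lowloss) / pd_lowloss, 0.01)

  # strictly decreasing in sigma at fixed f, eps_r
  pds <- vapply(c(0.1, 0.3, 1, 3), function(s) {
    penetration_depth(medium(50, s), 3)
  }, numeric(1))
  expect_true(all(diff(pds) < 0))
  expect_error(penetration_depth(medium(1, 1), 0), "f must be")
})

test_that("spatial resolution follows the v/(2B) convention", {
  expect_equal(spatial_resolution(sweep_spec(0.0001, 6.0001, 101)),
               299.792458 / 12, tolerance = 1e-9)
  r1 <- spatial_resolution(sweep_spec(1, 4, 11))
  r2 <- spatial_resolution(sweep_spec(1, 7, 11))
  expect_equal(r1 / r2, 2)
  expect_equal(spatial_resolution(sweep_spec(1, 4, 11), medium(4)), r1 / 2)
})
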