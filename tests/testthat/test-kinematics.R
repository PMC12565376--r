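test_that("acceleration magnitude follows Pythagoras and unit conversion", {
  tri <- triaxial_series(
    (0:9) / 31.25, c(1, 0, 3, rep(0, 7)), c(0, 0, 4, rep(0, 7)),
    c(0, 0, 0, rep(1, 7)),
    sampling_rate = 31.25
  )
  n <- accel_norm(tri)
  expect_equal(n$value[1], 1)
  expect_equal(n$value[2], 0)
  expect_equal(n$value[3], 5)

  si <- accel_norm(tri, to_si = TRUE)
  expect_equal(si$value[1], 9.8)
  expect_equal(si$value, 9.8 * n$value, tolerance = 1e-12)
  expect_equal(series_units(si), "m/s^2")
})

test_that("the magnitude is invariant to 3-D rotations", {
  withr::with_seed(8, {
    n <- 200
    x <- rnorm(n)
    y <- rnorm(n)
    z <- rnorm(n)
    # random rotation from QR of a Gaussian matrix
    qr_m <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(qr_m) < 0) qr_m[, 1] <- -qr_m[, 1]
  })
  tri <- triaxial_series((0:(n - 1)) / 31.25, x, y, z, sampling_rate = 31.25)
  rot <- t(qr_m %*% rbind(x, y, z))
  tri_r <- triaxial_series((0:(n - 1)) / 31.25, rot[, 1], rot[, 2], rot[, 3],
    sampling_rate = 31.25
  )
  expect_equal(accel_norm(tri)$value, accel_norm(tri_r)$value, tolerance = 1e-9)
})

test_that("task signatures expose NSR and center of position", {
  tri <- gen_imu(duration = 180, seed = 4, task = "resting", osc_amp = 0)
  sig <- imu_signature(tri)
  truth <- attr(tri, "truth")
  expect_true(in_ci(truth$mms_scale, sig$gamma$scale_ci))
  expect_equal(sig$location, "pectoralis")
  expect_named(sig$center, c("x", "y", "z", "norm"))

  flatg <- gen_imu(duration = 60, seed = 1, fluct_scale = 0, osc_amp = 0)
  expect_error(imu_signature(flatg))

  # dispersion ordering across generator regimes
  walk <- imu_signature(gen_imu(duration = 180, seed = 4, task = "walking", osc_amp = 0))
  expect_gt(walk$gamma$nsr, sig$gamma$nsr)
})

test_that("the task space table is tidy, keyed, and clusterable", {
  skip_if_not_installed("mclust")
  sigs <- list()
  for (loc in c("pectoralis", "arm", "leg")) {
    for (task in c("resting", "walking")) {
      tri <- gen_imu(
        duration = 150, seed = match(loc, c("pectoralis", "arm", "leg")),
        location = loc, task = task, osc_amp = 0,
        participant = "p1"
      )
      sigs[[paste(loc, task)]] <- imu_signature(tri)
    }
  }
  ts <- task_space(sigs)
  expect_equal(nrow(ts), 6)
  expect_equal(nrow(task_space(list())), 0)
  expect_error(task_space(c(sigs, sigs[1])), "duplicate")

  km <- kmeans(scale(log(ts$nsr)), centers = 2, nstart = 10)
  ari <- mclust::adjustedRandIndex(km$cluster, ts$task)
  expect_gt(ari, 0.9)
})
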