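test_that("shape normalization centres, scales, and is similarity-invariant", {
  g <- gen_face(n_frames = 20, seed = 1)
  ng <- normalize_face(g)
  per_frame <- ng |>
    dplyr::group_by(frame) |>
    dplyr::summarise(
      cx = mean(x), cy = mean(y), s = sd(sqrt(x^2 + y^2))
    )
  expect_lt(max(abs(per_frame$cx)), 1e-9)
  expect_lt(max(abs(per_frame$cy)), 1e-9)
  expect_lt(max(abs(per_frame$s - 1)), 1e-9)

  moved <- dplyr::mutate(g, x = 7 * x + 100, y = 7 * y - 40)
  ng2 <- normalize_face(spiba:::new_face_grid(moved, fps = 30))
  expect_equal(ng2$x, ng$x, tolerance = 1e-9)
  expect_equal(ng2$y, ng$y, tolerance = 1e-9)

  # idempotence
  ng3 <- normalize_face(ng)
  expect_equal(ng3$x, ng$x, tolerance = 1e-12)

  degen <- dplyr::mutate(g, x = 1, y = 2)
  expect_error(normalize_face(spiba:::new_face_grid(degen, fps = 30)), "degenerate")
})

test_that("the trigeminal region map is a validated disjoint cover", {
  rm <- face_region_map()
  expect_equal(sort(rm$landmark), 0:67)
  expect_equal(length(unique(rm$region)), 3)
  expect_true(all(table(rm$region) > 0))

  expect_error(face_region_map(v1 = c(5, 17:26, 36:47)), "more than one region")
  expect_error(face_region_map(v1 = 17:26), "cover all 68")

  path <- withr::local_tempfile(fileext = ".json")
  write_region_map(rm, path)
  rm2 <- read_region_map(path)
  expect_equal(
    dplyr::arrange(rm2, landmark), dplyr::arrange(rm, landmark)
  )

  parts <- parcellate(gen_face(n_frames = 10, seed = 2), rm)
  expect_equal(sum(vapply(parts, function(p) length(unique(p$landmark)), numeric(1))), 68)
})

test_that("spline speed fields recover analytic kinematics", {
  n <- 90
  fps <- 30
  tt <- (0:(n - 1)) / fps
  # landmark 0 static at (1, 2); landmark 1 moves linearly at (3, 4)/s
  two <- dplyr::bind_rows(
    tibble::tibble(frame = 1:n, time = tt, landmark = 0L, x = 1, y = 2),
    tibble::tibble(frame = 1:n, time = tt, landmark = 1L, x = 3 * tt, y = 4 * tt)
  )
  grid <- spiba:::new_face_grid(dplyr::arrange(two, frame, landmark), fps = fps)
  sp <- landmark_speeds(grid)
  s0 <- sp$speed[sp$landmark == 0]
  s1 <- sp$speed[sp$landmark == 1]
  expect_equal(max(abs(s0)), 0)
  interior <- 10:(n - 10)
  expect_true(all(abs(s1[interior] - 5) / 5 < 0.01))

  # circular motion: speed = r * omega
  r <- 2
  om <- 2 * pi * 0.5
  circ <- tibble::tibble(
    frame = rep(1:n, each = 2), time = rep(tt, each = 2), landmark = rep(0:1, n),
    x = c(rbind(r * cos(om * tt), 0)),
    y = c(rbind(r * sin(om * tt), 1))
  )
  spc <- landmark_speeds(spiba:::new_face_grid(circ, fps = fps))
  sc0 <- spc$speed[spc$landmark == 0]
  expect_true(all(abs(sc0[interior] - r * om) / (r * om) < 0.02))

  expect_error(landmark_speeds(gen_face(n_frames = 3, seed = 1)), "at least 5")
})

test_that("region signatures pool spikes order-free and flag frozen regions", {
  g <- gen_face(
    n_frames = 1500, seed = 13, movers_per_region = 4, k = 15,
    peak_sigma = 2.5 / 30, orbit_radius = 0.3,
    pixel_scale = 1, pixel_offset = c(0, 0)
  )
  sigs <- region_signatures(g,
    min_prominence = 0.125, normalize = FALSE,
    smoothing = "interpolate"
  )
  tr <- attr(g, "truth")
  for (rg in c("V1", "V2", "V3")) {
    expect_true(sigs[[rg]]$sufficient)
    expect_lt(
      abs(sigs[[rg]]$gamma$scale - tr$regions[[rg]]$mms_scale) /
        tr$regions[[rg]]$mms_scale, 0.25
    )
    expect_equal(
      unname(sigs[[rg]]$moment_point),
      c(
        sigs[[rg]]$gamma$mean, sigs[[rg]]$gamma$variance,
        sigs[[rg]]$gamma$skewness
      )
    )
  }
  # injected dispersion ordering across the three regions
  nsrs <- vapply(sigs, function(s) s$gamma$nsr, numeric(1))
  expect_true(all(diff(nsrs[c("V1", "V2", "V3")]) > 0))

  # pooling is invariant to landmark order within a region
  shuffled <- g[order(g$frame, rev(g$landmark)), ]
  sig2 <- region_signatures(spiba:::new_face_grid(shuffled, fps = 30),
    min_prominence = 0.125, normalize = FALSE, smoothing = "interpolate"
  )
  expect_equal(sig2$V1$gamma$shape, sigs$V1$gamma$shape, tolerance = 1e-9)

  frozen <- gen_face(n_frames = 150, seed = 1, movers_per_region = 0)
  fsig <- region_signatures(frozen)
  expect_false(any(vapply(fsig, function(s) s$sufficient, logical(1))))
})

test_that("moment triangles match an independent Heron oracle", {
  stub <- function(p) {
    structure(
      list(
        sufficient = TRUE, region = "V1",
        moment_point = c(mean = p[1], variance = p[2], skewness = p[3])
      ),
      class = "region_signature"
    )
  }
  tri <- moment_triangle(stub(c(0, 0, 0)), stub(c(1, 0, 0)), stub(c(0, 1, 0)))
  expect_equal(tri$area, 0.5, tolerance = 1e-12)

  col <- moment_triangle(stub(c(0, 0, 0)), stub(c(1, 1, 1)), stub(c(2, 2, 2)))
  expect_equal(col$area, 0, tolerance = 1e-12)

  for (seed in 1:5) {
    withr::with_seed(seed, pts <- matrix(runif(9), 3))
    t2 <- moment_triangle(stub(pts[1, ]), stub(pts[2, ]), stub(pts[3, ]))
    a <- sqrt(sum((pts[2, ] - pts[1, ])^2))
    b <- sqrt(sum((pts[3, ] - pts[2, ])^2))
    cc <- sqrt(sum((pts[3, ] - pts[1, ])^2))
    s <- (a + b + cc) / 2
    heron <- sqrt(max(s * (s - a) * (s - b) * (s - cc), 0))
    expect_equal(t2$area, heron, tolerance = 1e-9)
  }
})

test_that("EMD trajectories are zero against their own window", {
  g <- gen_face(
    n_frames = 900, seed = 17, movers_per_region = 6, k = 15,
    peak_sigma = 2.5 / 30, orbit_radius = 0.3,
    pixel_scale = 1, pixel_offset = c(0, 0)
  )
  sigs <- region_signatures(g,
    min_prominence = 0.125, normalize = FALSE,
    smoothing = "interpolate"
  )
  # reference = the first 150-frame window's own spikes, per region
  refs <- lapply(sigs, function(s) {
    s$amplitudes$amplitude[s$amplitudes$time < 150 / 30]
  })
  traj <- emd_trajectory(g,
    references = list(rest = refs), window = 150, overlap = 0.5,
    min_prominence = 0.125, normalize = FALSE, smoothing = "interpolate"
  )
  expect_equal(length(unique(traj$window_start)), floor((900 - 150) / 75) + 1)
  first <- traj[traj$window_start == 1, ]
  expect_true(all(first$emd < 1e-12))
  expect_true(all(traj$emd >= 0, na.rm = TRUE))
})

test_that("transfer entropy detects directed lag-1 coupling", {
  withr::with_seed(21, {
    x <- rnorm(5000)
    y <- rnorm(5000)
  })
  expect_lt(abs(transfer_entropy(x, y)), 0.05)

  y2 <- c(0, x[-5000])
  te_fwd <- transfer_entropy(x, y2)
  te_rev <- transfer_entropy(y2, x)
  expect_gte(te_fwd - te_rev, 0.2)

  expect_equal(transfer_entropy(rep(1, 100), rep(2, 100)), 0)

  speeds <- tibble::tibble(
    region = rep(c("V1", "V2", "V3"), each = 5000),
    time = rep(1:5000, 3),
    speed = c(x, y2, withr::with_seed(22, rnorm(5000)))
  )
  m <- transfer_entropy_matrix(speeds)
  expect_true(all(is.na(diag(m))))
  expect_gt(m["V1", "V2"], m["V2", "V1"])
})

test_that("1-D EMD behaves as a metric on sampled distributions", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      a <- rgamma(100, 3, scale = 0.2)
      b <- rgamma(120, 5, scale = 0.1)
      cc <- runif(80)
    })
    expect_equal(emd_1d(a, b), emd_1d(b, a), tolerance = 1e-12)
    expect_equal(emd_1d(a, a), 0)
    expect_lte(emd_1d(a, cc), emd_1d(a, b) + emd_1d(b, cc) + 1e-12)
  }
})
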