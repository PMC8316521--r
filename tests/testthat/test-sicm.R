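# hopping-mode scan simulation and height-map processing

as_topo <- function(height, pixel_size) {
  structure(list(height = height, pixel_size = pixel_size,
                 feature_truth = NULL), class = "topography")
}

test_that("the current-distance law obeys its limits and inversion", {
  pip <- pipette_model(radius = 50, c_s = 0.01)
  expect_gt(current_distance(1e9, pip), 1 - 1e-6)          # bulk limit
  expect_equal(current_distance(0.5, pip), 0.5)            # z = c_s r_p
  z <- seq(0.1, 100, length.out = 200)
  expect_true(all(diff(current_distance(z, pip)) > 0))     # monotone
  expect_error(current_distance(-1, pip), "z must be")

  # setpoint inversion against a numerical root-finding oracle
  for (sp in c(0.9, 0.98, 0.99)) {
    z_root <- stats::uniroot(function(z) current_distance(z, pip) - sp,
                             c(1e-6, 1e6), tol = 1e-12)$root
    expect_equal(detection_gap(pip, sp), z_root, tolerance = 1e-8)
  }
  expect_equal(detection_gap(pip, 0.99), 99 * 0.01 * 50)
})

test_that("a flat surface scans flat and scan time follows the pixel budget", {
  pip <- pipette_model(50)
  topo <- as_topo(matrix(500, 64, 64), 78)
  hm <- hop_scan(topo, pip, scan_config(hopping_height = 2000), noise_sigma = 0)
  expect_lt(max(abs(hm$height - 500)), 0.1)
  expect_true(all(hm$valid))

  # 200 x 100 pixels at 200 Hz -> 100 s (ideal, no overhead)
  topo2 <- as_topo(matrix(100, 100, 200), 200)
  hm2 <- hop_scan(topo2, pip, scan_config(hopping_height = 1000, pixel_rate = 200),
                  noise_sigma = 0)
  expect_equal(hm2$meta$scan_time_s, 100)
  expect_error(hop_scan(as_topo(matrix(c(0, 900), 64, 64), 78), pip,
                        scan_config(hopping_height = 500)), "hopping_height")
})

test_that("step-edge width reflects the ~3 r_p lateral resolution rule", {
  h <- matrix(0, 64, 128); h[, 65:128] <- 300
  pip <- pipette_model(50)
  hm <- hop_scan(as_topo(h, 10), pip, scan_config(hopping_height = 2000),
                 noise_sigma = 0)
  prof <- hm$height[32, ]
  x10 <- stats::approx(prof, seq_along(prof), 30, ties = "ordered")$y
  x90 <- stats::approx(prof, seq_along(prof), 270, ties = "ordered")$y
  width_nm <- (x90 - x10) * 10
  expect_gt(width_nm, 3 * 50 / 2)
  expect_lt(width_nm, 3 * 50 * 2)
})

test_that("scanning a smooth topography is faithful within the stated bound", {
  tp <- simulate_topography(c(96, 96), pixel_size = 78, n_microvilli = 10,
                            n_filopodia = 1, seed = 3)
  pip <- pipette_model(50)
  hm <- hop_scan(tp, pip, scan_config(hopping_height = 4000), noise_sigma = 1,
                 seed = 4)
  rmse <- sqrt(mean((hm$height - tp$height)^2))
  expect_lte(rmse, max(1, 50 / 5))
  # same seed -> identical map
  hm2 <- hop_scan(tp, pip, scan_config(hopping_height = 4000), noise_sigma = 1,
                  seed = 4)
  expect_identical(hm$height, hm2$height)
})

test_that("relative topography is independent of the setpoint", {
  tp <- simulate_topography(c(64, 64), pixel_size = 78, n_microvilli = 5,
                            seed = 9)
  pip <- pipette_model(50)
  h98 <- hop_scan(tp, pip, scan_config(setpoint = 0.98, hopping_height = 4000),
                  noise_sigma = 0)
  h99 <- hop_scan(tp, pip, scan_config(setpoint = 0.99, hopping_height = 4000),
                  noise_sigma = 0)
  d <- h98$height - h99$height
  expect_lt(diff(range(d)), 0.3)   # constant offset only (quantization)
})

test_that("plane leveling is exact, bump-preserving, and idempotent", {
  ny <- 64; nx <- 64
  yy <- matrix(seq_len(ny), ny, nx); xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  plane <- 3 * xx - 2 * yy + 40
  hm <- cumulantscope:::new_height_map(plane, 78)
  lv <- level_plane(hm)
  expect_lt(max(abs(lv$height)), 1e-9 * diff(range(plane)))
  expect_true(lv$leveled)

  # bump amplitude preserved within 1% when the bump is small in area
  bump <- 200 * exp(-((yy - 32)^2 + (xx - 32)^2) / (2 * 2^2))
  lvb <- level_plane(cumulantscope:::new_height_map(plane + bump, 78))
  expect_lt(abs((max(lvb$height) - stats::median(lvb$height)) - 200) / 200, 0.01)

  # idempotence
  lv2 <- level_plane(lvb)
  expect_equal(level_plane(lv2)$height, lv2$height, tolerance = 1e-12)
  bad <- cumulantscope:::new_height_map(matrix(1, 8, 8),
                                        78, valid = matrix(FALSE, 8, 8))
  expect_error(level_plane(bad), "valid")
})

test_that("band-pass isolates microvilli-scale features", {
  # plane input: (interior) output is ~0 -- a plane is all low frequency
  ny <- 96; nx <- 96
  yy <- matrix(seq_len(ny), ny, nx); xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  hmp <- cumulantscope:::new_height_map((2 * xx + yy) * 10, 50)
  bp0 <- bandpass(hmp, 2000, 150)
  inner <- bp0$height[25:72, 25:72]
  expect_lt(max(abs(inner)), 0.01 * diff(range(hmp$height)))

  # white noise: variance strictly reduced, zero mean
  set.seed(10)
  hmn <- cumulantscope:::new_height_map(matrix(stats::rnorm(96^2, 0, 10), 96, 96), 50)
  bpn <- bandpass(hmn, 2000, 150)
  expect_lt(stats::var(as.vector(bpn$height)), stats::var(as.vector(hmn$height)))
  expect_equal(mean(bpn$height), 0, tolerance = 1e-12)

  # microvilli on a dome: >= 90% of features recovered within 2 px
  tpm <- simulate_topography(c(128, 128), pixel_size = 50,
                             dome = list(height = 2000),
                             n_microvilli = 15,
                             microvillus_width = c(120, 160),
                             n_filopodia = 0, seed = 5)
  hmm <- hop_scan(tpm, pipette_model(50), scan_config(hopping_height = 4000),
                  noise_sigma = 1, seed = 6)
  bp <- bandpass(hmm, 2000, 150)
  ft <- tpm$feature_truth
  found <- 0
  for (i in seq_len(nrow(ft))) {
    cy <- round(ft$y[i] / 50); cx <- round(ft$x[i] / 50)
    win <- bp$height[max(1, cy - 2):min(128, cy + 2),
                     max(1, cx - 2):min(128, cx + 2)]
    if (max(win) == max(bp$height[max(1, cy - 4):min(128, cy + 4),
                                  max(1, cx - 4):min(128, cx + 4)]))
      found <- found + 1
  }
  expect_gte(found / nrow(ft), 0.9)
  expect_error(bandpass(hmm, 150, 2000), "exceed")
})
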