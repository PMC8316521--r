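# cumulant engine: joint cumulants, 2D/3D cross-cumulant images, flattening

test_that("joint cumulants follow the closed forms and contracts", {
  expect_equal(cumulant_timeseries(matrix(5, 100, 2), 2), 0)
  expect_equal(cumulant_timeseries(matrix(5, 100, 3), 3), 0)
  expect_equal(cumulant_timeseries(matrix(5, 100, 4), 4), 0)
  expect_error(cumulant_timeseries(matrix(1, 100, 3), 2), "columns")
  expect_error(cumulant_timeseries(matrix(1, 5, 2), 2), "10")

  em <- emitter_set(0, 0, epsilon = 1, tau_on = 10, tau_off = 10)
  tr <- as.numeric(simulate_blink_traces(em, 1e5, seed = 4))
  m <- matrix(tr, ncol = 1)
  expect_equal(cumulant_timeseries(m[, c(1, 1)], 2), 0.25, tolerance = 0.01)
  expect_lt(abs(cumulant_timeseries(m[, c(1, 1, 1)], 3)),
            5 * cumulant_block_se(tr, 3))
  expect_equal(cumulant_timeseries(m[, c(1, 1, 1, 1)], 4), -0.125,
               tolerance = 0.02)
})

test_that("auto-cumulant pixels reduce to cumulant_timeseries", {
  sc <- dense_scene_movie(8, 300, ny = 12, nx = 12,
                          optics = std_optics(sigma0 = 100), seed = 3)
  mv <- sc$movie
  for (n in 2:4) {
    ci <- sofi2d(mv, n)
    for (px in list(c(3, 4), c(7, 7))) {
      trace <- mv$data[, px[1], px[2]]
      expect_equal(ci$values[n * (px[1] - 1) + 1, n * (px[2] - 1) + 1],
                   cumulant_timeseries(matrix(trace, ncol = 1)[, rep(1, n)], n),
                   tolerance = 1e-12)
    }
  }
})

test_that("grid arithmetic: padded shape, mask, and determinism", {
  sc <- dense_scene_movie(8, 150, ny = 12, nx = 12,
                          optics = std_optics(sigma0 = 100), seed = 3)
  for (n in 2:4) {
    ci <- sofi2d(sc$movie, n)
    expect_equal(dim(ci$values), c(n * 12, n * 12))
    expect_equal(ci$grid_spacing, 100 / n)
    # valid exactly up to refined index n*(Y-1)+1
    expect_true(all(ci$mask[seq_len(n * 11 + 1), seq_len(n * 11 + 1)]))
    expect_true(all(!ci$mask[(n * 11 + 2):(n * 12), ]))
    expect_equal(dim(valid_region(ci)), c(n * 12 - (n - 1), n * 12 - (n - 1)))
  }
  expect_identical(sofi2d(sc$movie, 2)$values, sofi2d(sc$movie, 2)$values)
  expect_error(sofi2d(sc$movie, 5), "order")
})

test_that("sqrt(n) PSF narrowing holds for a single blinking emitter", {
  sim <- single_emitter_movie(3000, tau_on = 2, tau_off = 2, seed = 11)
  wf_sigma <- fit_g2d(apply(sim$movie$data, c(2, 3), mean), 100)$sigma
  ci <- sofi2d(sim$movie, 2, flatten = TRUE)
  s2 <- fit_g2d(abs(valid_region(ci)), 50)$sigma
  expect_lt(abs(s2 - wf_sigma / sqrt(2)) / (wf_sigma / sqrt(2)), 0.05)
})

test_that("cumulant images are additive over independent emitters and scale as eps^n", {
  opt <- std_optics()
  noise_off <- list(poisson = FALSE, read_sigma = 0)
  e1 <- emitter_set(600, 800, epsilon = 500, tau_on = 2, tau_off = 2)
  e2 <- emitter_set(1000, 800, epsilon = 500, tau_on = 2, tau_off = 2)
  both <- emitter_set(c(600, 1000), 800, epsilon = 500, tau_on = 2, tau_off = 2)
  t1 <- simulate_blink_traces(e1, 4000, seed = 21)
  t2 <- simulate_blink_traces(e2, 4000, seed = 22)
  m1 <- render_movie(e1, t1, opt, 16, 16, noise = noise_off)
  m2 <- render_movie(e2, t2, opt, 16, 16, noise = noise_off)
  mb <- m1; mb$data <- m1$data + m2$data      # independent emitters summed
  c1 <- valid_region(sofi2d(m1, 2)); c2 <- valid_region(sofi2d(m2, 2))
  cbth <- valid_region(sofi2d(mb, 2))
  scale <- max(abs(cbth))
  expect_lt(max(abs(cbth - (c1 + c2))) / scale, 0.05)

  # eps -> 2 eps multiplies the order-n image by 2^n (noise-free: exact)
  for (n in 2:4) {
    e2x <- e1; e2x$epsilon <- 1000
    m2x <- render_movie(e2x, t1, opt, 16, 16, noise = noise_off)
    r <- valid_region(sofi2d(m2x, n)) / valid_region(sofi2d(m1, n))
    r <- r[is.finite(r)]
    expect_equal(stats::median(r), 2^n, tolerance = 1e-6)
  }
})

test_that("3rd-order image of a 50% duty-cycle emitter is null", {
  # noise-free: Poisson shot noise and zero-clipped read noise both carry
  # their own positive 3rd cumulants on auto-pixels, which is real physics
  # but not the blinking-statistics property under test. The null holds in
  # expectation over trace realizations (any single trace has an empirical
  # duty cycle slightly off 0.5 and hence a genuine (1 - 2p) residual), so
  # the image mean is averaged over independent seeds.
  s_k <- vapply(1:10, function(k) {
    sim <- single_emitter_movie(1500, tau_on = 3, tau_off = 3, ny = 12,
                                nx = 12, seed = 300 + k,
                                noise = list(poisson = FALSE, read_sigma = 0))
    mean(valid_region(sofi2d(sim$movie, 3)))
  }, numeric(1))
  expect_lt(abs(mean(s_k)), 3 * stats::sd(s_k) / sqrt(length(s_k)))
})

test_that("multiplane plane count matches the combinatorial oracle", {
  # oracle: enumerate multisets of n plane indices confined to adjacent
  # pairs and count the distinct centroid positions
  oracle_planes <- function(n, P) {
    sums <- c()
    for (q in seq_len(P - 1)) {
      for (k in 0:n) sums <- c(sums, (n - k) * q + k * (q + 1))
    }
    length(unique(sums))
  }
  opt <- optics_model(150, 100, n_planes = 5, plane_spacing = 350)
  cx <- 3 * 100
  em <- emitter_set(cx, cx, z = 0, epsilon = 800, tau_on = 2, tau_off = 4)
  tr <- simulate_blink_traces(em, 120, seed = 41)
  # the grid-arithmetic contract does not depend on flux capture, so the
  # PSF-support check is disabled for this deliberately tiny field
  mv <- render_movie(em, tr, opt, 6, 6,
                     noise = list(poisson = FALSE, read_sigma = 0),
                     flux_tol = 1)
  for (n in 2:4) {
    for (P in 2:5) {
      sub <- mv
      sub$data <- mv$data[, seq_len(P), , , drop = FALSE]
      sub$optics$n_planes <- P
      ci <- sofi3d(sub, n)
      expect_equal(dim(ci$values)[1], n * (P - 1) + 1)
      expect_equal(dim(ci$values)[1], oracle_planes(n, P))
      expect_equal(ci$plane_spacing_out, 350 / n)
      expect_equal(dim(ci$values)[2:3], c(n * 6, n * 6))
    }
  }
  expect_error(sofi3d(single_emitter_movie(150)$movie, 2), "single plane")
})

test_that("the cumulant volume peaks at the emitter's plane", {
  opt <- optics_model(150, 100, n_planes = 4, plane_spacing = 350)
  cx <- 7 * 100
  em <- emitter_set(cx, cx, z = plane_positions(opt)[2], epsilon = 1500,
                    tau_on = 2, tau_off = 4)
  tr <- simulate_blink_traces(em, 500, seed = 43)
  mv <- render_movie(em, tr, opt, 14, 14, seed = 44)
  ci <- sofi3d(mv, 2, flatten = TRUE)
  prof <- apply(abs(ci$values), 1, max)
  # physical plane 2 sits at virtual axial index 2*(2-1)+1 = 3
  expect_equal(which.max(prof), 3)
})

test_that("flattening divides by the Gaussian distance factor", {
  sc <- dense_scene_movie(20, 200, ny = 16, nx = 16,
                          optics = std_optics(sigma0 = 100), seed = 51)
  raw <- sofi2d(sc$movie, 2, flatten = FALSE)
  flat <- flatten(raw, sigma = 150)

  # auto pixels (D = 1) unchanged
  expect_equal(flat$values[1, 1], raw$values[1, 1])
  expect_equal(flat$values[5, 7], raw$values[5, 7])
  # order 2, pixel pair at distance d: divisor exp(-d^2 / (4 sigma^2))
  d_lat <- 100
  expect_equal(flat$values[2, 1],
               raw$values[2, 1] / exp(-d_lat^2 / (4 * 150^2)),
               tolerance = 1e-12)
  d_diag2 <- 2 * 100^2
  expect_equal(flat$values[2, 2],
               raw$values[2, 2] / exp(-d_diag2 / (4 * 150^2)),
               tolerance = 1e-12)
  # flatten-at-compute and flatten-after agree; double flattening errors
  expect_equal(flat$values, sofi2d(sc$movie, 2, flatten = TRUE, sigma = 150)$values)
  expect_error(flatten(flat), "already")
})

test_that("flattening suppresses the virtual-pixel checkerboard", {
  sc <- dense_scene_movie(500, 2000, ny = 48, nx = 48,
                          noise = list(poisson = FALSE, read_sigma = 0),
                          seed = 61)
  raw <- sofi2d(sc$movie, 2, flatten = FALSE)
  expect_gt(checkerboard_amp(raw) / checkerboard_amp(flatten(raw)), 10)
})
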