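# affine registration, warping, cross-sections, correlation statistics

test_that("affine fitting recovers known transforms", {
  # identity
  pts <- data.frame(x_src = c(0, 100, 0, 100), y_src = c(0, 0, 100, 100))
  idm <- fit_affine(cbind(pts, x_dst = pts$x_src, y_dst = pts$y_src))
  expect_equal(idm$A, diag(2), tolerance = 1e-12)
  expect_equal(idm$t, c(0, 0), tolerance = 1e-12)
  expect_equal(idm$residual_rms, 0, tolerance = 1e-12)

  # rotation 17 deg, scale 1.03, shift (5, -3): machine precision
  th <- 17 * pi / 180
  A <- 1.03 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tt <- c(5, -3)
  set.seed(2)
  src <- cbind(stats::runif(10, 0, 100), stats::runif(10, 0, 100))
  dst <- sweep(src %*% t(A), 2, tt, `+`)
  am <- fit_affine(data.frame(x_src = src[, 1], y_src = src[, 2],
                              x_dst = dst[, 1], y_dst = dst[, 2]))
  expect_lt(max(abs(am$A - A)), 1e-9)
  expect_lt(max(abs(am$t - tt)), 1e-9)

  # exact interpolation with 3 non-collinear points
  am3 <- fit_affine(data.frame(x_src = src[1:3, 1], y_src = src[1:3, 2],
                               x_dst = dst[1:3, 1], y_dst = dst[1:3, 2]))
  expect_lt(am3$residual_rms, 1e-9)

  # 0.5 px noise -> residual RMS about 0.5 px
  set.seed(3)
  noisy <- dst + matrix(stats::rnorm(20, 0, 0.5), 10, 2)
  amn <- fit_affine(data.frame(x_src = src[, 1], y_src = src[, 2],
                               x_dst = noisy[, 1], y_dst = noisy[, 2]))
  expect_gt(amn$residual_rms, 0.25)
  expect_lt(amn$residual_rms, 1.0)

  expect_error(fit_affine(data.frame(x_src = 1:3, y_src = 2 * (1:3),
                                     x_dst = 1:3, y_dst = 2 * (1:3))),
               "collinear")
  expect_error(fit_affine(data.frame(x_src = 1, y_src = 1,
                                     x_dst = 1, y_dst = 1)), "at least 3")
})

test_that("warping is exact for identity/integer shifts and closes under inversion", {
  set.seed(4)
  img <- matrix(0, 64, 64)
  for (k in 1:25)
    img <- img + outer(stats::dnorm(1:64, stats::runif(1, 12, 52), 3),
                       stats::dnorm(1:64, stats::runif(1, 12, 52), 3))
  idm <- fit_affine(data.frame(x_src = c(0, 100, 0), y_src = c(0, 0, 100),
                               x_dst = c(0, 100, 0), y_dst = c(0, 0, 100)))
  w <- warp_image(img, 50, idm, c(64, 64), 50)
  expect_equal(w$values[2:63, 2:63], img[2:63, 2:63], tolerance = 1e-12)

  # pure integer-pixel translation: exact shift
  shm <- fit_affine(data.frame(x_src = c(0, 100, 0), y_src = c(0, 0, 100),
                               x_dst = c(150, 250, 150), y_dst = c(100, 100, 200)))
  ws <- warp_image(img, 50, shm, c(64, 64), 50)
  expect_equal(ws$values[10:60, 10:60], img[10:60 - 2, 10:60 - 3],
               tolerance = 1e-12)

  # warp then inverse-warp: interior RMSE < 1% of the dynamic range
  th <- 4 * pi / 180
  A <- 1.05 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  src <- cbind(c(0, 1000, 0), c(0, 0, 1000))
  dst <- sweep(src %*% t(A), 2, c(60, -40), `+`)
  am <- fit_affine(data.frame(x_src = src[, 1], y_src = src[, 2],
                              x_dst = dst[, 1], y_dst = dst[, 2]))
  w1 <- warp_image(img, 50, am, c(64, 64), 50)
  v1 <- w1$values; v1[!w1$valid] <- 0
  w2 <- warp_image(v1, 50, affine_invert(am), c(64, 64), 50)
  inner <- matrix(FALSE, 64, 64); inner[12:52, 12:52] <- TRUE
  ok <- inner & w2$valid
  rmse <- sqrt(mean((w2$values[ok] - img[ok])^2))
  expect_lt(rmse / diff(range(img)), 0.01)
})

test_that("cross-section extraction normalizes and flags degenerate profiles", {
  hm <- cumulantscope:::new_height_map(matrix(5, 32, 32), 50)
  flat <- extract_profiles(hm, matrix(2, 32, 32), c(100, 800, 1400, 800))
  expect_true(all(flat$zero_range))
  expect_true(is.na(pearson(flat)))
  expect_true(attr(pearson(flat), "undefined"))

  # aligned bumps peak at the same sample
  xs <- seq_len(64)
  ridge <- outer(rep(1, 64), exp(-(xs - 30)^2 / (2 * 3^2)))
  hm2 <- cumulantscope:::new_height_map(ridge * 300, 50)
  cs <- extract_profiles(hm2, ridge * 7, c(100, 1600, 3100, 1600))
  expect_equal(which.max(cs$height), which.max(cs$intensity))
  expect_equal(range(cs$height), c(0, 1))
  expect_equal(pearson(cs), 1, tolerance = 1e-12)

  # width = 1 equals single-line sampling; wider sections average
  cs1 <- extract_profiles(hm2, ridge, c(100, 1600, 3100, 1600), width = 1)
  expect_identical(cs$height, cs1$height)
  cs3 <- extract_profiles(hm2, ridge, c(100, 1600, 3100, 1600), width = 3)
  expect_equal(cs3$height, cs1$height, tolerance = 1e-9)

  # sections leaving the image fail loudly
  expect_error(extract_profiles(hm2, ridge, c(-500, 1600, 3100, 1600)),
               "valid image area")
})

test_that("anti-correlated profiles give r = -1", {
  xs <- seq_len(64)
  ridge <- outer(rep(1, 64), exp(-(xs - 30)^2 / (2 * 3^2)))
  hm <- cumulantscope:::new_height_map(ridge * 100, 50)
  cs <- extract_profiles(hm, 10 - ridge * 5, c(100, 1600, 3100, 1600))
  expect_equal(pearson(cs), -1, tolerance = 1e-12)
})

test_that("co-localized sections correlate strongly, displaced ones do not", {
  r_match <- numeric(30); r_disp <- numeric(30)
  pm <- ridge_pair(shift_px = 0, seed = 11)
  pd <- ridge_pair(shift_px = 8, seed = 12)   # displaced by 2x width
  for (i in 1:30) {
    y_nm <- (2 * i + 3) * 50
    sec <- c(20 * 50, y_nm, 120 * 50, y_nm)
    r_match[i] <- pearson(extract_profiles(pm$height, pm$intensity, sec))
    r_disp[i] <- pearson(extract_profiles(pd$height, pd$intensity, sec))
  }
  expect_gt(stats::median(r_match), 0.8)
  expect_lt(stats::median(r_disp), 0.3)
  expect_lt(compare_groups(r_match, r_disp)$p, 0.05)
})

test_that("the Welch test matches the closed form and stats::t.test", {
  a <- c(0.91, 0.85, 0.88, 0.95, 0.79)
  b <- c(0.35, 0.41, 0.28, 0.33, 0.45)
  # dual route 1: textbook Welch formula on the Fisher-z values
  za <- atanh(a); zb <- atanh(b)
  se2 <- stats::var(za) / 5 + stats::var(zb) / 5
  t_manual <- (mean(za) - mean(zb)) / sqrt(se2)
  dof_manual <- se2^2 / ((stats::var(za) / 5)^2 / 4 + (stats::var(zb) / 5)^2 / 4)
  res <- compare_groups(a, b)
  expect_equal(res$t, t_manual, tolerance = 1e-10)
  expect_equal(res$dof, dof_manual, tolerance = 1e-10)
  # dual route 2: stats::t.test as an independent implementation
  tt <- stats::t.test(za, zb)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)

  # identical groups: t = 0, p = 1
  same <- compare_groups(c(0.1, 0.2, 0.3, 0.4), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # degenerate: zero variance in both groups
  deg <- compare_groups(rep(0.5, 4), rep(0.5, 4))
  expect_true(deg$degenerate)
  expect_error(compare_groups(c(0.1, 0.2), c(0.3, 0.4, 0.5)), "at least 3")
})
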