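# Control-point affine registration of fluorescence onto topography, and
# topography-fluorescence correspondence statistics from cross-section
# profiles (Pearson r, Welch group comparison on Fisher-z transformed r).

#' Fit a 2D affine transform from control-point pairs
#'
#' Least-squares estimate of `target = A %*% source + t` from >= 3
#' non-collinear point pairs (hand-selected features). With exactly 3
#' non-collinear pairs the fit interpolates exactly.
#'
#' @param pairs data.frame with columns `x_src, y_src, x_dst, y_dst`
#'   (physical units, nm).
#' @return object of class `affine_map`: list(A (2x2), t (length 2),
#'   residual_rms, n_points).
#' @export
fit_affine <- function(pairs) {
  pairs <- as.data.frame(pairs)
  need <- c("x_src", "y_src", "x_dst", "y_dst")
  if (!all(need %in% names(pairs)))
    stop_param("pairs needs columns %s", paste(need, collapse = ", "))
  n <- nrow(pairs)
  if (n < 3) stop_param("need at least 3 control-point pairs")
  X <- cbind(pairs$x_src, pairs$y_src, 1)
  if (qr(X)$rank < 3)
    stop_param("control points are collinear: affine transform is degenerate")
  bx <- qr.coef(qr(X), pairs$x_dst)
  by <- qr.coef(qr(X), pairs$y_dst)
  A <- rbind(c(bx[1], bx[2]), c(by[1], by[2]))
  t <- c(bx[3], by[3])
  pred <- X %*% rbind(c(bx[1], by[1]), c(bx[2], by[2]), c(bx[3], by[3]))
  resid <- sqrt(rowSums((cbind(pairs$x_dst, pairs$y_dst) - pred)^2))
  structure(list(A = A, t = t, residual_rms = sqrt(mean(resid^2)),
                 n_points = n), class = "affine_map")
}

#' Apply an affine map to points
#' @param map an `affine_map`.
#' @param pts matrix/data.frame with columns x, y.
#' @return matrix with columns x, y in target coordinates.
#' @export
affine_apply <- function(map, pts) {
  pts <- as.matrix(pts)[, 1:2, drop = FALSE]
  sweep(pts %*% t(map$A), 2, map$t, `+`)
}

#' Invert an affine map
#' @param map an `affine_map`.
#' @export
affine_invert <- function(map) {
  Ai <- solve(map$A)
  structure(list(A = Ai, t = as.vector(-Ai %*% map$t),
                 residual_rms = map$residual_rms, n_points = map$n_points),
            class = "affine_map")
}

#' @export
print.affine_map <- function(x, ...) {
  cat(sprintf("<affine_map> A = [%.4f %.4f; %.4f %.4f], t = (%.2f, %.2f), rms %.3g nm (%d points)\n",
              x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2], x$t[1], x$t[2],
              x$residual_rms, x$n_points))
  invisible(x)
}

#' Warp an image onto a target grid through an affine map
#'
#' Resamples a source image (e.g. a SOFI image) onto the target (SICM)
#' pixel grid by bilinear interpolation: each target pixel center is
#' mapped back through the inverse transform and sampled in the source.
#' Target pixels falling outside the source are masked (`NA` + mask).
#'
#' @param image source matrix.
#' @param src_pixel_size nm per source pixel.
#' @param map `affine_map` from source nm coordinates to target nm
#'   coordinates.
#' @param target_shape integer c(Y, X) of the target grid.
#' @param target_pixel_size nm per target pixel.
#' @return list(values (matrix, NA outside), valid (logical matrix)).
#' @export
warp_image <- function(image, src_pixel_size, map, target_shape,
                       target_pixel_size) {
  image <- as.matrix(image)
  ny <- target_shape[1]; nx <- target_shape[2]
  tx <- ((rep(seq_len(nx), each = ny)) - 0.5) * target_pixel_size
  ty <- ((rep(seq_len(ny), times = nx)) - 0.5) * target_pixel_size
  inv <- affine_invert(map)
  src <- affine_apply(inv, cbind(tx, ty))
  # nm -> fractional source pixel index (center of pixel i at (i-0.5)*px)
  col <- src[, 1] / src_pixel_size + 0.5
  row <- src[, 2] / src_pixel_size + 0.5
  v <- bilinear_sample(image, row, col)
  values <- matrix(v, ny, nx)
  list(values = values, valid = !is.na(values))
}

#' Extract paired height/intensity cross-section profiles
#'
#' Samples both channels along a line segment (optionally averaged across
#' `width` parallel lines spaced one pixel apart) and min-max normalizes
#' each profile to [0, 1]. Both images must live on the same grid
#' (registration first).
#'
#' @param height `height_map` (or matrix) on the target grid.
#' @param intensity matrix on the same grid.
#' @param section numeric c(x0, y0, x1, y1) endpoints in nm.
#' @param width number of parallel sampling lines (odd; 1 = single line).
#' @param n_samples samples along the line; default one per pixel.
#' @param pixel_size nm per pixel (taken from `height` if it is a
#'   `height_map`).
#' @return object of class `cross_section`: list(height, intensity
#'   (normalized), height_raw, intensity_raw, s (arclength nm), zero_range
#'   (named flags)).
#' @export
extract_profiles <- function(height, intensity, section, width = 1,
                             n_samples = NULL, pixel_size = NULL) {
  if (inherits(height, "height_map")) {
    pixel_size <- pixel_size %||% height$pixel_size
    hmat <- height$height
  } else hmat <- as.matrix(height)
  if (is.null(pixel_size)) stop_param("pixel_size is required")
  imat <- as.matrix(intensity)
  if (!all(dim(hmat) == dim(imat)))
    stop_param("height and intensity must share the same grid")
  p0 <- section[1:2]; p1 <- section[3:4]
  len <- sqrt(sum((p1 - p0)^2))
  if (len <= 0) stop_param("degenerate section")
  n_samples <- n_samples %||% max(3L, ceiling(len / pixel_size) + 1L)
  tvec <- seq(0, 1, length.out = n_samples)
  dir <- (p1 - p0) / len
  nrm <- c(-dir[2], dir[1])
  offs <- (seq_len(width) - (width + 1) / 2) * pixel_size
  hs <- matrix(NA_real_, n_samples, width)
  is <- matrix(NA_real_, n_samples, width)
  for (w in seq_len(width)) {
    px_x <- (p0[1] + tvec * (p1[1] - p0[1]) + offs[w] * nrm[1]) / pixel_size + 0.5
    px_y <- (p0[2] + tvec * (p1[2] - p0[2]) + offs[w] * nrm[2]) / pixel_size + 0.5
    hs[, w] <- bilinear_sample(hmat, px_y, px_x)
    is[, w] <- bilinear_sample(imat, px_y, px_x)
  }
  if (anyNA(hs) || anyNA(is)) {
    bad <- which(rowSums(is.na(hs) | is.na(is)) > 0)
    stop_param("section leaves the valid image area at samples %s",
               paste(utils::head(bad, 5), collapse = ", "))
  }
  hp <- rowMeans(hs); ip <- rowMeans(is)
  mm <- function(v) {
    rg <- range(v)
    if (diff(rg) == 0) list(v = v * 0, zero = TRUE)
    else list(v = (v - rg[1]) / diff(rg), zero = FALSE)
  }
  hn <- mm(hp); iN <- mm(ip)
  structure(list(height = hn$v, intensity = iN$v, height_raw = hp,
                 intensity_raw = ip, s = tvec * len,
                 zero_range = c(height = hn$zero, intensity = iN$zero),
                 endpoints = section, width = width),
            class = "cross_section")
}

#' Pearson correlation of a cross-section's two profiles
#'
#' Standard product-moment correlation of the normalized height and
#' intensity profiles. Constant profiles have no defined correlation: the
#' result is `NA` with `attr(_, "undefined") = TRUE`.
#'
#' @param section a `cross_section` (>= 3 samples).
#' @return scalar r in `[-1, 1]`, or NA (undefined).
#' @export
pearson <- function(section) {
  stopifnot(inherits(section, "cross_section"))
  if (length(section$height) < 3) stop_param("need at least 3 samples")
  if (any(section$zero_range)) {
    r <- NA_real_
    attr(r, "undefined") <- TRUE
    return(r)
  }
  stats::cor(section$height, section$intensity)
}

#' Compare two groups of correlation coefficients (Welch two-sided t-test)
#'
#' By default the r values are Fisher-z transformed (`atanh`) before the
#' unequal-variance t-test, since r is bounded; set `fisher_z = FALSE` for
#' the test on raw r. The Welch statistic and Welch-Satterthwaite degrees
#' of freedom are computed explicitly.
#'
#' @param r_a,r_b numeric vectors of r values (each >= 3, within (-1, 1]).
#' @param fisher_z transform r before testing (default TRUE).
#' @return list(t, dof, p, fisher_z, degenerate).
#' @export
compare_groups <- function(r_a, r_b, fisher_z = TRUE) {
  r_a <- r_a[!is.na(r_a)]; r_b <- r_b[!is.na(r_b)]
  if (length(r_a) < 3 || length(r_b) < 3)
    stop_param("each group needs at least 3 values")
  xa <- if (fisher_z) atanh(pmin(pmax(r_a, -1 + 1e-12), 1 - 1e-12)) else r_a
  xb <- if (fisher_z) atanh(pmin(pmax(r_b, -1 + 1e-12), 1 - 1e-12)) else r_b
  va <- stats::var(xa); vb <- stats::var(xb)
  na <- length(xa); nb <- length(xb)
  if (va == 0 && vb == 0) {
    return(list(t = if (mean(xa) == mean(xb)) 0 else Inf, dof = NA_real_,
                p = if (mean(xa) == mean(xb)) 1 else 0,
                fisher_z = fisher_z, degenerate = TRUE))
  }
  se2 <- va / na + vb / nb
  tstat <- (mean(xa) - mean(xb)) / sqrt(se2)
  dof <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df = dof)
  list(t = tstat, dof = dof, p = p, fisher_z = fisher_z, degenerate = FALSE)
}
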