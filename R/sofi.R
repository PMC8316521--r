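# Cross-cumulant SOFI engine.
#
# Order-n cumulants of the zero-mean pixel fluctuations are computed for a
# canonical combination of n real pixels per virtual pixel of the
# n-times-refined grid. The combination for refined index u (0-based) along
# one axis is: q = u %/% n, r = u %% n, pixels = (n - r) copies of q and r
# copies of q + 1 -- the nearest real pixels whose centroid lands exactly on
# the virtual position. Axes (and, in 3D, planes) are paired slot-by-slot
# with all per-axis offset lists sorted ascending; this fixes a single
# deterministic scheme so outputs are reproducible bit for bit.

axis_offsets <- function(n, r) c(rep(0L, n - r), rep(1L, r))

#' Joint cumulant of k simultaneous time series
#'
#' Computes the order-n joint cumulant (all time lags zero) of the
#' zero-mean fluctuations of `n` series: `k2 = <dF1 dF2>`,
#' `k3 = <dF1 dF2 dF3>`,
#' `k4 = <dF1 dF2 dF3 dF4> - <dF1 dF2><dF3 dF4> - <dF1 dF3><dF2 dF4>
#'  - <dF1 dF4><dF2 dF3>`.
#'
#' @param traces numeric matrix `T x k` with `k == order`.
#' @param order cumulant order, 2, 3 or 4.
#' @return scalar cumulant value (time-average estimate).
#' @export
cumulant_timeseries <- function(traces, order) {
  traces <- as.matrix(traces)
  if (!order %in% 2:4) stop_param("order must be 2, 3 or 4")
  if (ncol(traces) != order)
    stop_param("traces must have exactly %d columns for order %d", order, order)
  if (nrow(traces) < 10) stop_param("need at least 10 time points")
  d <- sweep(traces, 2, colMeans(traces))
  switch(as.character(order),
    "2" = mean(d[, 1] * d[, 2]),
    "3" = mean(d[, 1] * d[, 2] * d[, 3]),
    "4" = mean(d[, 1] * d[, 2] * d[, 3] * d[, 4]) -
      mean(d[, 1] * d[, 2]) * mean(d[, 3] * d[, 4]) -
      mean(d[, 1] * d[, 3]) * mean(d[, 2] * d[, 4]) -
      mean(d[, 1] * d[, 4]) * mean(d[, 2] * d[, 3]))
}

# order-n cumulant of n mean-subtracted T x a x b arrays, elementwise over
# (a, b); returns an a x b matrix.
k_stat_arrays <- function(As, order) {
  tm <- function(A) colMeans(A, dims = 1)
  if (order == 2) return(tm(As[[1]] * As[[2]]))
  if (order == 3) return(tm(As[[1]] * As[[2]] * As[[3]]))
  tm(As[[1]] * As[[2]] * As[[3]] * As[[4]]) -
    tm(As[[1]] * As[[2]]) * tm(As[[3]] * As[[4]]) -
    tm(As[[1]] * As[[3]]) * tm(As[[2]] * As[[4]]) -
    tm(As[[1]] * As[[4]]) * tm(As[[2]] * As[[3]])
}

# Distance factor of a pixel combination under a Gaussian PSF of width
# sigma: D = prod_{i<j} exp(-|r_i - r_j|^2 / (2 n sigma^2)), positions in nm.
distance_factor <- function(coords, order, sigma) {
  n <- nrow(coords)
  D <- 1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d2 <- sum((coords[i, ] - coords[j, ])^2)
    D <- D * exp(-d2 / (2 * order * sigma^2))
  }
  D
}

new_cumulant_image <- function(values, mask, order, grid_spacing,
                               n_frames_used, pixel_size_in,
                               plane_spacing_out = NULL, flattened = FALSE,
                               sigma = NULL, linearized = FALSE) {
  structure(list(values = values, mask = mask, order = as.integer(order),
                 grid_spacing = grid_spacing,
                 plane_spacing_out = plane_spacing_out,
                 n_frames_used = as.integer(n_frames_used),
                 pixel_size_in = pixel_size_in, flattened = flattened,
                 sigma = sigma, linearized = linearized),
            class = "cumulant_image")
}

#' @export
print.cumulant_image <- function(x, ...) {
  d <- dim(x$values)
  dims <- paste(d, collapse = "x")
  cat(sprintf(
    "<cumulant_image> order %d, %s on %.3g nm grid%s, %d frames%s%s\n",
    x$order, dims, x$grid_spacing,
    if (!is.null(x$plane_spacing_out))
      sprintf(" (plane spacing %.4g nm)", x$plane_spacing_out) else "",
    x$n_frames_used,
    if (x$flattened) ", flattened" else "",
    if (x$linearized) ", linearized" else ""))
  invisible(x)
}

#' 2D cross-cumulant SOFI image
#'
#' Computes the order-n SOFI image of a single-plane movie on the
#' n-times-refined virtual-pixel grid. Virtual pixels whose canonical
#' combination would need pixels outside the detector (refined indices
#' beyond `n*(Y-1)` on either axis) are masked invalid rather than
#' zero-filled; the output is padded to `n*Y x n*X` with that mask.
#'
#' @param movie a single-plane `blink_movie`.
#' @param order cumulant order, 2, 3 or 4.
#' @param flatten divide each virtual pixel by its combination's distance
#'   factor (see [flatten()]).
#' @param sigma PSF sigma (nm) used for the distance factor; defaults to
#'   the movie's optics metadata.
#' @return A [`cumulant_image`][sofi2d] with grid spacing `pixel_size/n`.
#' @export
sofi2d <- function(movie, order, flatten = FALSE, sigma = NULL) {
  stopifnot(inherits(movie, "blink_movie"))
  if (!order %in% 2:4) stop_param("order must be 2, 3 or 4")
  if (is_multiplane(movie))
    stop_param("sofi2d expects a single-plane movie; use sofi3d")
  X <- movie$data
  nT <- dim(X)[1]; Y <- dim(X)[2]; Xn <- dim(X)[3]
  if (nT < 100) warning("fewer than 100 frames: cumulant estimates will be noisy")
  sigma <- sigma %||% movie$optics$sigma0
  if (flatten && is.null(sigma))
    stop_param("flattening requires a PSF sigma")
  n <- as.integer(order)
  px <- movie$optics$pixel_size
  d <- sweep(X, c(2, 3), colMeans(X, dims = 1))
  out <- matrix(0, n * Y, n * Xn)
  mask <- matrix(FALSE, n * Y, n * Xn)
  for (ry in 0:(n - 1)) for (rx in 0:(n - 1)) {
    oy <- axis_offsets(n, ry); ox <- axis_offsets(n, rx)
    my <- max(oy); mx <- max(ox)
    yb <- seq_len(Y - my); xb <- seq_len(Xn - mx)
    As <- lapply(seq_len(n), function(i)
      d[, yb + oy[i], xb + ox[i], drop = FALSE])
    K <- k_stat_arrays(As, n)
    if (flatten) {
      Dp <- distance_factor(cbind(oy * px, ox * px), n, sigma)
      K <- K / Dp
    }
    rows <- seq(ry + 1L, by = n, length.out = length(yb))
    cols <- seq(rx + 1L, by = n, length.out = length(xb))
    out[rows, cols] <- K
    mask[rows, cols] <- TRUE
  }
  new_cumulant_image(out, mask, n, grid_spacing = px / n,
                     n_frames_used = nT, pixel_size_in = px,
                     flattened = flatten, sigma = sigma)
}

#' Multiplane 3D cross-cumulant SOFI volume
#'
#' Extends the cross-cumulant scheme axially: virtual plane j (0-based,
#' j in 0..n*(P-1)) draws its combination from the two adjacent physical
#' planes `j %/% n` and `j %/% n + 1` using the same nearest-neighbour
#' offset rule as the lateral axes, so P physical planes produce
#' `n*(P-1) + 1` output planes spaced `plane_spacing/n` apart. Lateral
#' treatment is identical to [sofi2d()].
#'
#' @param movie a multiplane `blink_movie` (`T x P x Y x X`).
#' @param order cumulant order, 2, 3 or 4.
#' @inheritParams sofi2d
#' @return A `cumulant_image` whose `values` is an array
#'   `(n*(P-1)+1) x n*Y x n*X`, with `plane_spacing_out = plane_spacing/n`.
#' @export
sofi3d <- function(movie, order, flatten = FALSE, sigma = NULL) {
  stopifnot(inherits(movie, "blink_movie"))
  if (!order %in% 2:4) stop_param("order must be 2, 3 or 4")
  if (!is_multiplane(movie))
    stop_param("movie has a single plane; use sofi2d for 2D data")
  X <- movie$data
  nT <- dim(X)[1]; P <- dim(X)[2]; Y <- dim(X)[3]; Xn <- dim(X)[4]
  if (P < 2) stop_param("need at least 2 physical planes")
  n <- as.integer(order)
  px <- movie$optics$pixel_size
  dz <- movie$optics$plane_spacing
  sigma <- sigma %||% movie$optics$sigma0
  d <- sweep(X, c(2, 3, 4), colMeans(X, dims = 1))
  n_out <- n * (P - 1L) + 1L
  out <- array(0, c(n_out, n * Y, n * Xn))
  mask <- array(FALSE, c(n_out, n * Y, n * Xn))
  for (j in 0:(n_out - 1L)) {
    qp <- j %/% n; rp <- j %% n
    op <- axis_offsets(n, rp)
    for (ry in 0:(n - 1)) for (rx in 0:(n - 1)) {
      oy <- axis_offsets(n, ry); ox <- axis_offsets(n, rx)
      my <- max(oy); mx <- max(ox)
      yb <- seq_len(Y - my); xb <- seq_len(Xn - mx)
      As <- lapply(seq_len(n), function(i) {
        A <- d[, qp + op[i] + 1L, yb + oy[i], xb + ox[i], drop = FALSE]
        array(A, dim(A)[-2])
      })
      K <- k_stat_arrays(As, n)
      if (flatten) {
        # lateral distances only: the axial brightness falloff follows the
        # (non-Gaussian) defocus law, so only the in-plane checkerboard is
        # corrected by the Gaussian distance factor
        Dp <- distance_factor(cbind(oy * px, ox * px), n, sigma)
        K <- K / Dp
      }
      rows <- seq(ry + 1L, by = n, length.out = length(yb))
      cols <- seq(rx + 1L, by = n, length.out = length(xb))
      out[j + 1L, rows, cols] <- K
      mask[j + 1L, rows, cols] <- TRUE
    }
  }
  new_cumulant_image(out, mask, n, grid_spacing = px / n,
                     n_frames_used = nT, pixel_size_in = px,
                     plane_spacing_out = dz / n,
                     flattened = flatten, sigma = sigma)
}

#' Flatten a cumulant image (distance-factor correction)
#'
#' Cross-cumulants are attenuated relative to auto-cumulants by the
#' distance factor `D = prod_{i<j} exp(-|r_i - r_j|^2 / (2 n sigma^2))`
#' of their pixel combination, which imprints an `n x n` checkerboard on
#' the virtual-pixel grid. Flattening divides each virtual pixel by its
#' combination's D. Auto-cumulant pixels (all pairwise distances zero)
#' have D = 1 and are unchanged. For multiplane volumes only the lateral
#' (in-plane) distances enter D: the axial falloff between planes follows
#' the defocus law of the optics rather than a Gaussian in z, so the
#' axial weighting is deliberately left untouched.
#'
#' @param image an unflattened `cumulant_image`.
#' @param sigma PSF sigma in nm; defaults to the value stored at
#'   computation time.
#' @return the flattened `cumulant_image`.
#' @export
flatten <- function(image, sigma = NULL) {
  stopifnot(inherits(image, "cumulant_image"))
  if (image$flattened) stop_param("image is already flattened")
  sigma <- sigma %||% image$sigma
  if (is.null(sigma)) stop_param("flattening requires a PSF sigma")
  n <- image$order
  px <- image$pixel_size_in
  v <- image$values
  if (is.matrix(v)) {
    for (ry in 0:(n - 1)) for (rx in 0:(n - 1)) {
      Dp <- distance_factor(cbind(axis_offsets(n, ry) * px,
                                  axis_offsets(n, rx) * px), n, sigma)
      rows <- seq(ry + 1L, nrow(v), by = n)
      cols <- seq(rx + 1L, ncol(v), by = n)
      v[rows, cols] <- v[rows, cols] / Dp
    }
  } else {
    for (ry in 0:(n - 1)) for (rx in 0:(n - 1)) {
      Dp <- distance_factor(cbind(axis_offsets(n, ry) * px,
                                  axis_offsets(n, rx) * px), n, sigma)
      rows <- seq(ry + 1L, dim(v)[2], by = n)
      cols <- seq(rx + 1L, dim(v)[3], by = n)
      v[, rows, cols] <- v[, rows, cols] / Dp
    }
  }
  image$values <- v
  image$flattened <- TRUE
  image$sigma <- sigma
  image
}

#' Valid (unmasked) sub-image of a cumulant image
#'
#' Returns the interior-complete region of a 2D cumulant image, i.e. the
#' `(n*Y - (n-1)) x (n*X - (n-1))` block for which every virtual pixel has
#' a valid combination.
#' @param image a 2D `cumulant_image`.
#' @export
valid_region <- function(image) {
  stopifnot(inherits(image, "cumulant_image"), is.matrix(image$values))
  n <- image$order
  image$values[seq_len(nrow(image$values) - (n - 1L)),
               seq_len(ncol(image$values) - (n - 1L))]
}
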