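# Internal numerical helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# `seed = NULL` leaves the global RNG stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 1D Gaussian kernel, truncated at `trunc` sigmas, normalized to sum 1.
gauss_kernel1d <- function(sigma_px, trunc = 4) {
  if (sigma_px <= 0) return(1)
  r <- max(1L, ceiling(trunc * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k / sum(k)
}

# Separable Gaussian blur with replicate (nearest-edge) padding.
gauss_blur <- function(mat, sigma_px, trunc = 4) {
  if (sigma_px <= 0) return(mat)
  k <- gauss_kernel1d(sigma_px, trunc)
  r <- (length(k) - 1L) / 2L
  conv_axis <- function(m) {
    n <- nrow(m)
    pad <- m[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * pad[seq_len(n) + (j - 1L), , drop = FALSE]
    out
  }
  t(conv_axis(t(conv_axis(mat))))
}

# Circular 2D convolution via FFT with a centered kernel (kernel origin at
# its middle element). Used where exact flux conservation matters (LR).
fft_convolve2 <- function(img, kernel) {
  ny <- nrow(img); nx <- ncol(img)
  kb <- matrix(0, ny, nx)
  ky <- nrow(kernel); kx <- ncol(kernel)
  stopifnot(ky <= ny, kx <= nx)
  kb[seq_len(ky), seq_len(kx)] <- kernel
  # shift kernel center to (1,1)
  cy <- (ky + 1L) %/% 2L; cx <- (kx + 1L) %/% 2L
  kb <- kb[c(cy:ny, seq_len(cy - 1L)), c(cx:nx, seq_len(cx - 1L))]
  Re(fft(fft(img) * fft(kb), inverse = TRUE)) / (ny * nx)
}

# Least-squares isotropic 2D Gaussian fit (amplitude, center, sigma, offset).
# Coordinates are in physical units: pixel i (row) center at (i - 0.5)*spacing.
fit_gaussian2d <- function(img, spacing = 1) {
  img <- as.matrix(img)
  ny <- nrow(img); nx <- ncol(img)
  yc <- (seq_len(ny) - 0.5) * spacing
  xc <- (seq_len(nx) - 0.5) * spacing
  w <- pmax(img - stats::median(img), 0)
  if (sum(w) <= 0) stop("fit_gaussian2d: image has no positive excursion")
  y0 <- sum(w * yc) / sum(w)
  x0 <- sum(sweep(w, 2, xc, `*`)) / sum(w)
  s0 <- sqrt(sum(w * outer(yc - y0, rep(1, nx))^2 + sweep(w, 2, (xc - x0)^2, `*`)) /
               (2 * sum(w)))
  par0 <- c(A = max(img), y0 = y0, x0 = x0, logs = log(max(s0, spacing / 4)),
            off = stats::median(img))
  yy <- matrix(yc, ny, nx)
  xx <- matrix(xc, ny, nx, byrow = TRUE)
  obj <- function(p) {
    s <- exp(p[4])
    m <- p[1] * exp(-((yy - p[2])^2 + (xx - p[3])^2) / (2 * s^2)) + p[5]
    sum((m - img)^2)
  }
  fit <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(amplitude = unname(fit$par[1]), y0 = unname(fit$par[2]),
       x0 = unname(fit$par[3]), sigma = unname(exp(fit$par[4])),
       offset = unname(fit$par[5]), sse = fit$value)
}

# Bilinear sampling of matrix `m` at fractional (row, col) positions given in
# pixel units where pixel i has center i (1-based). Out-of-range -> NA.
bilinear_sample <- function(m, row, col) {
  ny <- nrow(m); nx <- ncol(m)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= ny & c0 + 1 <= nx
  # clamp exact upper edge
  edge <- row == ny & col >= 1 & col <= nx
  out <- rep(NA_real_, length(row))
  idx <- function(r, c) (c - 1L) * ny + r
  i <- which(ok)
  if (length(i)) {
    v00 <- m[idx(r0[i], c0[i])]; v10 <- m[idx(r0[i] + 1L, c0[i])]
    v01 <- m[idx(r0[i], c0[i] + 1L)]; v11 <- m[idx(r0[i] + 1L, c0[i] + 1L)]
    out[i] <- v00 * (1 - fr[i]) * (1 - fc[i]) + v10 * fr[i] * (1 - fc[i]) +
      v01 * (1 - fr[i]) * fc[i] + v11 * fr[i] * fc[i]
  }
  # points exactly on the last row/col line
  j <- which(!ok & row >= 1 & col >= 1 & row <= ny & col <= nx)
  if (length(j)) {
    rj <- pmin(row[j], ny - 1e-9); cj <- pmin(col[j], nx - 1e-9)
    out[j] <- bilinear_sample(m, rj, cj)
  }
  out
}

# Translate an image by (dy, dx) pixels with bilinear interpolation;
# out-of-field samples become `fill`.
translate_bilinear <- function(m, dy, dx, fill = 0) {
  ny <- nrow(m); nx <- ncol(m)
  rows <- matrix(seq_len(ny), ny, nx) - dy
  cols <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - dx
  v <- bilinear_sample(m, as.vector(rows), as.vector(cols))
  v[is.na(v)] <- fill
  matrix(v, ny, nx)
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)
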