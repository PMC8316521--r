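# Stack preparation ahead of cumulant analysis: frame exclusion, bleaching
# lifetime estimation, cross-correlation drift correction between
# sub-sequences.

#' Drop the first frames of a movie
#'
#' Used to discard the initial frames of an acquisition (e.g. the rapid
#' intensity transient after photo-activation) before cumulant analysis.
#' The exclusion is recorded in the movie metadata and composes
#' additively.
#'
#' @param movie a `blink_movie`.
#' @param n_skip number of leading frames to drop; must leave >= 1 frame.
#' @return the trimmed `blink_movie`.
#' @export
exclude_frames <- function(movie, n_skip) {
  stopifnot(inherits(movie, "blink_movie"))
  n_skip <- as.integer(n_skip)
  if (n_skip < 0) stop_param("n_skip must be >= 0")
  nT <- n_frames(movie)
  if (n_skip >= nT)
    stop_param("n_skip (%d) must be smaller than the frame count (%d)", n_skip, nT)
  if (n_skip == 0L) return(movie)
  keep <- (n_skip + 1L):nT
  movie$data <- if (is_multiplane(movie)) movie$data[keep, , , , drop = FALSE]
  else movie$data[keep, , , drop = FALSE]
  movie$meta$frames_excluded <- (movie$meta$frames_excluded %||% 0L) + n_skip
  movie
}

#' Fit a single-exponential photobleaching lifetime
#'
#' Least-squares fit of the total frame intensity
#' `I(t) = A exp(-t / lambda) + c`, with t in seconds from the exposure
#' metadata. A non-decaying trace is reported with `lifetime = Inf`
#' (flag, not an error) since it carries no bleaching information.
#'
#' @param movie a `blink_movie` with at least 10 frames.
#' @return object of class `bleach_fit`: list(lifetime, amplitude, offset,
#'   rms, infinite).
#' @export
fit_bleaching <- function(movie) {
  stopifnot(inherits(movie, "blink_movie"))
  nT <- n_frames(movie)
  if (nT < 10) stop_param("need at least 10 frames to fit bleaching")
  I <- if (is_multiplane(movie)) apply(movie$data, 1, sum) else
    apply(movie$data, 1, sum)
  t <- (seq_len(nT) - 1) * movie$exposure
  # decay present? compare first and last fifths
  k <- max(2L, nT %/% 5L)
  if (mean(I[seq_len(k)]) <= mean(I[(nT - k + 1L):nT]) * (1 + 1e-12) ||
      stats::var(I) == 0) {
    return(structure(list(lifetime = Inf, amplitude = 0, offset = mean(I),
                          rms = stats::sd(I), infinite = TRUE),
                     class = "bleach_fit"))
  }
  # log-linear start values, then Gauss-Newton refinement (optim fallback)
  c0 <- min(I) * 0.9
  lam0 <- tryCatch({
    fitl <- stats::lm(log(pmax(I - c0, max(I) * 1e-6)) ~ t)
    max(-1 / stats::coef(fitl)[2], t[2])
  }, error = function(e) diff(range(t)))
  A0 <- max(I[1] - c0, 1e-9)
  dfit <- data.frame(I = I, t = t)
  nfit <- tryCatch(suppressWarnings(
    stats::nls(I ~ A * exp(-t / lam) + cc, data = dfit,
               start = list(A = A0, lam = lam0, cc = c0),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(nfit)) {
    cf <- stats::coef(nfit)
    A <- cf[["A"]]; lam <- cf[["lam"]]; cc <- cf[["cc"]]
    sse <- sum(stats::resid(nfit)^2)
  } else {
    obj <- function(p) {
      sum((exp(p[1]) * exp(-t / exp(p[2])) + p[3] - I)^2)
    }
    fit <- stats::optim(c(log(A0), log(lam0), c0), obj, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14))
    A <- exp(fit$par[1]); lam <- exp(fit$par[2]); cc <- fit$par[3]
    sse <- fit$value
  }
  if (!is.finite(lam) || lam <= 0) lam <- Inf
  # a fitted lifetime far beyond the trace duration is indistinguishable
  # from no decay: report the infinite-lifetime flag
  inf_flag <- !is.finite(lam) || lam > 1e4 * diff(range(t))
  structure(list(lifetime = if (inf_flag) Inf else lam, amplitude = A,
                 offset = cc, rms = sqrt(sse / nT),
                 infinite = inf_flag),
            class = "bleach_fit")
}

#' @export
print.bleach_fit <- function(x, ...) {
  if (x$infinite) cat("<bleach_fit> no measurable decay (lifetime = Inf)\n")
  else cat(sprintf("<bleach_fit> lifetime %.3g s, amplitude %.3g, offset %.3g, rms %.3g\n",
                   x$lifetime, x$amplitude, x$offset, x$rms))
  invisible(x)
}

# cross-correlation peak between two images with 3-point quadratic
# sub-pixel refinement per axis; returns c(dy, dx) such that `b` is `a`
# shifted by (dy, dx). Also returns the normalized peak height.
xcorr_shift <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  ny <- nrow(a); nx <- ncol(a)
  cc <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE)) / (ny * nx)
  norm <- sqrt(sum(a^2) * sum(b^2))
  peak_val <- max(cc) / max(norm, .Machine$double.eps)
  i <- which.max(cc)
  py <- (i - 1L) %% ny + 1L
  px <- (i - 1L) %/% ny + 1L
  wrap <- function(idx, n) ifelse(idx > n / 2, idx - n, idx)
  sub <- function(cm, p, n, fixed, along) {
    get <- function(off) {
      q <- (p - 1L + off) %% n + 1L
      if (along == "y") cm[q, fixed] else cm[fixed, q]
    }
    ym <- get(-1L); y0 <- get(0L); yp <- get(1L)
    den <- ym - 2 * y0 + yp
    if (den == 0) 0 else max(min(0.5 * (ym - yp) / den, 0.5), -0.5)
  }
  dy <- wrap(py, ny) - 1 + sub(cc, py, ny, px, "y")
  dx <- wrap(px, nx) - 1 + sub(cc, px, nx, py, "x")
  list(shift = c(dy, dx), peak = peak_val)
}

#' Estimate lateral drift from cumulant sub-sequences
#'
#' Splits the movie into consecutive blocks of `block_len` frames (a
#' trailing partial block is dropped), computes a 2nd-order cumulant image
#' per block, and locates each block's translation against the first block
#' by the cross-correlation peak with 3-point quadratic sub-pixel
#' refinement. Per-frame shifts are interpolated linearly between block
#' centers (constant extrapolation at the ends). Blocks whose normalized
#' correlation peak falls below `peak_threshold` are considered
#' featureless: a warning is issued and the block's shift set to zero.
#'
#' @param movie a single-plane `blink_movie` with `T >= 2 * block_len`.
#' @param block_len frames per sub-sequence (default 500).
#' @param peak_threshold minimum normalized correlation peak.
#' @return object of class `drift_track`: list(blocks = data.frame(block,
#'   frame_center, dx, dy), frame_shifts = data.frame(frame, dx, dy),
#'   block_len).
#' @export
estimate_drift <- function(movie, block_len = 500, peak_threshold = 0.05) {
  stopifnot(inherits(movie, "blink_movie"))
  if (is_multiplane(movie))
    stop_param("drift estimation operates on single-plane movies")
  nT <- n_frames(movie)
  if (nT < 2 * block_len)
    stop_param("need at least 2 blocks (T >= %d)", 2 * block_len)
  n_blocks <- nT %/% block_len
  imgs <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1L) * block_len + 1L):(b * block_len)
    sub <- movie
    sub$data <- movie$data[idx, , , drop = FALSE]
    ci <- sofi2d(sub, order = 2)
    imgs[[b]] <- valid_region(ci)
  }
  shifts <- matrix(0, n_blocks, 2)
  for (b in seq_len(n_blocks)[-1]) {
    xc <- xcorr_shift(imgs[[1]], imgs[[b]])
    if (xc$peak < peak_threshold) {
      warning(sprintf("block %d: correlation peak %.3g below threshold; shift set to 0",
                      b, xc$peak))
    } else {
      # cumulant grid is 2x refined -> convert to camera pixels
      shifts[b, ] <- xc$shift / 2
    }
  }
  centers <- (seq_len(n_blocks) - 0.5) * block_len
  frames <- seq_len(nT)
  interp <- function(v) stats::approx(centers, v, xout = frames, rule = 2)$y
  track <- structure(list(
    blocks = data.frame(block = seq_len(n_blocks), frame_center = centers,
                        dy = shifts[, 1], dx = shifts[, 2]),
    frame_shifts = data.frame(frame = frames,
                              dy = if (n_blocks > 1) interp(shifts[, 1]) else 0,
                              dx = if (n_blocks > 1) interp(shifts[, 2]) else 0),
    block_len = as.integer(block_len)), class = "drift_track")
  track
}

#' Apply (or inject) a drift track
#'
#' Translates each frame by minus its tracked shift with bilinear
#' interpolation; pixels sampled from outside the field are zero-filled.
#' Applying the negated track of a known drift injects that drift, which
#' is how tests construct movies with ground-truth motion.
#'
#' @param movie single-plane `blink_movie`.
#' @param track a `drift_track`, or a data.frame(frame, dy, dx) covering
#'   every frame.
#' @return the corrected `blink_movie`.
#' @export
apply_drift <- function(movie, track) {
  stopifnot(inherits(movie, "blink_movie"))
  fs <- if (inherits(track, "drift_track")) track$frame_shifts else track
  nT <- n_frames(movie)
  if (nrow(fs) < nT) stop_param("track covers %d of %d frames", nrow(fs), nT)
  for (t in seq_len(nT)) {
    if (fs$dy[t] == 0 && fs$dx[t] == 0) next
    movie$data[t, , ] <- translate_bilinear(movie$data[t, , ],
                                            -fs$dy[t], -fs$dx[t])
  }
  movie$meta$drift_corrected <- TRUE
  movie
}
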