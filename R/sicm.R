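# Hopping-mode scanning ion-conductance topography: a simulated nanopipette
# approaches the surface vertically at every pixel until the normalized
# ionic current drops to the setpoint, and the detection height (minus the
# constant setpoint gap) is recorded. Processing utilities: least-squares
# plane leveling and spatial band-pass filtering.

#' Nanopipette sensing model
#'
#' The normalized ionic current follows `I(z)/I_inf = 1 / (1 + c_s r_p / z)`
#' for tip-surface gap z: it rises monotonically to the bulk value as the
#' pipette retracts. With the default `c_s = 0.01` the current has dropped
#' by 1% at a gap of about one pipette radius, reflecting that the sensing
#' distance tracks the pore size.
#'
#' @param radius pipette (pore) radius r_p in nm; typical 10-100.
#' @param c_s dimensionless sensing coefficient (decay scale `c_s * r_p`).
#' @return object of class `pipette_model`.
#' @export
pipette_model <- function(radius = 50, c_s = 0.01) {
  if (radius <= 0) stop_param("radius must be > 0")
  if (c_s <= 0) stop_param("c_s must be > 0")
  structure(list(radius = radius, c_s = c_s, I_inf = 1.0),
            class = "pipette_model")
}

#' Hopping-scan configuration
#'
#' @param setpoint fractional normalized current at which the surface is
#'   declared detected (0 < setpoint < 1; 0.99 is the usual operating point).
#' @param hopping_height retract height above the highest surface point, nm.
#' @param pixel_rate pixels per second (default 200).
#' @param pixels integer c(Y, X) scan size.
#' @param pixel_size nm per pixel.
#' @export
scan_config <- function(setpoint = 0.99, hopping_height = 5000,
                        pixel_rate = 200, pixels = c(128, 128),
                        pixel_size = 78) {
  if (setpoint <= 0 || setpoint >= 1) stop_param("setpoint must be in (0, 1)")
  if (hopping_height <= 0) stop_param("hopping_height must be > 0")
  if (pixel_rate <= 0) stop_param("pixel_rate must be > 0")
  structure(list(setpoint = setpoint, hopping_height = hopping_height,
                 pixel_rate = pixel_rate, pixels = as.integer(pixels),
                 pixel_size = pixel_size), class = "scan_config")
}

#' Normalized current versus tip-surface gap
#'
#' @param z gap in nm (> 0), vectorized.
#' @param pipette a [pipette_model()].
#' @return normalized current I(z)/I_inf, strictly increasing to 1.
#' @export
current_distance <- function(z, pipette) {
  stopifnot(inherits(pipette, "pipette_model"))
  if (any(z <= 0)) stop_param("gap z must be > 0")
  1 / (1 + pipette$c_s * pipette$radius / z)
}

#' Detection gap for a current setpoint
#'
#' Solves `I(z)/I_inf = setpoint` for the gap: `z* = c_s r_p s / (1 - s)`.
#' At the 99% setpoint this is `99 c_s r_p`.
#' @inheritParams current_distance
#' @param setpoint fractional current in (0, 1).
#' @export
detection_gap <- function(pipette, setpoint) {
  stopifnot(inherits(pipette, "pipette_model"))
  if (setpoint <= 0 || setpoint >= 1) stop_param("setpoint must be in (0, 1)")
  pipette$c_s * pipette$radius * setpoint / (1 - setpoint)
}

new_height_map <- function(height, pixel_size, valid = NULL, leveled = FALSE,
                           meta = list()) {
  structure(list(height = height, pixel_size = pixel_size,
                 valid = valid %||% matrix(TRUE, nrow(height), ncol(height)),
                 leveled = leveled, meta = meta),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %dx%d px at %g nm/px%s, range %.1f..%.1f nm, %d invalid px\n",
              nrow(x$height), ncol(x$height), x$pixel_size,
              if (x$leveled) " (leveled)" else "",
              min(x$height[x$valid]), max(x$height[x$valid]), sum(!x$valid)))
  invisible(x)
}

#' Hopping-mode scan of a ground-truth topography
#'
#' At each pixel the pipette descends from `max(surface) + hopping_height`
#' in steps of `step` nm; the surface sensed under the tip is the mean
#' height within the aperture footprint, a uniform disk of radius
#' `1.5 * r_p` (which reproduces the ~3 r_p lateral resolution rule).
#' Detection occurs when the normalized current first falls to the
#' setpoint, i.e. when the gap reaches `z* = detection_gap(...)`; the
#' recorded height is the detection z minus the constant z*, plus Gaussian
#' axial noise. Scan time metadata is `pixels / pixel_rate` seconds
#' (ideal, no overhead).
#'
#' @param topo a [simulate_topography()] result, or a `height_map` used as
#'   ground truth (its pixel grid defines the scan).
#' @param pipette a [pipette_model()].
#' @param config a [scan_config()]; `pixels`/`pixel_size` are taken from
#'   the topography grid.
#' @param noise_sigma axial Gaussian noise, nm (default 1).
#' @param seed RNG seed for the noise.
#' @param step descent step, nm (<= 1 so axial quantization stays well
#'   below the ~10 nm axial resolution scale; default 0.1).
#' @return a `height_map` with scan metadata (`scan_time_s`, config).
#' @export
hop_scan <- function(topo, pipette, config, noise_sigma = 1, seed = NULL,
                     step = 0.1) {
  stopifnot(inherits(pipette, "pipette_model"), inherits(config, "scan_config"))
  h_true <- if (inherits(topo, "topography")) topo$height else topo$height
  px <- if (inherits(topo, "topography")) topo$pixel_size else topo$pixel_size
  if (config$hopping_height <= diff(range(h_true)))
    stop_param("hopping_height must exceed the surface height range")
  if (step <= 0 || step > 1) stop_param("descent step must be in (0, 1] nm")
  # aperture footprint: mean over a uniform disk of radius 1.5 r_p
  r_px <- 1.5 * pipette$radius / px
  surf <- h_true
  if (r_px >= 0.5) {
    r_int <- ceiling(r_px)
    d2 <- outer((-r_int:r_int)^2, (-r_int:r_int)^2, `+`)
    disk <- (d2 <= r_px^2) * 1
    disk <- disk / sum(disk)
    # replicate-padded convolution
    ny <- nrow(h_true); nx <- ncol(h_true)
    padidx <- function(n, r) c(rep(1L, r), seq_len(n), rep(n, r))
    hp <- h_true[padidx(ny, r_int), padidx(nx, r_int)]
    surf <- matrix(0, ny, nx)
    for (i in seq_len(2 * r_int + 1)) for (j in seq_len(2 * r_int + 1)) {
      if (disk[i, j] == 0) next
      surf <- surf + disk[i, j] *
        hp[(i - 1L) + seq_len(ny), (j - 1L) + seq_len(nx)]
    }
  }
  zstar <- detection_gap(pipette, config$setpoint)
  hop_top <- max(h_true) + config$hopping_height
  # quasi-static descent: first step position with gap <= z*
  n_steps <- ceiling((hop_top - (surf + zstar)) / step)
  detected <- n_steps >= 0 & (hop_top - n_steps * step) > 0
  z_detect <- hop_top - n_steps * step
  height <- z_detect - zstar
  if (noise_sigma > 0)
    height <- height + with_seed(seed,
      matrix(stats::rnorm(length(height), 0, noise_sigma),
             nrow(height), ncol(height)))
  height[!detected] <- NA_real_
  new_height_map(height, px, valid = detected,
                 meta = list(scan_time_s = length(height) / config$pixel_rate,
                             config = config, pipette = pipette,
                             noise_sigma = noise_sigma, step = step,
                             source = "hop_scan"))
}

#' Subtract the least-squares mean plane
#'
#' Fits `h = a x + b y + c` over the valid pixels and subtracts the plane
#' everywhere. Idempotent up to floating-point round-off; an exact plane
#' input maps to zero.
#'
#' @param map a `height_map` with at least 3 valid pixels.
#' @return the leveled `height_map` (`leveled = TRUE`).
#' @export
level_plane <- function(map) {
  stopifnot(inherits(map, "height_map"))
  ok <- map$valid & is.finite(map$height)
  if (sum(ok) < 3) stop_param("need at least 3 valid pixels to level")
  ny <- nrow(map$height); nx <- ncol(map$height)
  yy <- matrix(seq_len(ny), ny, nx); xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  X <- cbind(1, xx[ok], yy[ok])
  beta <- qr.coef(qr(X), map$height[ok])
  plane <- beta[1] + beta[2] * xx + beta[3] * yy
  map$height <- map$height - plane
  map$leveled <- TRUE
  map
}

#' Spatial band-pass filter (difference of Gaussians)
#'
#' Passes feature wavelengths between `high_cut` and `low_cut` nm by
#' subtracting a wide Gaussian blur from a narrow one (blur sigma =
#' wavelength / 4, replicate-padded separable convolution). The output is
#' forced to zero mean. Used to highlight sub-micrometre membrane
#' protrusions (microvilli) on top of the cell body.
#'
#' @param map a `height_map`.
#' @param low_cut longest passed wavelength, nm.
#' @param high_cut shortest passed wavelength, nm; requires
#'   `low_cut > high_cut > 2 * pixel_size`.
#' @return filtered, zero-mean `height_map`.
#' @export
bandpass <- function(map, low_cut, high_cut) {
  stopifnot(inherits(map, "height_map"))
  if (!(low_cut > high_cut)) stop_param("low_cut must exceed high_cut")
  if (!(high_cut > 2 * map$pixel_size))
    stop_param("high_cut must exceed 2 pixels (%g nm)", 2 * map$pixel_size)
  h <- map$height
  h[!map$valid] <- mean(h[map$valid])
  s_hi <- high_cut / 4 / map$pixel_size
  s_lo <- low_cut / 4 / map$pixel_size
  out <- gauss_blur(h, s_hi) - gauss_blur(h, s_lo)
  out <- out - mean(out)
  map$height <- out
  map$leveled <- TRUE
  map$meta$bandpass <- c(low_cut = low_cut, high_cut = high_cut)
  map
}
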