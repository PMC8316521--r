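#' Simulate a cell-like ground-truth topography
#'
#' Builds a surface (nm) as the sum of a smooth micrometre-scale dome (the
#' cell body), Gaussian bumps emulating microvilli (sub-micrometre width,
#' 100-300 nm amplitude), and elongated Gaussian ridges emulating
#' filopodia. Every feature is recorded in `feature_truth` so downstream
#' recovery tests have an exact oracle.
#'
#' @param shape integer c(Y, X) in pixels; at least 64 x 64.
#' @param pixel_size nm per pixel.
#' @param dome list(height, radius) in nm; `radius = NULL` defaults to 40%
#'   of the smaller field extent. `height = 0` disables the dome.
#' @param n_microvilli number of microvilli bumps.
#' @param microvillus_amplitude range (nm) amplitudes are drawn from.
#' @param microvillus_width range (nm) of Gaussian sigma values.
#' @param n_filopodia number of ridge features.
#' @param filopodium_amplitude,filopodium_width,filopodium_length ranges (nm).
#' @param features optional data.frame overriding random placement; columns
#'   `type` ("microvillus" or "filopodium"), `x`, `y`, `width`, `amplitude`
#'   and, for filopodia, `length`, `angle` (radians).
#' @param seed RNG seed; a fixed seed gives a bit-identical surface.
#' @return Object of class `topography`: list(height, pixel_size,
#'   feature_truth).
#' @export
simulate_topography <- function(shape = c(128, 128), pixel_size = 78,
                                dome = list(height = 2000, radius = NULL),
                                n_microvilli = 20,
                                microvillus_amplitude = c(100, 300),
                                microvillus_width = c(100, 250),
                                n_filopodia = 2,
                                filopodium_amplitude = c(100, 250),
                                filopodium_width = c(100, 200),
                                filopodium_length = c(2000, 6000),
                                features = NULL, seed = NULL) {
  if (any(shape < 64)) stop_param("shape must be at least 64 x 64 pixels")
  ny <- as.integer(shape[1]); nx <- as.integer(shape[2])
  fovy <- ny * pixel_size; fovx <- nx * pixel_size
  yc <- (seq_len(ny) - 0.5) * pixel_size
  xc <- (seq_len(nx) - 0.5) * pixel_size
  yy <- matrix(yc, ny, nx); xx <- matrix(xc, ny, nx, byrow = TRUE)

  h <- matrix(0, ny, nx)
  dome_h <- dome$height %||% 0
  if (dome_h > 0) {
    dr <- dome$radius %||% (0.4 * min(fovy, fovx))
    h <- dome_h * exp(-((yy - fovy / 2)^2 + (xx - fovx / 2)^2) / (2 * dr^2))
  }

  if (is.null(features)) {
    features <- with_seed(seed, {
      mk <- function(n, type, amp, wid) {
        if (n <= 0) return(NULL)
        data.frame(type = type,
                   x = stats::runif(n, 0.1 * fovx, 0.9 * fovx),
                   y = stats::runif(n, 0.1 * fovy, 0.9 * fovy),
                   width = stats::runif(n, wid[1], wid[2]),
                   amplitude = stats::runif(n, amp[1], amp[2]),
                   length = NA_real_, angle = NA_real_)
      }
      mv <- mk(n_microvilli, "microvillus", microvillus_amplitude, microvillus_width)
      fp <- mk(n_filopodia, "filopodium", filopodium_amplitude, filopodium_width)
      if (!is.null(fp) && nrow(fp)) {
        fp$length <- stats::runif(nrow(fp), filopodium_length[1], filopodium_length[2])
        fp$angle <- stats::runif(nrow(fp), 0, pi)
      }
      rbind(mv, fp)
    })
  } else {
    features <- as.data.frame(features)
    if (!"length" %in% names(features)) features$length <- NA_real_
    if (!"angle" %in% names(features)) features$angle <- NA_real_
  }

  if (!is.null(features) && nrow(features)) {
    if (any(features$amplitude <= 0)) stop_param("feature amplitudes must be > 0")
    for (i in seq_len(nrow(features))) {
      f <- features[i, ]
      if (f$type == "microvillus") {
        h <- h + f$amplitude *
          exp(-((yy - f$y)^2 + (xx - f$x)^2) / (2 * f$width^2))
      } else if (f$type == "filopodium") {
        # ridge: Gaussian cross-section around a finite line segment
        ca <- cos(f$angle); sa <- sin(f$angle)
        u <- (xx - f$x) * ca + (yy - f$y) * sa        # along
        v <- -(xx - f$x) * sa + (yy - f$y) * ca       # across
        along <- pmax(abs(u) - f$length / 2, 0)
        h <- h + f$amplitude * exp(-(v^2 + along^2) / (2 * f$width^2))
      } else stop_param("unknown feature type '%s'", f$type)
    }
  }

  structure(list(height = h, pixel_size = pixel_size,
                 feature_truth = features %||%
                   data.frame(type = character(), x = numeric(), y = numeric(),
                              width = numeric(), amplitude = numeric(),
                              length = numeric(), angle = numeric())),
            class = "topography")
}

#' @export
print.topography <- function(x, ...) {
  cat(sprintf("<topography> %dx%d px at %g nm/px, %d features, range %.0f..%.0f nm\n",
              nrow(x$height), ncol(x$height), x$pixel_size,
              nrow(x$feature_truth), min(x$height), max(x$height)))
  invisible(x)
}
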