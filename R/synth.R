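#' Construct a set of blinking point emitters
#'
#' Emitters are the ground-truth objects of the fluctuation-imaging
#' simulator: point sources at fixed positions that switch stochastically
#' between a bright ("on") and a dark ("off") state. Blinking is modeled as
#' a stationary two-state Markov chain (telegraph process) with mean dwell
#' times `tau_on` and `tau_off` in frames, so the stationary duty cycle is
#' `p_on = tau_on / (tau_on + tau_off)`.
#'
#' All positions are in nanometres. The coordinate convention used
#' throughout the package: pixel (1,1) covers `[0, pixel_size]^2` and has
#' its center at `(pixel_size/2, pixel_size/2)`; `x` runs along columns,
#' `y` along rows, `z` is the axial offset from the stack center.
#'
#' @param x,y,z numeric vectors of positions in nm (recycled to a common
#'   length); `z` defaults to 0 (in focus).
#' @param epsilon mean on-state brightness, photons/frame; must be > 0.
#' @param tau_on,tau_off mean dwell times in frames; must be >= 1.
#' @return An object of class `emitter_set`: a data.frame with columns
#'   `x, y, z, epsilon, p_on, tau_on, tau_off`.
#' @examples
#' em <- emitter_set(x = 800, y = 800, epsilon = 500, tau_on = 5, tau_off = 15)
#' em$p_on  # 0.25
#' @export
emitter_set <- function(x, y, z = 0, epsilon = 500, tau_on = 2, tau_off = 2) {
  n <- max(length(x), length(y), length(z), length(epsilon),
           length(tau_on), length(tau_off))
  df <- data.frame(x = rep_len(x, n), y = rep_len(y, n), z = rep_len(z, n),
                   epsilon = rep_len(epsilon, n),
                   tau_on = rep_len(tau_on, n), tau_off = rep_len(tau_off, n))
  if (any(!is.finite(as.matrix(df)))) stop_param("emitter parameters must be finite")
  if (any(df$epsilon <= 0)) stop_param("epsilon must be > 0")
  if (any(df$tau_on < 1) || any(df$tau_off < 1))
    stop_param("dwell times tau_on, tau_off must be >= 1 frame")
  df$p_on <- df$tau_on / (df$tau_on + df$tau_off)
  df <- df[, c("x", "y", "z", "epsilon", "p_on", "tau_on", "tau_off")]
  class(df) <- c("emitter_set", "data.frame")
  df
}

#' Optical model: Gaussian PSF, pixel grid and (optional) multiplane geometry
#'
#' The point-spread function is an isotropic 2D Gaussian of standard
#' deviation `sigma0` (nm) in focus. Defocus is modeled as a linear growth
#' of the PSF width: `sigma(p, z) = sigma0 + defocus_slope * |z - z_plane(p)|`.
#' For `n_planes > 1` the detection planes are equally spaced by
#' `plane_spacing` nm and centered on z = 0, mimicking an image-splitting
#' prism multiplane system.
#'
#' @param sigma0 in-focus PSF standard deviation, nm.
#' @param pixel_size detector pixel size, nm.
#' @param n_planes number of simultaneously acquired focal planes (>= 1).
#' @param plane_spacing axial distance between adjacent planes, nm
#'   (default 350, the geometry of an 8-plane prism system).
#' @param defocus_slope PSF sigma growth per nm of defocus (dimensionless).
#' @return An object of class `optics_model`.
#' @export
optics_model <- function(sigma0 = 150, pixel_size = 107, n_planes = 1L,
                         plane_spacing = 350, defocus_slope = 0.3) {
  if (sigma0 <= 0) stop_param("sigma0 must be > 0")
  if (pixel_size <= 0) stop_param("pixel_size must be > 0")
  if (n_planes < 1) stop_param("n_planes must be >= 1")
  if (n_planes > 1 && plane_spacing <= 0)
    stop_param("plane_spacing must be > 0 for multiplane optics")
  structure(list(sigma0 = sigma0, pixel_size = pixel_size,
                 n_planes = as.integer(n_planes),
                 plane_spacing = plane_spacing,
                 defocus_slope = defocus_slope),
            class = "optics_model")
}

#' Axial positions of the detection planes
#'
#' Planes are centered on z = 0: plane p sits at
#' `(p - (n_planes + 1)/2) * plane_spacing` nm.
#' @param optics an [optics_model()].
#' @return numeric vector of plane z positions in nm.
#' @export
plane_positions <- function(optics) {
  p <- seq_len(optics$n_planes)
  (p - (optics$n_planes + 1) / 2) * optics$plane_spacing
}

#' Simulate telegraph blinking traces
#'
#' Each emitter's on/off state evolves as a stationary two-state Markov
#' chain with per-frame switching probabilities `1/tau_off` (off -> on) and
#' `1/tau_on` (on -> off); the initial state is drawn from the stationary
#' distribution, so the traces are stationary from frame 1. Traces of
#' different emitters are mutually independent.
#'
#' @param emitters an [emitter_set()].
#' @param n_frames number of frames (>= 2).
#' @param seed integer RNG seed; identical seeds give identical traces.
#' @return integer matrix `n_frames x n_emitters` of 0/1 states.
#' @export
simulate_blink_traces <- function(emitters, n_frames, seed = NULL) {
  stopifnot(inherits(emitters, "emitter_set"))
  if (n_frames < 2) stop_param("n_frames must be >= 2")
  n <- nrow(emitters)
  p_off2on <- 1 / emitters$tau_off
  p_on2off <- 1 / emitters$tau_on
  with_seed(seed, {
    out <- matrix(0L, n_frames, n)
    state <- as.integer(stats::runif(n) < emitters$p_on)
    out[1L, ] <- state
    for (t in 2L:n_frames) {
      u <- stats::runif(n)
      state <- ifelse(state == 1L,
                      as.integer(u >= p_on2off),
                      as.integer(u < p_off2on))
      out[t, ] <- state
    }
    out
  })
}

# Per-emitter, per-plane pixel response: epsilon-scaled Gaussian density
# evaluated at pixel centers times pixel area. Returns Y*X x n matrix.
psf_weights <- function(emitters, optics, ny, nx, plane_z = 0) {
  px <- optics$pixel_size
  yc <- (seq_len(ny) - 0.5) * px
  xc <- (seq_len(nx) - 0.5) * px
  n <- nrow(emitters)
  W <- matrix(0, ny * nx, n)
  for (e in seq_len(n)) {
    s <- optics$sigma0 + optics$defocus_slope * abs(emitters$z[e] - plane_z)
    gy <- exp(-(yc - emitters$y[e])^2 / (2 * s^2))
    gx <- exp(-(xc - emitters$x[e])^2 / (2 * s^2))
    W[, e] <- emitters$epsilon[e] * (px^2 / (2 * pi * s^2)) *
      as.vector(outer(gy, gx))
  }
  W
}

#' Render a blinking-emitter movie
#'
#' Forms the noiseless expected image of every frame as the sum of the
#' emitters' Gaussian PSFs (integrated as pixel-center value times pixel
#' area) gated by their on/off traces, then applies Poisson shot noise and
#' additive Gaussian read noise (clipped at zero). With multiplane optics
#' every frame is rendered on all planes simultaneously with the
#' defocus-dependent PSF width.
#'
#' @param emitters an [emitter_set()]; positions must lie inside the field.
#' @param traces 0/1 matrix from [simulate_blink_traces()] (`T x n`).
#' @param optics an [optics_model()].
#' @param ny,nx field of view in pixels.
#' @param noise list with elements `poisson` (logical) and `read_sigma`
#'   (photons, additive Gaussian, default 1.6 — typical sCMOS).
#' @param exposure seconds per frame (metadata only; default 0.05).
#' @param seed RNG seed for the noise.
#' @param flux_tol maximum tolerated fraction of an emitter's in-focus flux
#'   lost off the field edge before an error is raised.
#' @return A `blink_movie`: list with `data` (array `T x Y x X`, or
#'   `T x P x Y x X` for multiplane), `exposure`, `optics`, `seed`, `meta`.
#' @export
render_movie <- function(emitters, traces, optics, ny, nx,
                         noise = list(poisson = TRUE, read_sigma = 1.6),
                         exposure = 0.05, seed = NULL, flux_tol = 0.01) {
  stopifnot(inherits(emitters, "emitter_set"), inherits(optics, "optics_model"))
  nT <- nrow(traces)
  if (ncol(traces) != nrow(emitters))
    stop_param("traces has %d columns but there are %d emitters",
               ncol(traces), nrow(emitters))
  fovy <- ny * optics$pixel_size; fovx <- nx * optics$pixel_size
  if (any(emitters$x < 0 | emitters$x > fovx | emitters$y < 0 | emitters$y > fovy))
    stop_param("emitter positions must lie inside the field of view")
  zp <- plane_positions(optics)
  P <- optics$n_planes
  # flux capture check at each emitter's best-focus plane
  best <- vapply(emitters$z, function(z) zp[which.min(abs(zp - z))], numeric(1))
  for (e in seq_len(nrow(emitters))) {
    w <- psf_weights(emitters[e, , drop = FALSE], optics, ny, nx, best[e])
    if (sum(w) < (1 - flux_tol) * emitters$epsilon[e])
      stop_param("field too small to contain the PSF support of emitter %d", e)
  }
  dat <- if (P == 1L) array(0, c(nT, ny, nx)) else array(0, c(nT, P, ny, nx))
  with_seed(seed, {
    for (p in seq_len(P)) {
      W <- psf_weights(emitters, optics, ny, nx, zp[p])     # (Y*X) x n
      expected <- traces %*% t(W)                           # T x (Y*X)
      vals <- if (isTRUE(noise$poisson))
        stats::rpois(length(expected), lambda = pmax(expected, 0))
      else expected
      rs <- noise$read_sigma %||% 0
      if (rs > 0) vals <- vals + stats::rnorm(length(vals), 0, rs)
      vals <- pmax(vals, 0)
      if (P == 1L) dat[] <- array(vals, c(nT, ny, nx))
      else dat[, p, , ] <- array(vals, c(nT, ny, nx))
    }
  })
  structure(list(data = dat, exposure = exposure, optics = optics, seed = seed,
                 meta = list(frames_excluded = 0L)),
            class = "blink_movie")
}

#' @export
print.blink_movie <- function(x, ...) {
  d <- dim(x$data)
  if (length(d) == 3L)
    cat(sprintf("<blink_movie> %d frames, %dx%d px, pixel %g nm, exposure %g s\n",
                d[1], d[2], d[3], x$optics$pixel_size, x$exposure))
  else
    cat(sprintf("<blink_movie> %d frames, %d planes, %dx%d px, pixel %g nm, spacing %g nm\n",
                d[1], d[2], d[3], d[4], x$optics$pixel_size, x$optics$plane_spacing))
  invisible(x)
}

n_frames <- function(movie) dim(movie$data)[1]
is_multiplane <- function(movie) length(dim(movie$data)) == 4L

#' One-call blinking-movie simulation
#'
#' Convenience wrapper: simulates traces then renders the movie with a
#' single seed (traces use `seed`, noise uses `seed + 1`).
#' @inheritParams render_movie
#' @inheritParams simulate_blink_traces
#' @export
simulate_movie <- function(emitters, n_frames, optics, ny, nx,
                           noise = list(poisson = TRUE, read_sigma = 1.6),
                           exposure = 0.05, seed = 1L) {
  tr <- simulate_blink_traces(emitters, n_frames, seed = seed)
  render_movie(emitters, tr, optics, ny, nx, noise = noise,
               exposure = exposure, seed = if (is.null(seed)) NULL else seed + 1L)
}
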