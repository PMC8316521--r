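# Shared fixture builders. Everything is generated in code at test time;
# scene sizes are kept small so the whole suite runs in minutes on one CPU.

std_optics <- function(sigma0 = 150, pixel_size = 100, ...) {
  optics_model(sigma0 = sigma0, pixel_size = pixel_size, ...)
}

# single emitter centered in a small field
single_emitter_movie <- function(n_frames, tau_on = 2, tau_off = 2,
                                 epsilon = 1000, ny = 16, nx = 16,
                                 optics = std_optics(),
                                 noise = list(poisson = TRUE, read_sigma = 1.6),
                                 seed = 1L) {
  cx <- nx * optics$pixel_size / 2
  cy <- ny * optics$pixel_size / 2
  em <- emitter_set(cx, cy, epsilon = epsilon, tau_on = tau_on,
                    tau_off = tau_off)
  tr <- simulate_blink_traces(em, n_frames, seed = seed)
  list(movie = render_movie(em, tr, optics, ny, nx, noise = noise,
                            seed = seed + 1L),
       emitters = em, traces = tr)
}

# dense random field of emitters with a safety margin for the PSF support
dense_scene_movie <- function(n_emitters, n_frames, ny = 48, nx = 48,
                              optics = std_optics(), epsilon = 600,
                              tau_on = 2, tau_off = 6,
                              noise = list(poisson = TRUE, read_sigma = 1.6),
                              seed = 1L) {
  fovx <- nx * optics$pixel_size; fovy <- ny * optics$pixel_size
  mx <- max(0.1 * fovx, 3.5 * optics$sigma0)
  my <- max(0.1 * fovy, 3.5 * optics$sigma0)
  em <- with_seed(seed, emitter_set(
    stats::runif(n_emitters, mx, fovx - mx),
    stats::runif(n_emitters, my, fovy - my),
    epsilon = epsilon, tau_on = tau_on, tau_off = tau_off))
  list(movie = simulate_movie(em, n_frames, optics, ny, nx, noise = noise,
                              seed = seed + 1L),
       emitters = em)
}

with_seed <- cumulantscope:::with_seed
fit_g2d <- cumulantscope:::fit_gaussian2d

# standard error of an order-n cumulant estimate by block splitting
cumulant_block_se <- function(trace, order, n_blocks = 20) {
  T <- length(trace)
  bl <- T %/% n_blocks
  vals <- vapply(seq_len(n_blocks), function(b) {
    seg <- trace[((b - 1) * bl + 1):(b * bl)]
    cumulant_timeseries(matrix(seg, ncol = 1)[, rep(1, order), drop = FALSE],
                        order)
  }, numeric(1))
  stats::sd(vals) / sqrt(n_blocks)
}

# checkerboard amplitude of an order-2 cumulant image (interior crop to
# avoid border-weighting artifacts)
checkerboard_amp <- function(ci, crop = 12) {
  v <- valid_region(ci)
  v <- v[(crop + 1):(nrow(v) - crop), (crop + 1):(ncol(v) - crop)]
  ph <- function(ry, rx) mean(v[seq(ry + 1, nrow(v), by = 2),
                                seq(rx + 1, ncol(v), by = 2)])
  abs(ph(0, 0) - ph(1, 1)) / abs(mean(v))
}

# paired height/intensity maps for correlation tests: a vertical Gaussian
# ridge; the intensity ridge is displaced by `shift_px` columns
ridge_pair <- function(ny = 70, nx = 140, ridge_col = 70, width_px = 4,
                       shift_px = 0, noise_frac = 0.05, seed = 1L) {
  cols <- seq_len(nx)
  h <- matrix(rep(exp(-(cols - ridge_col)^2 / (2 * width_px^2)), each = ny),
              ny, nx)
  i <- matrix(rep(exp(-(cols - ridge_col - shift_px)^2 / (2 * width_px^2)),
                  each = ny), ny, nx)
  with_seed(seed, {
    h <- h + noise_frac * matrix(stats::rnorm(ny * nx), ny, nx)
    i <- i + noise_frac * matrix(stats::rnorm(ny * nx), ny, nx)
  })
  list(height = cumulantscope:::new_height_map(h * 200, 50), intensity = i)
}
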