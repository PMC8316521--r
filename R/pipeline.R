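# Umbrella pipeline: one YAML config drives simulate -> preprocess ->
# cumulants -> postprocess -> resolution -> scan -> register -> correlate,
# logging per-stage parameters, durations and output hashes. All
# randomness flows from the config's seed, so reruns are bit-identical.

pipeline_schema <- list(
  seed = TRUE, output_dir = TRUE, schema_version = TRUE,
  synth = c("n_emitters", "n_frames", "ny", "nx", "sigma0", "pixel_size",
            "epsilon", "tau_on", "tau_off", "read_sigma", "exposure"),
  preproc = c("skip_frames", "block_len"),
  sofi = c("order", "flatten"),
  postproc = c("deconv_iters"),
  decorr = c("n_filters"),
  sicm = c("shape_y", "shape_x", "pixel_size", "radius", "c_s", "setpoint",
           "hopping_height", "pixel_rate", "noise_sigma", "n_microvilli",
           "dome_height"),
  coreg = c("n_sections", "section_half_length"))

#' Validate and resolve a pipeline configuration
#'
#' Unknown keys are rejected (top level and per stage); missing values
#' fall back to documented defaults; the fully-resolved config is what
#' [run_pipeline()] echoes into its report.
#'
#' @param config a named list, or path to a YAML file.
#' @return the resolved config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_param("config must be a list or a YAML file path")
  unknown <- setdiff(names(config), names(pipeline_schema))
  if (length(unknown))
    stop_param("unknown config keys: %s", paste(unknown, collapse = ", "))
  for (stage in names(config)) {
    allowed <- pipeline_schema[[stage]]
    if (is.character(allowed)) {
      bad <- setdiff(names(config[[stage]]), allowed)
      if (length(bad))
        stop_param("unknown keys in '%s': %s", stage, paste(bad, collapse = ", "))
    }
  }
  dflt <- function(x, d) { d[names(x)] <- x; d }
  config$seed <- config$seed %||% 1L
  config$schema_version <- config$schema_version %||% 1L
  config$synth <- dflt(config$synth, list(
    n_emitters = 30L, n_frames = 500L, ny = 72L, nx = 72L, sigma0 = 150,
    pixel_size = 107, epsilon = 800, tau_on = 2, tau_off = 6,
    read_sigma = 1.6, exposure = 0.05))
  config$preproc <- dflt(config$preproc, list(skip_frames = 0L, block_len = 0L))
  config$sofi <- dflt(config$sofi, list(order = 2L, flatten = TRUE))
  if (!config$sofi$order %in% 2:4)
    stop_param("sofi order must be 2, 3 or 4 (got %s)", config$sofi$order)
  config$postproc <- dflt(config$postproc, list(deconv_iters = 10L))
  config$decorr <- dflt(config$decorr, list(n_filters = 10L))
  config$sicm <- dflt(config$sicm, list(
    shape_y = 72L, shape_x = 72L, pixel_size = 107, radius = 50, c_s = 0.01,
    setpoint = 0.99, hopping_height = 5000, pixel_rate = 200,
    noise_sigma = 2, n_microvilli = 12L, dome_height = 1500))
  config$coreg <- dflt(config$coreg, list(n_sections = 8L,
                                          section_half_length = 1000))
  config
}

#' Run the full correlative pipeline on a synthetic scene
#'
#' Builds a shared ground-truth scene (a cell-like topography whose
#' microvilli positions carry the blinking "actin" emitters), renders and
#' processes the fluorescence movie through cumulant analysis and
#' deconvolution, estimates resolution, scans the topography with the
#' simulated pipette, registers the channels, extracts cross-sections at
#' the feature positions and reports their Pearson correlations.
#'
#' @param config list or YAML path; see [validate_config()].
#' @return report list (also written as `report.json` in `output_dir` if
#'   set), containing the resolved config, per-stage parameters,
#'   durations, output hashes and summary statistics.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  t_all <- proc.time()[["elapsed"]]
  stages <- list()
  tick <- function() proc.time()[["elapsed"]]
  outdir <- cfg$output_dir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  # --- shared ground-truth scene ------------------------------------
  t0 <- tick()
  s <- cfg$synth; sc <- cfg$sicm
  topo <- simulate_topography(
    shape = c(sc$shape_y, sc$shape_x), pixel_size = sc$pixel_size,
    dome = list(height = sc$dome_height, radius = NULL),
    n_microvilli = sc$n_microvilli, n_filopodia = 0, seed = cfg$seed)
  ft <- topo$feature_truth
  margin <- 4 * s$sigma0
  fovx <- s$nx * s$pixel_size; fovy <- s$ny * s$pixel_size
  keep <- ft$x > margin & ft$x < fovx - margin &
    ft$y > margin & ft$y < fovy - margin
  em_xy <- ft[keep & ft$type == "microvillus", c("x", "y")]
  if (nrow(em_xy) < 3)
    stop_param("scene has too few interior features; enlarge the field")
  extra <- max(0L, s$n_emitters - nrow(em_xy))
  em <- with_seed(cfg$seed + 1L, {
    xs <- c(em_xy$x, stats::runif(extra, margin, fovx - margin))
    ys <- c(em_xy$y, stats::runif(extra, margin, fovy - margin))
    emitter_set(xs, ys, epsilon = s$epsilon, tau_on = s$tau_on,
                tau_off = s$tau_off)
  })
  movie <- simulate_movie(em, s$n_frames,
                          optics_model(s$sigma0, s$pixel_size),
                          s$ny, s$nx,
                          noise = list(poisson = TRUE, read_sigma = s$read_sigma),
                          exposure = s$exposure, seed = cfg$seed + 2L)
  stages$synth <- list(params = s, duration_s = tick() - t0,
                       n_emitters = nrow(em), n_features = nrow(ft))

  # --- preprocess ----------------------------------------------------
  t0 <- tick()
  if (cfg$preproc$skip_frames > 0)
    movie <- exclude_frames(movie, cfg$preproc$skip_frames)
  bleach <- fit_bleaching(movie)
  if (cfg$preproc$block_len > 0 &&
      n_frames(movie) >= 2 * cfg$preproc$block_len) {
    track <- estimate_drift(movie, cfg$preproc$block_len)
    movie <- apply_drift(movie, track)
  }
  stages$preproc <- list(params = cfg$preproc, duration_s = tick() - t0,
                         bleach_lifetime_s = bleach$lifetime,
                         frames_used = n_frames(movie))

  # --- cumulants + postprocessing ------------------------------------
  t0 <- tick()
  ci <- sofi2d(movie, order = cfg$sofi$order, flatten = cfg$sofi$flatten)
  sofi_img <- sofi_postprocess(ci, sigma0 = s$sigma0,
                               iters = cfg$postproc$deconv_iters)
  stages$sofi <- list(params = c(cfg$sofi, cfg$postproc),
                      duration_s = tick() - t0,
                      grid_spacing_nm = sofi_img$grid_spacing)

  # --- resolution -----------------------------------------------------
  t0 <- tick()
  wf <- apply(movie$data, c(2, 3), mean)
  res_wf <- estimate_resolution(wf, grid_spacing = s$pixel_size,
                                n_filters = cfg$decorr$n_filters)
  res_sofi <- estimate_resolution(sofi_img, n_filters = cfg$decorr$n_filters)
  stages$decorr <- list(duration_s = tick() - t0,
                        widefield_resolution_nm = res_wf$resolution_nm,
                        sofi_resolution_nm = res_sofi$resolution_nm)

  # --- topography scan ------------------------------------------------
  t0 <- tick()
  pip <- pipette_model(sc$radius, sc$c_s)
  scfg <- scan_config(sc$setpoint, sc$hopping_height, sc$pixel_rate,
                      pixels = dim(topo$height), pixel_size = sc$pixel_size)
  hm <- hop_scan(topo, pip, scfg, noise_sigma = sc$noise_sigma,
                 seed = cfg$seed + 3L)
  hm_lv <- level_plane(hm)
  stages$sicm <- list(params = sc, duration_s = tick() - t0,
                      scan_time_s = hm$meta$scan_time_s)

  # --- registration (channels share the physical frame here) ----------
  t0 <- tick()
  cp <- data.frame(x_src = ft$x[keep], y_src = ft$y[keep],
                   x_dst = ft$x[keep], y_dst = ft$y[keep])
  amap <- fit_affine(cp)
  sofi_on_sicm <- warp_image(sofi_img$values, sofi_img$grid_spacing, amap,
                             dim(hm$height), hm$pixel_size)
  stages$coreg_fit <- list(duration_s = tick() - t0,
                           residual_rms_nm = amap$residual_rms)

  # --- cross-section correlation --------------------------------------
  t0 <- tick()
  half <- cfg$coreg$section_half_length
  feats <- ft[keep & ft$type == "microvillus", ]
  n_sec <- min(cfg$coreg$n_sections, nrow(feats))
  r_vals <- numeric(0)
  inten <- sofi_on_sicm$values
  inten[is.na(inten)] <- 0
  for (i in seq_len(n_sec)) {
    sec <- c(feats$x[i] - half, feats$y[i], feats$x[i] + half, feats$y[i])
    cs <- tryCatch(extract_profiles(hm_lv, inten, sec), error = function(e) NULL)
    if (is.null(cs)) next
    r <- pearson(cs)
    if (!is.na(r)) r_vals <- c(r_vals, r)
  }
  stages$correlate <- list(duration_s = tick() - t0, n_sections = length(r_vals),
                           median_r = stats::median(r_vals))

  # --- outputs + report ----------------------------------------------
  hashes <- list()
  if (!is.null(outdir)) {
    f1 <- file.path(outdir, "sofi.tif"); write_stack(sofi_img, f1)
    f2 <- file.path(outdir, "heightmap.tif"); write_stack(hm_lv, f2)
    f3 <- file.path(outdir, "emitters.csv"); write_truth_csv(em, f3)
    hashes <- lapply(c(sofi = f1, heightmap = f2, emitters = f3),
                     function(f) unname(tools::md5sum(f)))
  }
  report <- list(config = cfg, stages = stages, output_hashes = hashes,
                 total_duration_s = tick() - t_all,
                 checks = list(
                   sofi_sharper_than_widefield =
                     isTRUE(res_sofi$resolution_nm < res_wf$resolution_nm),
                   median_r = stages$correlate$median_r,
                   leveled_mean_near_zero =
                     abs(mean(hm_lv$height[hm_lv$valid])) <
                       1e-9 * diff(range(hm_lv$height[hm_lv$valid])) + 1e-9))
  if (!is.null(outdir))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  invisible(report)
}
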