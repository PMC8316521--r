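# Interleaved live-cell acquisition bookkeeping: alternating topography
# scans and fluorescence sub-stacks, with per-cycle timing and frame
# accounting. The clock is purely simulated (ideal durations, explicit
# overhead parameter); no instrument control.

#' Define an interleaved SICM/SOFI time-lapse schedule
#'
#' One cycle = one topography scan followed by one fluorescence sub-stack.
#' Derived durations: `sicm_duration = prod(sicm_pixels) / pixel_rate`
#' seconds, `sofi_duration = sofi_frames * exposure` seconds; the frames
#' used for cumulant analysis are `sofi_frames - skip_frames`, so the
#' achieved SOFI temporal resolution is `(sofi_frames - skip_frames) *
#' exposure` seconds.
#'
#' @param n_cycles number of interleaved cycles.
#' @param sicm_pixels integer c(Y, X) of the topography scan.
#' @param pixel_rate SICM pixels per second (default 200).
#' @param sofi_frames frames recorded per fluorescence stack (default 300).
#' @param exposure seconds per frame (default 0.05).
#' @param skip_frames leading frames excluded from cumulant analysis
#'   (default 50); must be < `sofi_frames`.
#' @param dark_interval extra seconds between stacks (default 0).
#' @return object of class `timelapse_schedule`.
#' @export
timelapse_schedule <- function(n_cycles = 10, sicm_pixels = c(100, 200),
                               pixel_rate = 200, sofi_frames = 300,
                               exposure = 0.05, skip_frames = 50,
                               dark_interval = 0) {
  if (sofi_frames <= skip_frames)
    stop_param("sofi_frames must exceed skip_frames")
  if (n_cycles < 1) stop_param("n_cycles must be >= 1")
  structure(list(n_cycles = as.integer(n_cycles),
                 sicm_pixels = as.integer(sicm_pixels),
                 pixel_rate = pixel_rate,
                 sofi_frames = as.integer(sofi_frames),
                 exposure = exposure, skip_frames = as.integer(skip_frames),
                 dark_interval = dark_interval),
            class = "timelapse_schedule")
}

#' Per-cycle event table of a time-lapse schedule
#'
#' @param schedule a [timelapse_schedule()].
#' @return data.frame with one row per cycle: `cycle, t_start,
#'   sicm_duration, sofi_duration, frames_used_for_sofi,
#'   sofi_temporal_resolution, t_end` (seconds).
#' @export
plan_timelapse <- function(schedule) {
  stopifnot(inherits(schedule, "timelapse_schedule"))
  sicm_d <- prod(schedule$sicm_pixels) / schedule$pixel_rate
  sofi_d <- schedule$sofi_frames * schedule$exposure
  used <- schedule$sofi_frames - schedule$skip_frames
  res <- used * schedule$exposure
  cyc_d <- sicm_d + sofi_d + schedule$dark_interval
  t0 <- (seq_len(schedule$n_cycles) - 1) * cyc_d
  data.frame(cycle = seq_len(schedule$n_cycles), t_start = t0,
             sicm_duration = sicm_d, sofi_duration = sofi_d,
             frames_used_for_sofi = used, sofi_temporal_resolution = res,
             t_end = t0 + cyc_d)
}

#' Run a fully synthetic interleaved time-lapse
#'
#' For each cycle: scans the scene's current topography with
#' [hop_scan()], then renders the fluorescence sub-stack, excludes the
#' leading frames, and computes a flattened 2nd-order cumulant image.
#' Frames are never mixed across cycles. A simulated clock accumulates
#' the ideal durations of [plan_timelapse()].
#'
#' @param scene_fn function(cycle) returning list(topography = a
#'   `topography`, emitters = an `emitter_set`) describing the scene at
#'   that cycle.
#' @param schedule a [timelapse_schedule()].
#' @param optics an [optics_model()] for the fluorescence channel.
#' @param ny,nx fluorescence field of view in pixels.
#' @param pipette a [pipette_model()].
#' @param scan a [scan_config()].
#' @param noise_sigma SICM axial noise, nm.
#' @param seed base RNG seed; cycle c uses `seed + 7*c` offsets.
#' @return list of per-cycle lists: `cycle, t_start, t_end, height_map,
#'   sofi` plus the full `plan` table as attribute "plan".
#' @export
run_synthetic_timelapse <- function(scene_fn, schedule, optics, ny, nx,
                                    pipette = pipette_model(),
                                    scan = scan_config(),
                                    noise_sigma = 1, seed = 1L) {
  stopifnot(is.function(scene_fn), inherits(schedule, "timelapse_schedule"))
  plan <- plan_timelapse(schedule)
  out <- vector("list", schedule$n_cycles)
  for (cyc in seq_len(schedule$n_cycles)) {
    scene <- scene_fn(cyc)
    hm <- hop_scan(scene$topography, pipette, scan,
                   noise_sigma = noise_sigma, seed = seed + 7L * cyc)
    mv <- simulate_movie(scene$emitters, schedule$sofi_frames, optics, ny, nx,
                         exposure = schedule$exposure,
                         seed = seed + 7L * cyc + 3L)
    mv <- exclude_frames(mv, schedule$skip_frames)
    ci <- sofi2d(mv, order = 2, flatten = TRUE)
    out[[cyc]] <- list(cycle = cyc, t_start = plan$t_start[cyc],
                       t_end = plan$t_end[cyc], height_map = hm, sofi = ci)
  }
  attr(out, "plan") <- plan
  out
}
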