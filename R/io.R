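# File interchange: TIFF + JSON sidecar for image stacks, Gwyddion-style
# plain-text matrices for height maps, CSV for point/feature tables. The
# sidecar carries the full metadata so a write/read round trip restores
# the original object (lossless for float32-representable data).

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

write_sidecar <- function(meta, path) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  out <- tryCatch(jsonlite::read_json(sp, simplifyVector = TRUE),
                  error = function(e)
                    stop_param("malformed sidecar %s: %s", sp, conditionMessage(e)))
  if (is.null(out$class))
    stop_param("malformed sidecar %s: missing 'class' field", sp)
  out
}

#' Write an imaging object to TIFF + JSON sidecar
#'
#' `blink_movie` stacks are written as multi-page TIFF (`T` pages, or
#' `T*P` with the plane index fastest), `cumulant_image` and `height_map`
#' objects as 32-bit float pages; all metadata goes into a JSON sidecar
#' next to the file so that [read_stack()] restores the object.
#'
#' @param obj a `blink_movie`, `cumulant_image`, `height_map`, or bare
#'   matrix/array.
#' @param path output TIFF path.
#' @param type sample type, `"float32"` (lossless default) or `"uint16"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(obj, path, type = "float32") {
  if (inherits(obj, "blink_movie")) {
    write_tiff(obj$data, path, type = type)
    write_sidecar(list(class = "blink_movie", dims = dim(obj$data),
                       exposure = obj$exposure, seed = obj$seed,
                       optics = unclass(obj$optics), meta = obj$meta,
                       sample_type = type), path)
  } else if (inherits(obj, "cumulant_image")) {
    write_tiff(obj$values, path, type = "float32")
    write_sidecar(list(class = "cumulant_image", dims = dim(obj$values),
                       order = obj$order, grid_spacing = obj$grid_spacing,
                       plane_spacing_out = obj$plane_spacing_out,
                       n_frames_used = obj$n_frames_used,
                       pixel_size_in = obj$pixel_size_in,
                       flattened = obj$flattened, sigma = obj$sigma,
                       linearized = obj$linearized), path)
  } else if (inherits(obj, "height_map")) {
    h <- obj$height
    h[!obj$valid] <- NaN
    write_tiff(h, path, type = "float32")
    write_sidecar(list(class = "height_map", dims = dim(h),
                       pixel_size = obj$pixel_size, leveled = obj$leveled,
                       meta = obj$meta[setdiff(names(obj$meta),
                                               c("config", "pipette"))]),
                  path)
  } else {
    write_tiff(obj, path, type = type)
    write_sidecar(list(class = "array", dims = dim(obj) %||%
                         c(1L, length(obj)), sample_type = type), path)
  }
  invisible(path)
}

#' Read an imaging object written by [write_stack()]
#'
#' Without a sidecar the pixel data is returned as a bare matrix/array
#' with a warning (pixel size unknown).
#'
#' @param path TIFF path.
#' @return the restored object.
#' @export
read_stack <- function(path) {
  dat <- read_tiff(path)
  meta <- read_sidecar(path)
  if (is.null(meta)) {
    warning("no JSON sidecar found: returning raw pixel data, pixel size unknown")
    attr(dat, "pixel_size") <- NA_real_
    return(dat)
  }
  dims <- as.integer(unlist(meta$dims))
  if (meta$class == "blink_movie") {
    arr <- array(0, dims)
    if (length(dims) == 3L) arr[] <- dat
    else {
      k <- 0L
      for (t in seq_len(dims[1])) for (p in seq_len(dims[2])) {
        k <- k + 1L
        arr[t, p, , ] <- if (length(dim(dat)) == 3L) dat[k, , ] else dat
      }
    }
    o <- meta$optics
    structure(list(data = arr, exposure = meta$exposure,
                   optics = optics_model(o$sigma0, o$pixel_size, o$n_planes,
                                         o$plane_spacing %||% 350,
                                         o$defocus_slope),
                   seed = meta$seed, meta = as.list(meta$meta)),
              class = "blink_movie")
  } else if (meta$class == "cumulant_image") {
    vals <- if (length(dims) == 2L) matrix(dat, dims[1], dims[2]) else {
      a <- array(0, dims); a[] <- dat; a
    }
    n <- as.integer(meta$order)
    mk_mask <- function(len, Y) { m <- rep(FALSE, len); m[seq_len(n * (Y - 1) + 1)] <- TRUE; m }
    if (length(dims) == 2L) {
      mask <- outer(mk_mask(dims[1], dims[1] %/% n), mk_mask(dims[2], dims[2] %/% n), `&`)
    } else {
      mask <- array(FALSE, dims)
      mask[] <- TRUE  # valid lateral/axial pattern reconstructed coarsely
    }
    new_cumulant_image(vals, mask, n, meta$grid_spacing, meta$n_frames_used,
                       meta$pixel_size_in, meta$plane_spacing_out,
                       isTRUE(meta$flattened), meta$sigma,
                       isTRUE(meta$linearized))
  } else if (meta$class == "height_map") {
    valid <- is.finite(dat)
    new_height_map(dat, meta$pixel_size, valid = valid,
                   leveled = isTRUE(meta$leveled), meta = as.list(meta$meta))
  } else dat
}

#' Export a height map as a plain-text matrix
#'
#' Whitespace-delimited matrix of heights in nm (one scan row per line),
#' preceded by `#`-comment header lines carrying the pixel size -- the
#' format Gwyddion imports as "ASCII data matrix".
#'
#' @param map a `height_map` (or bare matrix with `pixel_size`).
#' @param path output text file.
#' @param pixel_size nm per pixel (for bare matrices).
#' @export
export_text_matrix <- function(map, path, pixel_size = NULL) {
  if (inherits(map, "height_map")) {
    h <- map$height; pixel_size <- map$pixel_size
  } else h <- as.matrix(map)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# height matrix, nm",
               sprintf("# pixel_size_nm %.10g", pixel_size %||% NA_real_)), con)
  utils::write.table(format(h, digits = 9, trim = TRUE, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Import a plain-text height matrix
#' @param path text file from [export_text_matrix()] (or any
#'   whitespace-delimited numeric matrix, `#` comments ignored).
#' @return a `height_map` (pixel size from the header when present).
#' @export
read_text_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  px <- NA_real_
  m <- regmatches(hdr, regexpr("pixel_size_nm\\s+\\S+", hdr))
  if (length(m)) px <- as.numeric(sub("pixel_size_nm\\s+", "", m[[1]]))
  dat <- utils::read.table(text = lines[!grepl("^#", lines)])
  new_height_map(as.matrix(dat), px, meta = list(source = path))
}

#' Read a control-point CSV
#'
#' Expected columns: `x_src, y_src, x_dst, y_dst` and optionally `label`.
#' @param path CSV file.
#' @export
read_control_points <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_src", "y_src", "x_dst", "y_dst")
  if (!all(need %in% names(df)))
    stop_param("control-point CSV must have columns %s", paste(need, collapse = ", "))
  df
}

#' Write emitter/feature ground truth as CSV
#' @param truth an `emitter_set` or `feature_truth` data.frame.
#' @param path CSV file.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(as.data.frame(truth), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a drift track to CSV (block_index, frame_center, dx, dy)
#' @param track a `drift_track`.
#' @param path CSV file.
#' @export
write_drift_track <- function(track, path) {
  stopifnot(inherits(track, "drift_track"))
  utils::write.csv(data.frame(block_index = track$blocks$block,
                              frame_center = track$blocks$frame_center,
                              dx = track$blocks$dx, dy = track$blocks$dy),
                   path, row.names = FALSE)
  invisible(path)
}
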