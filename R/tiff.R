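# Minimal baseline TIFF codec (uncompressed, little-endian writer; reader
# accepts either byte order). Grayscale, one sample per pixel, uint8/16/32
# or float32/64, one or more strips per page. This exists because no
# TIFF-capable R package is available in the target environment; the
# subset implemented is the plain multi-page format that scientific
# imaging tools (tifffile, Fiji) write by default for raw stacks.

#' Write a numeric array as a multi-page TIFF
#'
#' @param data matrix (one page), 3D array `P x Y x X` (P pages), or 4D
#'   array `T x P x Y x X` (written as `T*P` pages, plane index fastest).
#' @param path output file.
#' @param type `"float32"` (default, lossless for float32-representable
#'   data) or `"uint16"` (values rounded and clipped to 0..65535).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(data, path, type = c("float32", "uint16")) {
  type <- match.arg(type)
  pages <- tiff_pages(data)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  ifd0_ptr_pos <- 4L
  writeBin(0L, con, size = 4, endian = "little")   # patched later
  offsets <- integer(length(pages))
  bytecounts <- integer(length(pages))
  for (i in seq_along(pages)) {
    offsets[i] <- seek(con)
    m <- pages[[i]]
    v <- as.vector(t(m))                            # row-major
    if (type == "float32") {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
      bytecounts[i] <- 4L * length(v)
    } else {
      iv <- as.integer(pmin(pmax(round(v), 0), 65535))
      iv[iv > 32767L] <- iv[iv > 32767L] - 65536L   # two's complement
      writeBin(iv, con, size = 2, endian = "little")
      bytecounts[i] <- 2L * length(v)
    }
  }
  ifd_offsets <- integer(length(pages))
  for (i in seq_along(pages)) {
    ifd_offsets[i] <- seek(con)
    m <- pages[[i]]
    bits <- if (type == "float32") 32L else 16L
    fmt <- if (type == "float32") 3L else 1L
    entries <- list(
      c(256L, 4L, 1L, ncol(m)),            # ImageWidth
      c(257L, 4L, 1L, nrow(m)),            # ImageLength
      c(258L, 3L, 1L, bits),               # BitsPerSample
      c(259L, 3L, 1L, 1L),                 # Compression: none
      c(262L, 3L, 1L, 1L),                 # Photometric: BlackIsZero
      c(273L, 4L, 1L, offsets[i]),         # StripOffsets
      c(277L, 3L, 1L, 1L),                 # SamplesPerPixel
      c(278L, 4L, 1L, nrow(m)),            # RowsPerStrip
      c(279L, 4L, 1L, bytecounts[i]),      # StripByteCounts
      c(339L, 3L, 1L, fmt))                # SampleFormat
    writeBin(length(entries), con, size = 2, endian = "little")
    for (e in entries) {
      e <- as.integer(e)
      writeBin(e[1], con, size = 2, endian = "little")
      writeBin(e[2], con, size = 2, endian = "little")
      writeBin(e[3], con, size = 4, endian = "little")
      if (e[2] == 3L) {                    # SHORT: left-justified in 4 bytes
        writeBin(e[4], con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(e[4], con, size = 4, endian = "little")
      }
    }
    next_ptr_pos <- seek(con)
    writeBin(0L, con, size = 4, endian = "little")
    if (i == 1L) {
      seek(con, ifd0_ptr_pos, rw = "write")
      writeBin(as.integer(ifd_offsets[1]), con, size = 4, endian = "little")
    } else {
      # patch previous IFD's next pointer
      seek(con, prev_next_ptr, rw = "write")
      writeBin(as.integer(ifd_offsets[i]), con, size = 4, endian = "little")
    }
    seek(con, next_ptr_pos + 4L, rw = "write")
    prev_next_ptr <- next_ptr_pos
  }
  invisible(path)
}

tiff_pages <- function(data) {
  d <- dim(data)
  if (is.matrix(data)) return(list(data))
  if (length(d) == 3L)
    return(lapply(seq_len(d[1]), function(i) matrix(data[i, , ], d[2], d[3])))
  if (length(d) == 4L) {
    out <- vector("list", d[1] * d[2])
    k <- 0L
    for (t in seq_len(d[1])) for (p in seq_len(d[2])) {
      k <- k + 1L
      out[[k]] <- matrix(data[t, p, , ], d[3], d[4])
    }
    return(out)
  }
  stop_param("data must be a matrix or a 3D/4D array")
}

#' Read a (baseline, uncompressed, grayscale) TIFF
#'
#' @param path TIFF file.
#' @return matrix for a single page, otherwise an array `P x Y x X`.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop_param("not a TIFF file")
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
  else stop_param("not a TIFF file (bad byte-order mark)")
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = endian)
  u32 <- function(off) {
    v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = endian)
    if (v < 0) v + 2^32 else v
  }
  if (u16(2) != 42L) stop_param("not a TIFF file (bad magic)")
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    n_entries <- u16(ifd)
    tags <- list()
    for (k in seq_len(n_entries)) {
      base <- ifd + 2 + (k - 1) * 12
      tag <- u16(base); typ <- u16(base + 2); cnt <- u32(base + 4)
      tsize <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `11` = 4, `12` = 8)[as.character(typ)]
      if (is.na(tsize)) next
      nbytes <- tsize * cnt
      voff <- if (nbytes <= 4) base + 8 else u32(base + 8)
      vals <- switch(as.character(typ),
        `3` = vapply(seq_len(cnt), function(j) u16(voff + (j - 1) * 2), numeric(1)),
        `4` = vapply(seq_len(cnt), function(j) u32(voff + (j - 1) * 4), numeric(1)),
        `1` = as.numeric(raw[(voff + 1):(voff + cnt)]),
        `11` = readBin(raw[(voff + 1):(voff + 4 * cnt)], "numeric", n = cnt,
                       size = 4, endian = endian),
        `12` = readBin(raw[(voff + 1):(voff + 8 * cnt)], "numeric", n = cnt,
                       size = 8, endian = endian),
        NULL)
      tags[[as.character(tag)]] <- vals
    }
    g <- function(t, default = NULL) tags[[as.character(t)]] %||% default
    width <- g(256); height <- g(257)
    if (is.null(width) || is.null(height)) stop_param("TIFF page missing dimensions")
    bits <- g(258, 1)[1]
    if ((g(259, 1))[1] != 1) stop_param("compressed TIFF not supported")
    if (g(277, 1)[1] != 1) stop_param("only single-sample (grayscale) TIFF supported")
    fmt <- g(339, 1)[1]
    strip_off <- g(273); strip_cnt <- g(279)
    if (is.null(strip_off)) stop_param("TIFF page missing strip offsets")
    if (is.null(strip_cnt)) strip_cnt <- rep(width * height * bits / 8 /
                                               length(strip_off), length(strip_off))
    buf <- raw(0)
    for (s in seq_along(strip_off))
      buf <- c(buf, raw[(strip_off[s] + 1):(strip_off[s] + strip_cnt[s])])
    n_px <- width * height
    v <- if (fmt == 3 && bits == 32)
      readBin(buf, "numeric", n = n_px, size = 4, endian = endian)
    else if (fmt == 3 && bits == 64)
      readBin(buf, "numeric", n = n_px, size = 8, endian = endian)
    else if (bits == 8) as.numeric(readBin(buf, "integer", n = n_px, size = 1,
                                           signed = FALSE, endian = endian))
    else if (bits == 16) as.numeric(readBin(buf, "integer", n = n_px, size = 2,
                                            signed = FALSE, endian = endian))
    else if (bits == 32) {
      x <- readBin(buf, "integer", n = n_px, size = 4, endian = endian)
      ifelse(x < 0, x + 2^32, as.numeric(x))
    } else stop_param("unsupported TIFF sample type (bits=%s, format=%s)", bits, fmt)
    pages[[length(pages) + 1L]] <- matrix(v, height, width, byrow = TRUE)
    ifd <- u32(ifd + 2 + n_entries * 12)
  }
  if (length(pages) == 1L) return(pages[[1]])
  arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  arr
}
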