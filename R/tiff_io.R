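## Minimal multi-page grayscale TIFF I/O.
##
## No TIFF package ships with the analysis stack this package targets, so the
## small subset needed here is implemented directly: baseline TIFF, little
## endian, one 8-bit grayscale sample per pixel, one strip per page,
## uncompressed, with X/Y resolution recording the pixel size (px per cm).

tiff_tag <- function(con, id, type, count, value) {
  writeBin(as.integer(id), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == 3L) { # SHORT: value left-justified in 4 bytes
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {          # LONG or offset
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

#' Write a frame stack as a multi-page grayscale TIFF
#'
#' Frames are quantised to 8 bits. Pixel size is stored in the TIFF
#' resolution tags (pixels per centimetre) and recovered by [read_tiff()].
#'
#' @param stack a [frame_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  con <- file(path, "wb")
  on.exit(close(con))
  H <- nrow(stack$frames[[1]]); W <- ncol(stack$frames[[1]])
  n <- length(stack$frames)
  res_ppcm <- as.integer(round(0.01 / stack$pixel_size))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  ## each page block: [data W*H][xres 8][yres 8][IFD 2 + 12*12 + 4]
  ifd_size <- 2L + 12L * 12L + 4L
  page_size <- as.integer(W * H + 16L + ifd_size)
  first_ifd <- as.integer(8L + W * H + 16L)
  writeBin(first_ifd, con, size = 4, endian = "little")
  for (p in seq_len(n)) {
    base <- as.integer(8L + (p - 1L) * page_size)
    vals <- as.integer(round(pmin(pmax(t(stack$frames[[p]]), 0), 1) * 255))
    writeBin(as.raw(vals), con)
    writeBin(c(res_ppcm, 1L), con, size = 4, endian = "little") # XResolution
    writeBin(c(res_ppcm, 1L), con, size = 4, endian = "little") # YResolution
    writeBin(12L, con, size = 2, endian = "little")             # tag count
    data_off <- base
    xres_off <- as.integer(base + W * H)
    yres_off <- as.integer(xres_off + 8L)
    tiff_tag(con, 256L, 4L, 1L, W)            # ImageWidth
    tiff_tag(con, 257L, 4L, 1L, H)            # ImageLength
    tiff_tag(con, 258L, 3L, 1L, 8L)           # BitsPerSample
    tiff_tag(con, 259L, 3L, 1L, 1L)           # Compression: none
    tiff_tag(con, 262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
    tiff_tag(con, 273L, 4L, 1L, data_off)     # StripOffsets
    tiff_tag(con, 277L, 3L, 1L, 1L)           # SamplesPerPixel
    tiff_tag(con, 278L, 4L, 1L, H)            # RowsPerStrip
    tiff_tag(con, 279L, 4L, 1L, W * H)        # StripByteCounts
    tiff_tag(con, 282L, 5L, 1L, xres_off)     # XResolution (RATIONAL)
    tiff_tag(con, 283L, 5L, 1L, yres_off)     # YResolution
    tiff_tag(con, 296L, 3L, 1L, 3L)           # ResolutionUnit: cm
    next_ifd <- if (p < n) as.integer(base + page_size + W * H + 16L) else 0L
    writeBin(next_ifd, con, size = 4, endian = "little")
  }
  invisible(path)
}

read_u16 <- function(raw, off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
read_u32 <- function(raw, off) {
  sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
}

#' Read a multi-page grayscale TIFF written by [write_tiff()]
#'
#' Supports baseline little-endian uncompressed 8-bit grayscale TIFFs with
#' contiguous strips (not a general-purpose TIFF reader).
#'
#' @param path file path.
#' @param timestamps optional frame times, s (default frame index - 1).
#' @return a [frame_stack()].
#' @export
read_tiff <- function(path, timestamps = NULL) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8 || rawToChar(raw[1:2]) != "II" || read_u16(raw, 2) != 42L) {
    stop_mfs("mfs_io_error", "not a little-endian TIFF: %s", path)
  }
  off <- read_u32(raw, 4)
  frames <- list()
  pixel_size <- NA_real_
  while (off != 0) {
    n_tags <- read_u16(raw, off)
    tags <- list()
    for (i in seq_len(n_tags)) {
      t_off <- off + 2 + (i - 1) * 12
      id <- read_u16(raw, t_off)
      type <- read_u16(raw, t_off + 2)
      val <- if (type == 3L) read_u16(raw, t_off + 8) else read_u32(raw, t_off + 8)
      tags[[as.character(id)]] <- val
    }
    W <- tags[["256"]]; H <- tags[["257"]]
    if (is.null(W) || is.null(H)) {
      stop_mfs("mfs_io_error", "malformed TIFF page in %s", path)
    }
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1) {
      stop_mfs("mfs_io_error", "compressed TIFF not supported: %s", path)
    }
    strip <- tags[["273"]]
    count <- tags[["279"]]
    if (!is.null(tags[["282"]])) {
      num <- read_u32(raw, tags[["282"]]); den <- read_u32(raw, tags[["282"]] + 4)
      if (num > 0) pixel_size <- 0.01 * den / num
    }
    vals <- as.integer(raw[strip + seq_len(count)]) / 255
    frames[[length(frames) + 1L]] <- t(matrix(vals, nrow = W, ncol = H))
    off <- read_u32(raw, off + 2 + n_tags * 12)
  }
  if (is.null(timestamps)) timestamps <- seq_along(frames) - 1
  if (is.na(pixel_size)) pixel_size <- 1e-6
  frame_stack(frames, pixel_size, timestamps)
}
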