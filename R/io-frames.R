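# Frame I/O.  The acquisition contract is 8-bit grayscale frames in
# uncompressed BMP (PNG accepted).  No image codec package is available in
# the target R stack, so minimal readers/writers for exactly these two
# encodings live here.  Anything else (color, 16-bit, compressed BMP) is
# rejected explicitly rather than silently converted.

#' Read an 8-bit grayscale frame (BMP or PNG)
#'
#' @param path File path; format chosen by magic bytes.
#' @return Integer matrix (rows x cols) with values 0-255.
#' @export
read_frame <- function(path) {
  con <- file(path, "rb")
  magic <- readBin(con, "raw", 8)
  close(con)
  if (length(magic) >= 2 && magic[1] == as.raw(0x42) && magic[2] == as.raw(0x4d)) {
    return(read_bmp_gray(path))
  }
  png_sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(magic) == 8 && all(magic == png_sig)) {
    return(read_png_gray(path))
  }
  # float TIFF frames: the synthetic instrument's quantization-free mode
  if (length(magic) >= 4 && magic[1] == as.raw(0x49) &&
      magic[2] == as.raw(0x49) && magic[3] == as.raw(0x2a)) {
    return(read_float_tiff(path)[[1]])
  }
  stop("unsupported frame format (need 8-bit grayscale BMP or PNG): ", path)
}

#' Write an 8-bit grayscale frame
#'
#' @param frame Integer/numeric matrix with values 0-255.
#' @param path Output path; extension `.bmp` or `.png` selects the format.
#' @export
write_frame <- function(frame, path) {
  if (any(frame < 0 | frame > 255)) stop("frame values must be in 0..255")
  ext <- tolower(tools::file_ext(path))
  if (ext == "bmp") write_bmp_gray(frame, path)
  else if (ext == "png") write_png_gray(frame, path)
  else if (ext %in% c("tif", "tiff")) write_float_tiff(frame, path)
  else stop("unsupported frame extension: ", ext)
  invisible(path)
}

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

read_bmp_gray <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  s32 <- function(off) { v <- u32(off); if (v >= 2^31) v - 2^32 else v }
  if (u32(30) != 0) stop("compressed BMP is not supported: ", path)
  bitcount <- u16(28)
  if (bitcount != 8) {
    stop(sprintf("unsupported BMP bit depth %d (need 8-bit grayscale): %s",
                 bitcount, path))
  }
  width <- s32(18)
  height_raw <- s32(22)
  topdown <- height_raw < 0
  height <- abs(height_raw)
  offset <- u32(10)
  # verify the palette is gray (r == g == b); a color-mapped 8-bit image
  # is not a grayscale frame
  pal_off <- 14 + u32(14)
  n_colors <- u32(46)
  if (n_colors == 0) n_colors <- 256
  pal <- matrix(as.integer(raw[pal_off + seq_len(4 * n_colors)]),
                ncol = 4, byrow = TRUE)
  if (!all(pal[, 1] == pal[, 2] & pal[, 2] == pal[, 3])) {
    stop("BMP has a color palette; only grayscale frames are supported: ", path)
  }
  stride <- 4 * ceiling(width / 4)
  px <- matrix(as.integer(raw[offset + seq_len(stride * height)]),
               nrow = stride)[seq_len(width), , drop = FALSE]
  img <- t(px)  # rows of the file become rows of the matrix
  if (!topdown) img <- img[rev(seq_len(height)), , drop = FALSE]
  # map through the (gray) palette in case it is not the identity ramp
  matrix(pal[img + 1L, 1L], nrow = height)
}

write_bmp_gray <- function(frame, path) {
  frame <- matrix(as.integer(round(frame)), nrow = nrow(frame))
  h <- nrow(frame); w <- ncol(frame)
  stride <- 4 * ceiling(w / 4)
  offset <- 14 + 40 + 1024
  filesize <- offset + stride * h
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x42, 0x4d)), con)                # "BM"
  writeBin(c(u32le(filesize), u16le(0), u16le(0), u32le(offset)), con)
  writeBin(c(u32le(40), u32le(w), u32le(h), u16le(1), u16le(8),
             u32le(0), u32le(stride * h), u32le(2835), u32le(2835),
             u32le(256), u32le(0)), con)
  pal <- as.raw(rbind(0:255, 0:255, 0:255, 0L))       # B,G,R,0 gray ramp
  writeBin(as.vector(pal), con)
  pad <- raw(stride - w)
  for (r in rev(seq_len(h))) {                         # bottom-up rows
    writeBin(c(as.raw(frame[r, ]), pad), con)
  }
  invisible(path)
}

# ---- PNG (grayscale, bit depth 8, color type 0) ----

crc32_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (is.null(crc32_env$tab)) {
    tab <- integer(256)
    poly <- -306674912L  # 0xEDB88320
    for (i in 0:255) {
      c <- i
      for (k in 1:8) {
        c <- if (bitwAnd(c, 1L) != 0L) {
          bitwXor(poly, bitwShiftR(c, 1L))
        } else bitwShiftR(c, 1L)
      }
      tab[i + 1L] <- c
    }
    crc32_env$tab <- tab
  }
  crc32_env$tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

u32be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216 %% 256, x %/% 65536 %% 256, x %/% 256 %% 256,
           x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- crc32(body)
  crc_raw <- writeBin(crc, raw(), size = 4, endian = "big")
  c(u32be(length(data)), body, crc_raw)
}

write_png_gray <- function(frame, path) {
  frame <- matrix(as.integer(round(frame)), nrow = nrow(frame))
  h <- nrow(frame); w <- ncol(frame)
  ihdr <- c(u32be(w), u32be(h), as.raw(c(8, 0, 0, 0, 0)))
  scan <- as.raw(rbind(0L, t(frame)))  # filter byte 0 before each row
  # memCompress(type = "gzip") emits a zlib stream (0x78 header + adler32),
  # which is exactly the PNG IDAT payload format
  idat <- memCompress(as.vector(scan), type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", idat), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

read_png_gray <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  pos <- 9L  # after signature
  width <- height <- NA_integer_
  idat <- raw(0)
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * 256^(3:0))
  repeat {
    len <- u32(pos - 1L)
    type <- rawToChar(raw[pos + 4:7])
    data <- if (len > 0) raw[pos + 7L + seq_len(len)] else raw(0)
    if (type == "IHDR") {
      width <- u32(pos + 7L)
      height <- u32(pos + 11L)
      bitdepth <- as.integer(data[9])
      colortype <- as.integer(data[10])
      if (bitdepth != 8 || colortype != 0) {
        stop(sprintf(
          "unsupported PNG (bit depth %d, color type %d); need 8-bit grayscale: %s",
          bitdepth, colortype, path))
      }
      if (as.integer(data[13]) != 0) stop("interlaced PNG not supported: ", path)
    } else if (type == "IDAT") {
      idat <- c(idat, data)
    } else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  scan <- memDecompress(idat, type = "gzip")
  stride <- width + 1L
  img <- matrix(0L, nrow = height, ncol = width)
  prev <- integer(width)
  for (r in seq_len(height)) {
    row_raw <- as.integer(scan[(r - 1L) * stride + seq_len(stride)])
    ft <- row_raw[1]
    d <- row_raw[-1]
    rec <- switch(as.character(ft),
      "0" = d,
      "1" = cumsum(d) %% 256L,
      "2" = (d + prev) %% 256L,
      "3" = {
        out <- integer(width)
        left <- 0L
        for (i in seq_len(width)) {
          out[i] <- (d[i] + (left + prev[i]) %/% 2L) %% 256L
          left <- out[i]
        }
        out
      },
      "4" = {
        out <- integer(width)
        left <- 0L; upleft <- 0L
        for (i in seq_len(width)) {
          up <- prev[i]
          p <- left + up - upleft
          pa <- abs(p - left); pb <- abs(p - up); pc <- abs(p - upleft)
          pred <- if (pa <= pb && pa <= pc) left else if (pb <= pc) up else upleft
          out[i] <- (d[i] + pred) %% 256L
          upleft <- up
          left <- out[i]
        }
        out
      },
      stop("unsupported PNG filter type ", ft, ": ", path))
    img[r, ] <- rec
    prev <- rec
  }
  img
}

# ---- 32-bit float TIFF (little-endian, one strip per page) ----

#' Write 2-D float maps as a multi-page 32-bit float TIFF
#'
#' Minimal baseline TIFF writer (uncompressed, IEEE float, one strip per
#' page) for exporting Rd and optical-property maps.
#'
#' @param maps A matrix or list of matrices (one page each).
#' @param path Output path.
#' @export
write_float_tiff <- function(maps, path) {
  if (is.matrix(maps)) maps <- list(maps)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x49, 0x49)), u16le(42)), con)
  # layout: [header 8][page1 data][page1 IFD][page2 data][page2 IFD]...
  offset <- 8
  data_offsets <- integer(0)
  ifd_offsets <- integer(0)
  n_entries <- 9L
  ifd_size <- 2 + n_entries * 12 + 4
  for (m in maps) {
    nbytes <- 4 * length(m)
    data_offsets <- c(data_offsets, offset)
    ifd_offsets <- c(ifd_offsets, offset + nbytes)
    offset <- offset + nbytes + ifd_size
  }
  writeBin(u32le(8 + 4 * length(maps[[1]])), con)  # first IFD offset
  entry <- function(tag, type, count, value) {
    c(u16le(tag), u16le(type), u32le(count), u32le(value))
  }
  for (k in seq_along(maps)) {
    m <- maps[[k]]
    # pixel data, row-major (rows of the matrix are image rows)
    writeBin(as.vector(t(m)), con, size = 4, endian = "little")
    next_ifd <- if (k < length(maps)) ifd_offsets[k + 1] else 0
    ifd <- c(u16le(n_entries),
             entry(256, 3, 1, ncol(m)),           # ImageWidth
             entry(257, 3, 1, nrow(m)),           # ImageLength
             entry(258, 3, 1, 32),                # BitsPerSample
             entry(259, 3, 1, 1),                 # Compression: none
             entry(262, 3, 1, 1),                 # Photometric: BlackIsZero
             entry(273, 4, 1, data_offsets[k]),   # StripOffsets
             entry(277, 3, 1, 1),                 # SamplesPerPixel
             entry(279, 4, 1, 4 * length(m)),     # StripByteCounts
             entry(339, 3, 1, 3),                 # SampleFormat: IEEE float
             u32le(next_ifd))
    writeBin(ifd, con)
  }
  invisible(path)
}

#' Read a multi-page float TIFF written by [write_float_tiff()]
#'
#' @param path File path.
#' @return List of numeric matrices.
#' @export
read_float_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (!(raw[1] == as.raw(0x49) && raw[2] == as.raw(0x49))) {
    stop("not a little-endian TIFF: ", path)
  }
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * 256^(0:3))
  ifd_off <- u32(4)
  pages <- list()
  while (ifd_off != 0) {
    n <- u16(ifd_off)
    tags <- list()
    for (e in seq_len(n) - 1L) {
      base <- ifd_off + 2 + 12 * e
      tags[[as.character(u16(base))]] <- u32(base + 8)
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    off <- tags[["273"]]
    vals <- readBin(raw[off + seq_len(4 * w * h)], "numeric", n = w * h,
                    size = 4, endian = "little")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, byrow = TRUE)
    ifd_off <- u32(ifd_off + 2 + 12 * n)
  }
  pages
}
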