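#' Minimal multi-page grayscale TIFF input/output
#'
#' The acquisition and segmentation stages exchange image data as plain,
#' uncompressed, little-endian baseline TIFF (grayscale, 8- or 16-bit
#' unsigned, one sample per pixel). No pre-built TIFF binding is assumed;
#' the subset implemented here is the one the pipeline writes and is
#' sufficient for ImageJ-style grayscale stacks saved without compression.
#'
#' Frame-rate and pixel-size metadata — on which every lifetime in the
#' downstream analysis depends — travel in a JSON sidecar `<path>.meta.json`
#' written next to the stack.
#'
#' @name tiff-io
NULL

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, rows_per_strip = 278L,
               strip_byte_counts = 279L, sample_format = 339L)

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' @param stack a numeric matrix (single image) or 3D array indexed
#'   `[frame, row, col]`. Values are rounded and clamped to the unsigned
#'   range of `bits`.
#' @param path output file path.
#' @param bits 8 or 16 (default 16).
#' @param pixel_size_nm,frame_rate_hz metadata written to the JSON sidecar;
#'   either may be `NULL` to omit.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L,
                        pixel_size_nm = NULL, frame_rate_hz = NULL) {
  check_that(bits %in% c(8L, 16L), "bits must be 8 or 16")
  if (is.matrix(stack)) {
    stack <- array(stack, dim = c(1L, nrow(stack), ncol(stack)))
  }
  check_that(length(dim(stack)) == 3L, "stack must be a matrix or 3D array")
  n_frames <- dim(stack)[1]
  nr <- dim(stack)[2]
  nc <- dim(stack)[3]
  maxval <- 2^bits - 1
  bytes_px <- as.integer(bits) %/% 8L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  # first IFD offset placeholder, patched after layout is known
  header_end <- 8L
  writeBin(header_end, con, size = 4, endian = "little")

  # layout: [header][page1 data][page1 IFD][page2 data][page2 IFD]...
  n_tags <- length(TIFF_TAGS)
  ifd_size <- 2L + n_tags * 12L + 4L
  data_size <- nr * nc * bytes_px
  offs_data <- integer(n_frames)
  offs_ifd <- integer(n_frames)
  pos <- as.integer(header_end)
  for (f in seq_len(n_frames)) {
    offs_data[f] <- pos
    offs_ifd[f] <- pos + as.integer(data_size)
    pos <- pos + as.integer(data_size) + ifd_size
  }
  # patch first-IFD offset
  seek(con, 4, rw = "write")
  writeBin(as.integer(offs_ifd[1]), con, size = 4, endian = "little")
  seek(con, header_end, rw = "write")

  write_tag <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT, left-justified in the 4-byte slot
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }

  for (f in seq_len(n_frames)) {
    img <- stack[f, , , drop = TRUE]
    if (!is.matrix(img)) img <- matrix(img, nr, nc)
    v <- as.integer(pmin(pmax(round(img), 0), maxval))
    # TIFF stores rows of pixels; R matrices are column-major -> transpose
    writeBin(as.vector(t(matrix(v, nr, nc))), con,
             size = bytes_px, endian = "little")
    writeBin(n_tags, con, size = 2, endian = "little")
    write_tag(256L, 3L, 1L, nc)
    write_tag(257L, 3L, 1L, nr)
    write_tag(258L, 3L, 1L, bits)
    write_tag(259L, 3L, 1L, 1L)          # no compression
    write_tag(262L, 3L, 1L, 1L)          # BlackIsZero
    write_tag(273L, 4L, 1L, offs_data[f])
    write_tag(278L, 3L, 1L, nr)
    write_tag(279L, 4L, 1L, data_size)
    write_tag(339L, 3L, 1L, 1L)          # unsigned integer samples
    next_ifd <- if (f < n_frames) offs_ifd[f + 1] else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }

  meta <- list(pixel_size_nm = pixel_size_nm, frame_rate_hz = frame_rate_hz,
               n_frames = n_frames, height_px = nr, width_px = nc,
               bits = bits, schema = "irclusters-stack-1")
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_uint <- function(con, size) {
  if (size == 2) {
    readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  } else {
    v <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (v < 0) v <- v + 2^32
    v
  }
}

#' Read a multi-page grayscale TIFF stack
#'
#' Supports the uncompressed, little-endian grayscale subset written by
#' [write_stack()] (and by ImageJ "save as TIFF" without compression):
#' 8- or 16-bit unsigned, one sample per pixel, any strip layout.
#'
#' @param path TIFF file path.
#' @param pixel_size_nm,frame_rate_hz override/provide metadata; when `NULL`
#'   the values must be present in the `<path>.meta.json` sidecar, otherwise
#'   reading fails (downstream lifetimes depend on them).
#' @param require_metadata set `FALSE` to read pixel data without metadata.
#' @return a list of class `frame_stack`: `data` (3D array
#'   `[frame, row, col]`, double), `pixel_size_nm`, `frame_rate_hz`, `bits`.
#' @export
read_stack <- function(path, pixel_size_nm = NULL, frame_rate_hz = NULL,
                       require_metadata = TRUE) {
  check_that(file.exists(path), "no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2))
  check_that(magic == "II", "only little-endian TIFF is supported")
  check_that(read_uint(con, 2) == 42, "not a TIFF file: ", path)
  ifd_off <- read_uint(con, 4)

  pages <- list()
  while (ifd_off != 0) {
    seek(con, ifd_off)
    n_tags <- read_uint(con, 2)
    tags <- list()
    for (k in seq_len(n_tags)) {
      tag <- read_uint(con, 2)
      type <- read_uint(con, 2)
      count <- read_uint(con, 4)
      type_size <- c(`1` = 1, `3` = 2, `4` = 4)[as.character(type)]
      if (is.na(type_size)) { readBin(con, "raw", 4); next }
      here <- seek(con)  # position after reading the value slot
      if (count * type_size <= 4) {
        vals <- vapply(seq_len(count), function(i) {
          read_uint(con, max(type_size, 2))
        }, numeric(1))
        seek(con, here + 4)
      } else {
        off <- read_uint(con, 4)
        at <- seek(con)
        seek(con, off)
        vals <- vapply(seq_len(count), function(i) {
          read_uint(con, max(type_size, 2))
        }, numeric(1))
        seek(con, at)
      }
      tags[[as.character(tag)]] <- vals
    }
    next_off <- read_uint(con, 4)
    pages[[length(pages) + 1L]] <- tags
    ifd_off <- next_off
  }
  check_that(length(pages) > 0, "TIFF contains no images")

  g <- function(tags, id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) default else v
  }
  nc <- g(pages[[1]], 256L)
  nr <- g(pages[[1]], 257L)
  bits <- g(pages[[1]], 258L, 1)
  check_that(bits %in% c(8, 16), "only 8/16-bit grayscale TIFF is supported")
  out <- array(0, dim = c(length(pages), nr, nc))
  for (f in seq_along(pages)) {
    tags <- pages[[f]]
    check_that(identical(g(tags, 259L, 1), 1), "compressed TIFF not supported")
    offs <- g(tags, 273L)
    counts <- g(tags, 279L, nr * nc * bits / 8)
    px <- numeric(0)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      nval <- counts[s] / (bits / 8)
      v <- readBin(con, "integer", nval, size = bits / 8, signed = FALSE,
                   endian = "little")
      px <- c(px, v)
    }
    out[f, , ] <- matrix(px, nr, nc, byrow = TRUE)
  }

  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (is.null(pixel_size_nm)) {
      pixel_size_nm <- as.numeric(meta$pixel_size_nm)
    }
    if (is.null(frame_rate_hz)) {
      frame_rate_hz <- as.numeric(meta$frame_rate_hz)
    }
  }
  if (require_metadata) {
    check_that(is_number(pixel_size_nm, 0, strict = TRUE) &&
                 is_number(frame_rate_hz, 0, strict = TRUE),
               "pixel_size_nm and frame_rate_hz must come from the sidecar ",
               "or be given explicitly; refusing to guess (lifetimes depend ",
               "on them)")
  }
  structure(list(data = out, pixel_size_nm = pixel_size_nm,
                 frame_rate_hz = frame_rate_hz, bits = bits),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<frame_stack> %d frame(s), %d x %d px, %s-bit\n",
              d[1], d[2], d[3], x$bits))
  if (!is.null(x$pixel_size_nm)) {
    cat(sprintf("  pixel %g nm, %g Hz\n", x$pixel_size_nm,
                if (is.null(x$frame_rate_hz)) NA else x$frame_rate_hz))
  }
  invisible(x)
}
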