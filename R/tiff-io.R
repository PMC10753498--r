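# Minimal baseline TIFF I/O for single-channel image stacks.
#
# No TIFF reader ships with this R stack, so the package carries its own
# baseline implementation: uncompressed, grayscale, little- or big-endian on
# read, little-endian on write, uint8/uint16/float32 sample formats, one or
# more strips per page, multi-page (frame order = time). This covers the
# files the pipeline itself writes and the plain exports of common
# acquisition software; compressed or tiled TIFF is out of scope.

TIFF_TAGS <- c(
  width = 256L, length = 257L, bits = 258L, compression = 259L,
  photometric = 262L, strip_offsets = 273L, samples_per_pixel = 277L,
  rows_per_strip = 278L, strip_byte_counts = 279L, sample_format = 339L
)

#' Write an image stack as a multi-page grayscale TIFF
#'
#' @param frames A numeric matrix, a list of matrices, or a 3D array
#'   (row, col, frame). Values are expected in `[0, 1]` for integer modes.
#' @param path Output file.
#' @param format `"uint16"` (default), `"uint8"`, or `"float32"`. Integer
#'   modes scale `[0, 1]` to the full range; `float32` stores values as-is.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(frames, path, format = c("uint16", "uint8", "float32")) {
  format <- match.arg(format)
  frames <- as_frame_list(frames)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  offset_pos <- 4L
  writeBin(0L, con, size = 4, endian = "little")  # placeholder: first IFD
  pos <- 8L
  prev_link <- offset_pos
  for (f in frames) {
    nr <- nrow(f); nc <- ncol(f)
    if (format == "float32") {
      bits <- 32L; fmt <- 3L
      payload <- as.numeric(t(f))
      bytes_per <- 4L
    } else {
      bits <- if (format == "uint16") 16L else 8L
      fmt <- 1L
      maxv <- 2^bits - 1
      payload <- as.integer(round(pmin(pmax(t(f), 0), 1) * maxv))
      bytes_per <- bits %/% 8L
    }
    nbytes <- nr * nc * bytes_per
    data_off <- pos
    # strip data
    seek(con, data_off, rw = "write")
    if (format == "float32") {
      writeBin(payload, con, size = 4, endian = "little")
    } else {
      writeBin(payload, con, size = bytes_per, endian = "little")
    }
    ifd_off <- data_off + nbytes
    if (ifd_off %% 2 == 1) { writeBin(as.raw(0), con); ifd_off <- ifd_off + 1L }
    # patch previous IFD link
    seek(con, prev_link, rw = "write")
    writeBin(as.integer(ifd_off), con, size = 4, endian = "little")
    seek(con, ifd_off, rw = "write")
    entries <- list(
      c(TIFF_TAGS[["width"]], 3L, 1L, nc),
      c(TIFF_TAGS[["length"]], 3L, 1L, nr),
      c(TIFF_TAGS[["bits"]], 3L, 1L, bits),
      c(TIFF_TAGS[["compression"]], 3L, 1L, 1L),
      c(TIFF_TAGS[["photometric"]], 3L, 1L, 1L),
      c(TIFF_TAGS[["strip_offsets"]], 4L, 1L, data_off),
      c(TIFF_TAGS[["samples_per_pixel"]], 3L, 1L, 1L),
      c(TIFF_TAGS[["rows_per_strip"]], 3L, 1L, nr),
      c(TIFF_TAGS[["strip_byte_counts"]], 4L, 1L, nbytes),
      c(TIFF_TAGS[["sample_format"]], 3L, 1L, fmt)
    )
    writeBin(length(entries), con, size = 2, endian = "little")
    for (e in entries) {
      writeBin(as.integer(e[1]), con, size = 2, endian = "little")
      writeBin(as.integer(e[2]), con, size = 2, endian = "little")
      writeBin(as.integer(e[3]), con, size = 4, endian = "little")
      if (e[2] == 3L) {  # SHORT: value left-justified in 4-byte field
        writeBin(as.integer(e[4]), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(e[4]), con, size = 4, endian = "little")
      }
    }
    prev_link <- ifd_off + 2L + length(entries) * 12L
    writeBin(0L, con, size = 4, endian = "little")  # next-IFD placeholder
    pos <- prev_link + 4L
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF written by [write_tiff()] or similar
#'
#' Supports uncompressed single-sample pages, uint8/uint16/float32, both byte
#' orders, and multiple strips per page.
#'
#' @param path TIFF file.
#' @param rescale Divide integer samples by their type maximum so intensities
#'   land in `[0, 1]` (default `TRUE`); float samples are never rescaled.
#' @return A list of numeric matrices, one per page.
#' @export
read_tiff <- function(path, rescale = TRUE) {
  raw <- readBin(path, "raw", file.info(path)$size)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    stop("not a TIFF file: ", path)
  get_int <- function(off, size) {
    readBin(raw[(off + 1):(off + size)], "integer", n = 1, size = size,
            endian = endian, signed = size >= 4)
  }
  magic <- get_int(2, 2)
  if (magic != 42L) stop("not a baseline TIFF: ", path)
  ifd <- get_int(4, 4)
  frames <- list()
  while (ifd != 0) {
    n_entries <- get_int(ifd, 2)
    tags <- list()
    for (i in seq_len(n_entries)) {
      base <- ifd + 2 + (i - 1) * 12
      tag <- get_int(base, 2)
      type <- get_int(base + 2, 2)
      count <- get_int(base + 4, 4)
      val_off <- base + 8
      sz <- c(1L, 1L, 2L, 4L)[match(type, c(1L, 2L, 3L, 4L))]
      if (is.na(sz)) next
      vals <- if (count * sz <= 4) {
        vapply(seq_len(count), function(k) get_int(val_off + (k - 1) * sz, sz), 0)
      } else {
        ptr <- get_int(val_off, 4)
        vapply(seq_len(count), function(k) get_int(ptr + (k - 1) * sz, sz), 0)
      }
      tags[[as.character(tag)]] <- vals
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop("missing TIFF tag ", tag)
        default
      } else v
    }
    if (need(TIFF_TAGS[["compression"]], 1L)[1] != 1L)
      stop("compressed TIFF not supported")
    if (need(TIFF_TAGS[["samples_per_pixel"]], 1L)[1] != 1L)
      stop("multi-sample (color/channel-interleaved) TIFF not supported; ",
           "supply one single-channel file per channel")
    nc <- need(TIFF_TAGS[["width"]])[1]
    nr <- need(TIFF_TAGS[["length"]])[1]
    bits <- need(TIFF_TAGS[["bits"]], 1L)[1]
    fmt <- need(TIFF_TAGS[["sample_format"]], 1L)[1]
    offs <- need(TIFF_TAGS[["strip_offsets"]])
    counts <- need(TIFF_TAGS[["strip_byte_counts"]])
    buf <- raw(0)
    for (k in seq_along(offs))
      buf <- c(buf, raw[(offs[k] + 1):(offs[k] + counts[k])])
    if (fmt == 3L && bits == 32L) {
      v <- readBin(buf, "numeric", n = nr * nc, size = 4, endian = endian)
    } else if (fmt %in% c(1L, 2L) && bits %in% c(8L, 16L)) {
      v <- readBin(buf, "integer", n = nr * nc, size = bits %/% 8,
                   endian = endian, signed = FALSE)
      if (rescale) v <- v / (2^bits - 1)
    } else stop("unsupported TIFF sample format (bits=", bits, ", fmt=", fmt, ")")
    frames[[length(frames) + 1]] <- matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
    ifd <- get_int(ifd + 2 + n_entries * 12, 4)
  }
  frames
}

as_frame_list <- function(frames) {
  if (is.matrix(frames)) return(list(frames))
  if (is.array(frames) && length(dim(frames)) == 3)
    return(lapply(seq_len(dim(frames)[3]), function(k) frames[, , k]))
  stopifnot(is.list(frames), all(vapply(frames, is.matrix, TRUE)))
  frames
}
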