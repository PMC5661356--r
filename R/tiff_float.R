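# Minimal multi-page float32 TIFF writer.
#
# The tiff package reads IEEE-float TIFFs of any range, but its writer only
# stores values reliably inside [0, 1] (out-of-range storage is documented
# as undefined), which makes it unusable for raw fluorescence intensities.
# Writing an uncompressed single-sample float TIFF is simple enough to do
# directly; files written here are read back with tiff::readTIFF.

write_float_tiff <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1L, all(vapply(pages, is.matrix, logical(1))))
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  n <- length(pages)
  page_bytes <- 4L * h * w
  ifd_bytes <- 2L + 12L * 10L + 4L
  data_off <- 8L + (seq_len(n) - 1L) * page_bytes
  ifd_off <- 8L + n * page_bytes + (seq_len(n) - 1L) * ifd_bytes

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)                      # little-endian
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(ifd_off[1], con, size = 4L, endian = "little")
  for (p in seq_len(n)) {
    stopifnot(nrow(pages[[p]]) == h, ncol(pages[[p]]) == w)
    writeBin(as.numeric(t(pages[[p]])), con, size = 4L, endian = "little")
  }
  tag <- function(code, type, count, value) {
    writeBin(as.integer(code), con, size = 2L, endian = "little")
    writeBin(as.integer(type), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    if (type == 3L) {                                  # SHORT, inline
      writeBin(as.integer(value), con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {                                           # LONG, inline
      writeBin(as.integer(value), con, size = 4L, endian = "little")
    }
  }
  for (p in seq_len(n)) {
    writeBin(10L, con, size = 2L, endian = "little")   # tag count
    tag(256L, 3L, 1L, w)                               # ImageWidth
    tag(257L, 3L, 1L, h)                               # ImageLength
    tag(258L, 3L, 1L, 32L)                             # BitsPerSample
    tag(259L, 3L, 1L, 1L)                              # Compression: none
    tag(262L, 3L, 1L, 1L)                              # Photometric: min-is-black
    tag(273L, 4L, 1L, data_off[p])                     # StripOffsets
    tag(277L, 3L, 1L, 1L)                              # SamplesPerPixel
    tag(278L, 3L, 1L, h)                               # RowsPerStrip
    tag(279L, 4L, 1L, page_bytes)                      # StripByteCounts
    tag(339L, 3L, 1L, 3L)                              # SampleFormat: IEEE float
    nxt <- if (p < n) ifd_off[p + 1L] else 0L
    writeBin(nxt, con, size = 4L, endian = "little")
  }
  invisible(path)
}
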