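# Minimal BMP support: scanner elastograms are exported as uncompressed
# 24-bit BMP screenshots; no dependency provides a BMP codec, so the format
# is parsed directly (BITMAPINFOHEADER, BGR pixel order, 4-byte row padding,
# bottom-up or top-down row order).

int_le <- function(r, i, size = 4L) {
  readBin(r[i:(i + size - 1L)], "integer", n = 1L, size = size,
          endian = "little", signed = TRUE)
}

read_bmp <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 14L)
  if (length(hdr) < 14L || rawToChar(hdr[1:2]) != "BM") {
    stop("not a BMP file: ", path)
  }
  data_offset <- int_le(hdr, 11L)
  ih <- readBin(con, "raw", 40L)
  w <- int_le(ih, 5L)
  h_raw <- int_le(ih, 9L)
  bpp <- int_le(ih, 15L, 2L)
  compression <- int_le(ih, 17L)
  if (bpp != 24L || compression != 0L) {
    stop("only uncompressed 24-bit BMP images are supported: ", path)
  }
  h <- abs(h_raw)
  bottom_up <- h_raw > 0
  row_bytes <- ((w * 3L + 3L) %/% 4L) * 4L
  seek(con, data_offset)
  data <- readBin(con, "raw", row_bytes * h)
  m <- matrix(as.integer(data), nrow = row_bytes)  # one column per file row
  arr <- array(0L, c(h, w, 3L))
  rows <- if (bottom_up) h:1 else 1:h
  arr[rows, , 1L] <- t(m[seq(3L, w * 3L, 3L), , drop = FALSE])  # R
  arr[rows, , 2L] <- t(m[seq(2L, w * 3L, 3L), , drop = FALSE])  # G
  arr[rows, , 3L] <- t(m[seq(1L, w * 3L, 3L), , drop = FALSE])  # B
  arr
}

write_bmp <- function(rgb, path) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  row_bytes <- ((w * 3L + 3L) %/% 4L) * 4L
  pad <- row_bytes - w * 3L
  px <- raw(row_bytes * h)
  k <- 0L
  for (i in h:1) {  # bottom-up row order
    row <- as.raw(as.integer(t(cbind(rgb[i, , 3L], rgb[i, , 2L],
                                     rgb[i, , 1L]))))
    px[k + seq_along(row)] <- row
    k <- k + row_bytes
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(c(54L + length(px), 0L, 54L), con, size = 4L, endian = "little")
  writeBin(c(40L, w, h), con, size = 4L, endian = "little")
  writeBin(c(1L, 24L), con, size = 2L, endian = "little")
  writeBin(c(0L, length(px), 2835L, 2835L, 0L, 0L), con, size = 4L,
           endian = "little")
  writeBin(px, con)
  invisible(path)
}
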