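# Minimal 16-bit grayscale PNG encoder, used only to create read-side test
# fixtures (the png package writes 8-bit). Chunks are assembled by hand:
# CRC32 table-driven, deflate stream recycled from memCompress's gzip output
# with a zlib header and an Adler-32 trailer.

crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L)) bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1))
           else bitwShiftR(bitwAnd(c, -2L), 1)
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L
  for (b in as.integer(bytes))
    c <- bitwXor(crc32_table[bitwAnd(bitwXor(c, b), 255L) + 1L],
                 bitwShiftR(bitwAnd(c, -256L), 8))
  bitwXor(c, -1L)
}

int_be <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(int_be(length(data)), body, int_be(crc32(body)))
}

# R's memCompress(type = "gzip") emits a zlib-wrapped stream (0x78 header,
# Adler-32 trailer), which is exactly what a PNG IDAT chunk holds
zlib_compress <- function(bytes) memCompress(bytes, type = "gzip")

# m: integer matrix with values in [0, 65535]
write_png16 <- function(m, path) {
  w <- ncol(m); h <- nrow(m)
  ihdr <- c(int_be(w), int_be(h), as.raw(c(16, 0, 0, 0, 0)))
  rows <- lapply(seq_len(h), function(i) {
    v <- as.integer(m[i, ])
    c(as.raw(0), as.raw(rbind(v %/% 256L, v %% 256L)))
  })
  idat <- zlib_compress(do.call(c, rows))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
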