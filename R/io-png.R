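# Minimal PNG codec: 8-bit RGB, no interlace, filter type 0 scanlines,
# deflate via the system zlib. Covers exactly the tiles this package
# writes; read_png() rejects anything else with a clear error rather than
# guessing.

.cp_u32be <- function(x) {
  as.raw(c(x %/% 16777216 %% 256, x %/% 65536 %% 256,
           x %/% 256 %% 256, x %% 256))
}

.cp_be32_to_num <- function(b) {
  sum(as.double(as.integer(b)) * c(16777216, 65536, 256, 1))
}

.cp_png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(.cp_u32be(length(data)), body, .cp_u32be(cp_crc32(body)))
}

#' Write / read an RGB image as PNG
#'
#' A deliberately small codec for the package's own tiles: 8-bit RGB,
#' filter 0, single IDAT. `read_png` understands only files in this
#' dialect (which includes everything `write_png` produces).
#'
#' @param img `H x W x 3` numeric array in `[0, 1]`.
#' @param path file path.
#' @return `read_png` returns an `H x W x 3` array in `[0, 1]`.
#' @export
write_png <- function(img, path) {
  d <- dim(img)
  if (length(d) != 3 || d[3] != 3)
    stop("write_png: need an H x W x 3 array")
  H <- d[1]; W <- d[2]
  bytes <- as.raw(round(pmin(pmax(img, 0), 1) * 255))
  dim(bytes) <- d
  # scanlines: per row, pixels left to right, channels interleaved
  interleaved <- aperm(bytes, c(3, 2, 1))
  scan <- rbind(matrix(as.raw(0), 1, H),
                matrix(interleaved, nrow = 3 * W, ncol = H))
  ihdr <- c(.cp_u32be(W), .cp_u32be(H), as.raw(c(8, 2, 0, 0, 0)))
  idat <- cp_zlib_compress(as.raw(scan), 6L)
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           .cp_png_chunk("IHDR", ihdr),
           .cp_png_chunk("IDAT", idat),
           .cp_png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' @rdname write_png
#' @export
read_png <- function(path) {
  b <- readBin(path, "raw", file.size(path))
  sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(b) < 8 || !identical(b[1:8], sig))
    stop("read_png: not a PNG file: ", path)
  pos <- 9
  W <- H <- NULL
  idat <- raw(0)
  while (pos + 7 <= length(b)) {
    len <- .cp_be32_to_num(b[pos:(pos + 3)])
    type <- rawToChar(b[(pos + 4):(pos + 7)])
    data <- if (len > 0) b[(pos + 8):(pos + 7 + len)] else raw(0)
    if (type == "IHDR") {
      W <- .cp_be32_to_num(data[1:4])
      H <- .cp_be32_to_num(data[5:8])
      if (as.integer(data[9]) != 8 || as.integer(data[10]) != 2 ||
          as.integer(data[13]) != 0)
        stop("read_png: only 8-bit RGB non-interlaced PNG is supported")
    } else if (type == "IDAT") {
      idat <- c(idat, data)
    } else if (type == "IEND") break
    pos <- pos + 12 + len
  }
  if (is.null(W)) stop("read_png: missing IHDR")
  scan <- cp_zlib_uncompress(idat, H * (1 + 3 * W))
  dim(scan) <- c(1 + 3 * W, H)
  filters <- as.integer(scan[1, ])
  if (any(filters != 0))
    stop("read_png: unsupported scanline filter type ",
         filters[filters != 0][1])
  body <- scan[-1, , drop = FALSE]
  arr <- aperm(array(as.integer(body), c(3, W, H)), c(3, 2, 1)) / 255
  arr
}
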