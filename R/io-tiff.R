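# Minimal TIFF codec for heatmap persistence: uncompressed 32-bit float
# grayscale, one page (IFD) per class channel, little-endian, single strip
# per page. A JSON sidecar carries the class names, sizes and scale
# factor. As with the PNG codec, read_heatmap understands exactly the
# dialect write_heatmap emits.

.cp_tiff_entry <- function(tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG; value fits inline (<= 4 bytes)
  con <- raw(12)
  con[1:2] <- writeBin(as.integer(tag), raw(), size = 2,
                       endian = "little")
  con[3:4] <- writeBin(as.integer(type), raw(), size = 2,
                       endian = "little")
  con[5:8] <- writeBin(as.integer(count), raw(), size = 4,
                       endian = "little")
  con[9:12] <- if (type == 3)
    c(writeBin(as.integer(value), raw(), size = 2, endian = "little"),
      as.raw(c(0, 0)))
  else writeBin(as.integer(value), raw(), size = 4, endian = "little")
  con
}

#' Persist heatmaps as multi-page float TIFF with a JSON sidecar
#'
#' One grayscale 32-bit float page per class channel, plus
#' `<path>.json` recording `classes` (names, diameters, sigmas) and
#' `scale_factor`.
#'
#' @param heatmap a `cp_heatmap`.
#' @param path output `.tif` path.
#' @return `read_heatmap` returns the reconstructed `cp_heatmap`.
#' @export
write_heatmap <- function(heatmap, path) {
  stopifnot(inherits(heatmap, "cp_heatmap"))
  vals <- unclass(heatmap)
  H <- dim(vals)[1]; W <- dim(vals)[2]; C <- dim(vals)[3]
  strip_len <- W * H * 4
  ifd_len <- 2 + 10 * 12 + 4
  data_off <- 8 + (seq_len(C) - 1) * strip_len
  ifd_off <- 8 + C * strip_len + (seq_len(C) - 1) * ifd_len
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off[1]), con, size = 4, endian = "little")
  for (ci in seq_len(C))
    writeBin(as.numeric(t(vals[, , ci])), con, size = 4,
             endian = "little")
  for (ci in seq_len(C)) {
    writeBin(as.integer(10), con, size = 2, endian = "little")
    writeBin(.cp_tiff_entry(256, 4, 1, W), con)
    writeBin(.cp_tiff_entry(257, 4, 1, H), con)
    writeBin(.cp_tiff_entry(258, 3, 1, 32), con)
    writeBin(.cp_tiff_entry(259, 3, 1, 1), con)
    writeBin(.cp_tiff_entry(262, 3, 1, 1), con)
    writeBin(.cp_tiff_entry(273, 4, 1, data_off[ci]), con)
    writeBin(.cp_tiff_entry(277, 3, 1, 1), con)
    writeBin(.cp_tiff_entry(278, 4, 1, H), con)
    writeBin(.cp_tiff_entry(279, 4, 1, strip_len), con)
    writeBin(.cp_tiff_entry(339, 3, 1, 3), con)
    nxt <- if (ci < C) ifd_off[ci + 1] else 0
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  classes <- attr(heatmap, "classes")
  side <- list(class_names = attr(heatmap, "class_names"),
               scale_factor = attr(heatmap, "scale_factor"))
  if (!is.null(classes)) {
    side$diameter_px <- classes$diameter_px
    side$sigma_px <- classes$sigma_px
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.cp_rd <- function(b, off, size) {
  readBin(b[(off + 1):(off + size)], "integer", size = size,
          endian = "little", signed = size == 4)
}

#' @rdname write_heatmap
#' @export
read_heatmap <- function(path) {
  b <- readBin(path, "raw", file.size(path))
  if (rawToChar(b[1:2]) != "II" || .cp_rd(b, 2, 2) != 42)
    stop("read_heatmap: not a little-endian TIFF: ", path)
  off <- .cp_rd(b, 4, 4)
  pages <- list()
  while (off != 0) {
    n <- .cp_rd(b, off, 2)
    tags <- list()
    for (i in seq_len(n)) {
      e <- off + 2 + (i - 1) * 12
      tag <- .cp_rd(b, e, 2)
      type <- .cp_rd(b, e + 2, 2)
      val <- if (type == 3) .cp_rd(b, e + 8, 2) else .cp_rd(b, e + 8, 4)
      tags[[as.character(tag)]] <- val
    }
    if (is.null(tags[["258"]]) || tags[["258"]] != 32 ||
        !identical(tags[["259"]], 1L) || !identical(tags[["339"]], 3L))
      stop("read_heatmap: only the package's float32 TIFF dialect is read")
    W <- tags[["256"]]; H <- tags[["257"]]
    strip <- tags[["273"]]
    v <- readBin(b[(strip + 1):(strip + W * H * 4)], "numeric",
                 n = W * H, size = 4, endian = "little")
    pages[[length(pages) + 1]] <- matrix(v, H, W, byrow = TRUE)
    off <- .cp_rd(b, off + 2 + n * 12, 4)
  }
  arr <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (ci in seq_along(pages)) arr[, , ci] <- pages[[ci]]
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  classes <- if (!is.null(side$diameter_px))
    class_config(side$class_names, side$diameter_px, side$sigma_px)
  else side$class_names
  heatmap_tensor(pmin(pmax(arr, 0), 1), classes, side$scale_factor)
}
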