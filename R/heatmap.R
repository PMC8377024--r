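#' Heatmap tensors
#'
#' A heatmap tensor is an `H x W x C` array of values in `[0, 1]`, one
#' channel per cell class, used both for Gaussian training targets and for
#' network predictions. `scale_factor` is the number of native tile pixels
#' per heatmap pixel (4 for 1024-px tiles encoded at 256). Row index is y,
#' column index is x (both 1-based internally; coordinates in annotation and
#' prediction tables stay 0-based).
#'
#' @param values `H x W x C` numeric array in `[0, 1]`.
#' @param classes `cp_class_config` (native-scale sizes) or character names.
#' @param scale_factor native pixels per heatmap pixel.
#' @return A `cp_heatmap`.
#' @export
heatmap_tensor <- function(values, classes, scale_factor = 1) {
  if (length(dim(values)) != 3)
    stop("heatmap_tensor: values must be an H x W x C array")
  cls_names <- if (inherits(classes, "cp_class_config"))
    classes$cell_class else as.character(classes)
  if (dim(values)[3] != length(cls_names))
    stop("heatmap_tensor: channel count differs from class count")
  if (min(values) < 0 || max(values) > 1)
    stop("heatmap_tensor: values outside [0, 1]")
  structure(values, class = "cp_heatmap",
            classes = if (inherits(classes, "cp_class_config")) classes
                      else NULL,
            class_names = cls_names, scale_factor = scale_factor)
}

#' Encode consensus centre points as Gaussian heatmap targets
#'
#' Each annotation of class c at native `(x0, y0)` contributes an isotropic
#' 2-D Gaussian kernel `exp(-((x - x0')^2 + (y - y0')^2) / (2 sigma'^2))` on
#' channel c, where primed quantities are divided by `scale_factor`. The
#' kernel is evaluated at the real-valued rescaled centre (no rounding), is
#' truncated beyond `4 sigma'` (values < 3.4e-4 written as 0), and
#' overlapping kernels combine by element-wise maximum so every centre keeps
#' a peak of 1. The heatmap pixel nearest the centre is set to exactly 1:
#' the focal loss identifies centre pixels by `Y == 1`.
#'
#' @param consensus a `cp_annotations` (typically the consensus set).
#' @param classes `cp_class_config` with native-scale `sigma_px`.
#' @param out_size heatmap side length in pixels (square).
#' @param scale_factor native pixels per heatmap pixel;
#'   `out_size * scale_factor` must equal the native tile size.
#' @return A `cp_heatmap` of dimension `out_size x out_size x n_classes`.
#' @export
encode_targets <- function(consensus, classes, out_size,
                           scale_factor = consensus$tile_width / out_size) {
  stopifnot(inherits(consensus, "cp_annotations"))
  if (abs(out_size * scale_factor - consensus$tile_width) > 1e-6 ||
      abs(out_size * scale_factor - consensus$tile_height) > 1e-6)
    stop("encode_targets: out_size x scale_factor must match the tile size")
  cls <- classes$cell_class
  Y <- array(0, dim = c(out_size, out_size, length(cls)))
  ann <- consensus$annotations
  for (i in seq_len(nrow(ann))) {
    c_i <- match(ann$cell_class[i], cls)
    if (is.na(c_i)) stop("encode_targets: unannotated class ",
                         ann$cell_class[i])
    sig <- classes$sigma_px[c_i] / scale_factor
    if (!is.finite(sig) || sig <= 0)
      stop("encode_targets: non-positive sigma for class ", cls[c_i])
    x0 <- ann$x[i] / scale_factor
    y0 <- ann$y[i] / scale_factor
    r <- ceiling(4 * sig)
    xs <- max(0, floor(x0 - r)):min(out_size - 1, ceiling(x0 + r))
    ys <- max(0, floor(y0 - r)):min(out_size - 1, ceiling(y0 + r))
    k <- outer(exp(-(ys - y0)^2 / (2 * sig^2)),
               exp(-(xs - x0)^2 / (2 * sig^2)))
    k[k < exp(-8)] <- 0  # 4-sigma truncation
    sl <- Y[ys + 1, xs + 1, c_i]
    Y[ys + 1, xs + 1, c_i] <- pmax(sl, k)
    # exact-1 centre pixel (nearest pixel to the real-valued centre)
    cx <- min(max(round(x0), 0), out_size - 1)
    cy <- min(max(round(y0), 0), out_size - 1)
    Y[cy + 1, cx + 1, c_i] <- 1
  }
  heatmap_tensor(Y, classes, scale_factor)
}

# regional maxima of `vals` at cluster pixels (py, px 0-based), greedily
# thinned so accepted maxima are >= min_sep apart (descending value).
.cp_regional_maxima <- function(ch, py, px, min_sep) {
  H <- nrow(ch); W <- ncol(ch)
  v <- ch[cbind(py + 1, px + 1)]
  is_max <- vapply(seq_along(v), function(i) {
    ys <- max(0, py[i] - 1):min(H - 1, py[i] + 1)
    xs <- max(0, px[i] - 1):min(W - 1, px[i] + 1)
    v[i] >= max(ch[ys + 1, xs + 1])
  }, logical(1))
  cand <- which(is_max)
  cand <- cand[order(-v[cand], py[cand], px[cand])]
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) == 0 ||
        all((px[keep] - px[i])^2 + (py[keep] - py[i])^2 >= min_sep^2))
      keep <- c(keep, i)
  }
  keep
}

#' Decode predicted heatmaps into centre-point predictions
#'
#' Per channel, pixels above the score threshold are grouped into connected
#' components (8-connectivity by default). Each component with area at most
#' `max_cluster_area` yields one prediction at its maximum-valued pixel
#' (ties broken to the lowest `(y, x)`), with the maximum as the score.
#' Oversized components are either split at their regional maxima, thinned
#' to at least one class radius apart (`oversized = "split"`, the default,
#' so wide well-formed peaks remain detectable), or discarded
#' (`oversized = "discard"`). Decoded coordinates are pixel centres
#' multiplied by `scale_factor`, i.e. native-scale pixels.
#'
#' @param heatmap a `cp_heatmap`.
#' @param score_threshold minimum peak score (default 0.5, strict `>`).
#' @param max_cluster_area maximum component area in heatmap pixels
#'   (default 16).
#' @param classes optional `cp_class_config` used for the oversized-cluster
#'   separation radius; defaults to the config attached to the heatmap.
#' @param connectivity 8 (default) or 4.
#' @param oversized `"split"` or `"discard"`.
#' @param tile_id tile id stamped on the output rows.
#' @return data frame `tile_id, x, y, cell_class, score` (0 rows if nothing
#'   is above threshold).
#' @export
decode_peaks <- function(heatmap, score_threshold = 0.5,
                         max_cluster_area = 16,
                         classes = attr(heatmap, "classes"),
                         connectivity = 8,
                         oversized = c("split", "discard"),
                         tile_id = "tile") {
  oversized <- match.arg(oversized)
  stopifnot(connectivity %in% c(4, 8))
  cls_names <- attr(heatmap, "class_names")
  scale <- attr(heatmap, "scale_factor")
  vals <- unclass(heatmap)
  out <- list()
  for (ci in seq_along(cls_names)) {
    ch <- vals[, , ci]
    mask <- ch > score_threshold
    if (!any(mask)) next
    lab <- cp_label(mask, as.integer(connectivity))
    idx <- which(mask, arr.ind = TRUE)  # (row=y+1, col=x+1)
    labs <- lab[idx]
    min_sep <- if (!is.null(classes))
      cp_diameter_for(classes, cls_names[ci]) / (2 * scale)
    else sqrt(max_cluster_area)
    for (k in unique(labs)) {
      sel <- labs == k
      py <- idx[sel, 1] - 1L
      px <- idx[sel, 2] - 1L
      v <- ch[cbind(py + 1, px + 1)]
      if (sum(sel) <= max_cluster_area) {
        top <- which(v == max(v))
        top <- top[order(py[top], px[top])][1]
        out[[length(out) + 1]] <- data.frame(
          tile_id = tile_id, x = px[top] * scale, y = py[top] * scale,
          cell_class = cls_names[ci], score = v[top],
          stringsAsFactors = FALSE)
      } else if (oversized == "split") {
        keep <- .cp_regional_maxima(ch, py, px, min_sep)
        for (i in keep) {
          out[[length(out) + 1]] <- data.frame(
            tile_id = tile_id, x = px[i] * scale, y = py[i] * scale,
            cell_class = cls_names[ci], score = v[i],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(tile_id = character(0), x = numeric(0),
                      y = numeric(0), cell_class = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
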