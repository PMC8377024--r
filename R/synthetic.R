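#' Synthetic cytospin scene configuration
#'
#' Describes the stylised cytospin world the generator emulates: tiles with
#' a Poisson-like object count (mean 15, truncated to 0--43 on full-size
#' 1024-px tiles, matching the observed per-tile object counts), the
#' four-class mix observed in the consensus dataset (macrophage lineage
#' 45.4%, neutrophil 45.35%, eosinophil 4.2%, lymphocyte 5.07%, rescaled to
#' sum to 1), log-normal per-class diameters reproducing the measured
#' medians and interquartile ranges, optional debris specks and mucus
#' smears, and a stain palette with per-cytospin jitter. For small test
#' tiles (`tile_size < 1024`) diameters scale by `tile_size / 1024`
#' (self-similar scenes) while the object count defaults to a Poisson mean
#' of 6 truncated to 1--12: packing 15 cells into 1/256 of the area is
#' geometrically impossible, so the small-tile world keeps realistic
#' density instead.
#'
#' @param tile_size tile side in px (default 1024).
#' @param count_mean,count_range Poisson mean and truncation range of the
#'   per-tile object count.
#' @param class_mix named class probabilities (normalised internally).
#' @param classes `cp_class_config` at native 1024-px scale; diameters are
#'   rescaled by `tile_size / 1024`.
#' @param diameter_iqr named list of native-scale IQRs `c(q1, q3)` used to
#'   set the log-normal spread.
#' @param min_separation minimum centre-to-centre distance; default 0.4 x
#'   the smallest class diameter (touching cell bodies allowed, centres
#'   distinct).
#' @param debris_rate expected debris specks per tile; `mucus_rate`
#'   expected mucus smears per tile.
#' @param palette `"kwik_diff"` or `"mgg"` stain preset.
#' @return A `cp_scene_config`.
#' @export
scene_config <- function(tile_size = 1024,
                         count_mean = if (tile_size >= 1024) 15 else 6,
                         count_range = if (tile_size >= 1024) c(0, 43)
                                       else c(1, 12),
                         class_mix = c(macrophage_lineage = 0.454,
                                       neutrophil = 0.4535,
                                       eosinophil = 0.042,
                                       lymphocyte = 0.0507),
                         classes = default_class_config(),
                         diameter_iqr = list(
                           macrophage_lineage = c(114, 183),
                           neutrophil = c(92, 114),
                           eosinophil = c(101, 142),
                           lymphocyte = c(53, 68.5)),
                         min_separation = NULL,
                         debris_rate = 3, mucus_rate = 0.5,
                         palette = c("kwik_diff", "mgg")) {
  palette <- match.arg(palette)
  class_mix <- class_mix / sum(class_mix)
  scale <- tile_size / 1024
  scaled <- class_config(classes$cell_class,
                         diameter_px = classes$diameter_px * scale,
                         sigma_px = classes$sigma_px * scale)
  if (is.null(min_separation))
    min_separation <- 0.4 * min(scaled$diameter_px)
  if (min_separation <= 0) stop("scene_config: min_separation must be > 0")
  structure(list(tile_size = as.integer(tile_size), count_mean = count_mean,
                 count_range = count_range, class_mix = class_mix,
                 classes = scaled, scale = scale,
                 diameter_iqr = diameter_iqr,
                 min_separation = min_separation,
                 debris_rate = debris_rate, mucus_rate = mucus_rate,
                 palette = palette),
            class = "cp_scene_config")
}

.cp_palettes <- list(
  kwik_diff = list(bg = c(0.93, 0.90, 0.94),
                   nucleus = c(0.35, 0.22, 0.50),
                   cyto_pale = c(0.78, 0.76, 0.88),
                   cyto_eos = c(0.90, 0.55, 0.45),
                   mucus = c(0.80, 0.72, 0.82)),
  mgg = list(bg = c(0.95, 0.93, 0.90),
             nucleus = c(0.30, 0.25, 0.55),
             cyto_pale = c(0.72, 0.74, 0.86),
             cyto_eos = c(0.88, 0.48, 0.42),
             mucus = c(0.82, 0.76, 0.78)))

# draw a class-conditional diameter: log-normal with the configured median
# and a log-sd matched to the native IQR
.cp_draw_diameter <- function(cfg, cl) {
  med <- cp_diameter_for(cfg$classes, cl)
  iqr <- cfg$diameter_iqr[[cl]] * cfg$scale
  sdlog <- (log(iqr[2]) - log(iqr[1])) / (2 * 0.6744898)
  exp(rnorm(1, log(med), sdlog))
}

# sample scene geometry (no rendering): centres, classes, diameters
sample_scene <- function(cfg, n_objects = NULL) {
  S <- cfg$tile_size
  if (is.null(n_objects)) {
    n_objects <- max(cfg$count_range[1],
                     min(cfg$count_range[2], rpois(1, cfg$count_mean)))
  }
  cls <- character(0); xs <- numeric(0); ys <- numeric(0); di <- numeric(0)
  tries <- 0
  while (length(xs) < n_objects) {
    tries <- tries + 1
    if (tries > 200 * max(1, n_objects))
      stop("sample_scene: infeasible packing for ", n_objects,
           " objects at separation ", cfg$min_separation)
    cl <- sample(names(cfg$class_mix), 1, prob = cfg$class_mix)
    d <- .cp_draw_diameter(cfg, cl)
    r <- d / 2
    margin <- min(r, S / 8)
    x <- runif(1, margin, S - 1 - margin)
    y <- runif(1, margin, S - 1 - margin)
    if (length(xs) > 0 &&
        any((xs - x)^2 + (ys - y)^2 < cfg$min_separation^2)) next
    xs <- c(xs, x); ys <- c(ys, y); cls <- c(cls, cl); di <- c(di, d)
  }
  data.frame(x = xs, y = ys, cell_class = cls, diameter = di,
             stringsAsFactors = FALSE)
}

# paint an ellipse-shaped patch onto the 3-channel image (in place via
# return); col length-3; soft = edge softness in px
.cp_paint <- function(img, cx, cy, rx, ry, ang, col, soft = 1,
                      noise = 0) {
  S <- dim(img)[1]
  x0 <- max(0, floor(cx - rx - ry)); x1 <- min(S - 1, ceiling(cx + rx + ry))
  y0 <- max(0, floor(cy - rx - ry)); y1 <- min(S - 1, ceiling(cy + rx + ry))
  if (x1 < x0 || y1 < y0) return(img)
  xs <- x0:x1; ys <- y0:y1
  ca <- cos(ang); sa <- sin(ang)
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- (ca * dx + sa * dy) / rx
  v <- (-sa * dx + ca * dy) / ry
  d <- sqrt(u^2 + v^2)
  a <- pmin(pmax((1 - d) * max(rx, ry) / soft, 0), 1)  # soft edge mask
  if (all(a == 0)) return(img)
  if (noise > 0) {
    a <- a * (1 - noise * matrix(runif(length(a)), nrow(a)))
  }
  for (ch in 1:3) {
    sl <- img[ys + 1, xs + 1, ch]
    img[ys + 1, xs + 1, ch] <- sl * (1 - a) + col[ch] * a
  }
  img
}

# render one cell of the given class; styles are deliberately stylised but
# class-separable: size, cytoplasm hue and nuclear lobation differ
.cp_render_cell <- function(img, x, y, cl, d, pal) {
  r <- d / 2
  ang <- runif(1, 0, pi)
  ecc <- runif(1, 0.85, 1)
  if (cl == "macrophage_lineage") {
    img <- .cp_paint(img, x, y, r, r * ecc, ang, pal$cyto_pale, soft = 2)
    nr <- r * runif(1, 0.3, 0.45)
    off <- r * 0.25
    img <- .cp_paint(img, x + runif(1, -off, off), y + runif(1, -off, off),
                     nr, nr * 0.9, ang, pal$nucleus)
  } else if (cl == "lymphocyte") {
    img <- .cp_paint(img, x, y, r, r * ecc, ang, pal$cyto_pale, soft = 1)
    img <- .cp_paint(img, x, y, r * 0.85, r * 0.85 * ecc, ang, pal$nucleus)
  } else {
    cyto <- if (cl == "eosinophil") pal$cyto_eos else pal$cyto_pale
    gr <- if (cl == "eosinophil") 0.35 else 0
    img <- .cp_paint(img, x, y, r, r * ecc, ang, cyto, soft = 1.5,
                     noise = gr)
    nlobes <- if (cl == "eosinophil") 2 else 3
    th0 <- runif(1, 0, 2 * pi)
    for (l in seq_len(nlobes)) {
      th <- th0 + 2 * pi * l / nlobes
      lr <- r * 0.28
      img <- .cp_paint(img, x + 0.4 * r * cos(th), y + 0.4 * r * sin(th),
                       lr, lr * 0.8, th, pal$nucleus)
    }
  }
  img
}

#' Generate one synthetic cytospin tile
#'
#' Renders a stained-background RGB tile with planted class-styled cells
#' (large pale cytoplasm and single nucleus for the macrophage lineage;
#' small dark round cell for lymphocytes; multi-lobed nuclei for
#' neutrophils; lobed nuclei plus granular red-tinted cytoplasm for
#' eosinophils), optional debris specks and mucus smears, and returns the
#' exact ground-truth centre annotations. Identical `(cfg, seed)` give
#' bitwise-identical output.
#'
#' @param cfg a [scene_config()].
#' @param seed integer seed.
#' @param tile_id tile identifier stamped on the truth annotations.
#' @param n_objects optional fixed object count (overrides the draw).
#' @param style optional per-cytospin style jitter, a list with `hue_shift`
#'   (length-3 additive) and `gain` (scalar), as produced by
#'   [generate_dataset()].
#' @return A `cp_synthetic_tile`: list with `image` (`S x S x 3` in
#'   `[0,1]`), `truth` (a `cp_annotations`, assessor `"truth"`), `cfg`,
#'   `seed`.
#' @export
generate_tile <- function(cfg, seed, tile_id = sprintf("tile%06d", seed),
                          n_objects = NULL, style = NULL) {
  stopifnot(inherits(cfg, "cp_scene_config"))
  set.seed(seed)
  S <- cfg$tile_size
  pal <- .cp_palettes[[cfg$palette]]
  if (!is.null(style)) {
    pal <- lapply(pal, function(col)
      pmin(pmax(col * style$gain + style$hue_shift, 0), 1))
  }
  scene <- sample_scene(cfg, n_objects)
  img <- array(rep(pal$bg, each = S * S), c(S, S, 3))
  img <- img + array(rnorm(S * S, 0, 0.015), c(S, S, 3))
  n_mucus <- rpois(1, cfg$mucus_rate)
  for (i in seq_len(n_mucus)) {
    mr <- S * runif(1, 0.08, 0.25)
    img <- .cp_paint(img, runif(1, 0, S - 1), runif(1, 0, S - 1),
                     mr, mr * runif(1, 0.2, 0.5), runif(1, 0, pi),
                     pal$mucus, soft = mr / 2, noise = 0.2)
  }
  for (i in seq_len(nrow(scene))) {
    img <- .cp_render_cell(img, scene$x[i], scene$y[i],
                           scene$cell_class[i], scene$diameter[i], pal)
  }
  n_debris <- rpois(1, cfg$debris_rate)
  for (i in seq_len(n_debris)) {
    dr <- max(1, S / 1024 * runif(1, 4, 18))
    img <- .cp_paint(img, runif(1, 0, S - 1), runif(1, 0, S - 1),
                     dr, dr * runif(1, 0.5, 1), runif(1, 0, pi),
                     pal$nucleus * runif(1, 0.8, 1.4), noise = 0.4)
  }
  img <- pmin(pmax(img, 0), 1)
  tdf <- scene[, c("x", "y", "cell_class")]
  tdf$assessor_id <- rep("truth", nrow(tdf))
  truth <- annotation_set(tile_id, S, S, tdf,
                          classes = cfg$classes$cell_class)
  out <- list(image = img, truth = truth, cfg = cfg, seed = seed,
              diameters = scene$diameter)
  class(out) <- "cp_synthetic_tile"
  out
}

#' Generate a multi-cytospin synthetic dataset on disk
#'
#' Emulates the study layout (e.g. 19 cytospins x 40 tiles): each cytospin
#' gets a style jitter (stain hue/intensity around its palette preset, the
#' analogue of the two staining protocols) and all tiles are written as
#' PNG with a truth annotation CSV and a JSON manifest recording every
#' seed.
#'
#' @param cfg a [scene_config()].
#' @param n_cytospins,tiles_per_cytospin dataset shape.
#' @param base_seed global seed; per-tile seeds are derived
#'   deterministically.
#' @param out_dir output directory; must be empty or absent unless
#'   `overwrite`.
#' @param overwrite allow writing into a non-empty directory.
#' @return The manifest data frame (`cytospin_id, tile_id, seed, palette`),
#'   invisibly; files under `out_dir`.
#' @export
generate_dataset <- function(cfg, n_cytospins, tiles_per_cytospin,
                             base_seed = 1, out_dir, overwrite = FALSE) {
  stopifnot(n_cytospins >= 1, tiles_per_cytospin >= 1)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("generate_dataset: output directory not empty: ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  truth <- list()
  for (cs in seq_len(n_cytospins)) {
    cs_id <- sprintf("cytospin%02d", cs)
    set.seed(derive_seed(base_seed, paste0("style.", cs_id)))
    style <- list(hue_shift = runif(3, -0.04, 0.04),
                  gain = runif(1, 0.92, 1.08))
    pal_name <- if (cs %% 2 == 1) "kwik_diff" else "mgg"
    cfg_cs <- cfg
    cfg_cs$palette <- pal_name
    for (t in seq_len(tiles_per_cytospin)) {
      tile_id <- sprintf("%s_t%03d", cs_id, t)
      seed <- derive_seed(base_seed, tile_id)
      tl <- generate_tile(cfg_cs, seed, tile_id = tile_id, style = style)
      write_png(tl$image, file.path(out_dir, paste0(tile_id, ".png")))
      truth[[length(truth) + 1]] <- tl$truth
      rows[[length(rows) + 1]] <-
        data.frame(cytospin_id = cs_id, tile_id = tile_id, seed = seed,
                   palette = pal_name, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_annotations(truth, file.path(out_dir, "truth.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows")
  invisible(manifest)
}

#' Simulate imperfect human assessors from truth annotations
#'
#' Each simulated assessor re-annotates the truth with Gaussian positional
#' jitter, Bernoulli misses, and class confusions drawn from the rows of a
#' confusion matrix, enabling inter-rater (ICC/AP) experiments that mirror
#' multi-assessor variability testing.
#'
#' @param truth a `cp_annotations`.
#' @param n_assessors number of simulated assessors.
#' @param jitter_px positional jitter SD in native px.
#' @param miss_rate per-annotation probability of omission, in `[0, 1]`.
#' @param confuse_matrix square stochastic matrix (rows = true class,
#'   columns = annotated class, row sums 1); default identity.
#' @param seed integer seed.
#' @return List of `cp_annotations`, assessor ids `"assessor1"`, ...
#' @export
simulate_assessors <- function(truth, n_assessors, jitter_px = 0,
                               miss_rate = 0, confuse_matrix = NULL,
                               seed = 1) {
  stopifnot(inherits(truth, "cp_annotations"))
  if (miss_rate < 0 || miss_rate > 1)
    stop("simulate_assessors: miss_rate must be in [0, 1]")
  if (jitter_px < 0) stop("simulate_assessors: jitter_px must be >= 0")
  cls <- truth$classes
  if (is.null(confuse_matrix)) {
    confuse_matrix <- diag(length(cls))
    dimnames(confuse_matrix) <- list(cls, cls)
  }
  if (any(abs(rowSums(confuse_matrix) - 1) > 1e-9))
    stop("simulate_assessors: confuse_matrix rows must sum to 1")
  set.seed(seed)
  ann <- truth$annotations
  lapply(seq_len(n_assessors), function(a) {
    keep <- runif(nrow(ann)) >= miss_rate
    d <- ann[keep, , drop = FALSE]
    if (nrow(d) > 0) {
      d$x <- pmin(pmax(d$x + rnorm(nrow(d), 0, jitter_px), 0),
                  truth$tile_width - 1e-9)
      d$y <- pmin(pmax(d$y + rnorm(nrow(d), 0, jitter_px), 0),
                  truth$tile_height - 1e-9)
      d$cell_class <- vapply(d$cell_class, function(tc)
        sample(colnames(confuse_matrix), 1,
               prob = confuse_matrix[tc, ]), character(1))
      d$assessor_id <- paste0("assessor", a)
    }
    annotation_set(truth$tile_id, truth$tile_width, truth$tile_height, d,
                   classes = cls)
  })
}
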