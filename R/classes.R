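#' Class-size configuration
#'
#' A class configuration maps each cell class to a reference diameter (in
#' native-scale pixels, the longest span across the cell) and the Gaussian
#' spread `sigma_px` used when rendering heatmap targets. The default
#' diameters are the median measured diameters of the four immune cell
#' classes on x100 cytospin tiles: macrophage lineage 142 px, neutrophil
#' 104 px, eosinophil 126 px, lymphocyte 61 px. `sigma_px` defaults to the
#' class radius (`diameter_px / 2`).
#'
#' @param cell_class character vector of class names.
#' @param diameter_px numeric vector of reference diameters (px), `> 0`.
#' @param sigma_px numeric vector of Gaussian spreads (px), `> 0`; defaults
#'   to `diameter_px / 2`.
#' @return A `cp_class_config` data frame with one row per class.
#' @export
class_config <- function(cell_class, diameter_px,
                         sigma_px = diameter_px / 2) {
  cell_class <- as.character(cell_class)
  if (anyDuplicated(cell_class))
    stop("class_config: duplicated cell_class entries")
  if (length(diameter_px) != length(cell_class) ||
      length(sigma_px) != length(cell_class))
    stop("class_config: field lengths differ")
  if (any(!is.finite(diameter_px)) || any(diameter_px <= 0))
    stop("class_config: diameter_px must be positive")
  if (any(!is.finite(sigma_px)) || any(sigma_px <= 0))
    stop("class_config: sigma_px must be positive")
  out <- data.frame(cell_class = cell_class,
                    diameter_px = as.numeric(diameter_px),
                    sigma_px = as.numeric(sigma_px),
                    stringsAsFactors = FALSE)
  class(out) <- c("cp_class_config", "data.frame")
  out
}

#' Default class-size configuration
#'
#' @param scale rescale factor applied to diameters and sigmas; `scale = 1`
#'   is the native 1024-px tile world, `scale = 1/16` the 64-px test world.
#' @return A `cp_class_config`.
#' @export
default_class_config <- function(scale = 1) {
  class_config(cp_classes(),
               diameter_px = c(142, 104, 126, 61) * scale)
}

#' Estimate a class configuration from diameter measurements
#'
#' Reference diameters are the per-class medians of manual width
#' measurements (longest span per object); the heatmap spread is the class
#' radius, i.e. half the median diameter.
#'
#' @param measurements data frame with columns `cell_class`, `diameter_px`.
#' @param classes character vector of classes that must all be measured.
#' @param sigma_factor multiplier from diameter to sigma (default 0.5, the
#'   radius).
#' @return A `cp_class_config`.
#' @export
compute_class_config <- function(measurements, classes = cp_classes(),
                                 sigma_factor = 0.5) {
  if (!all(c("cell_class", "diameter_px") %in% names(measurements)))
    stop("compute_class_config: need columns cell_class, diameter_px")
  missing <- setdiff(classes, unique(measurements$cell_class))
  if (length(missing) > 0)
    stop("compute_class_config: no measurements for class ",
         paste(missing, collapse = ", "))
  med <- vapply(classes, function(cl) {
    median(measurements$diameter_px[measurements$cell_class == cl])
  }, numeric(1))
  class_config(classes, diameter_px = unname(med),
               sigma_px = unname(med) * sigma_factor)
}

cp_sigma_for <- function(classes, cell_class) {
  i <- match(cell_class, classes$cell_class)
  if (anyNA(i)) stop("unknown cell class: ",
                     paste(unique(cell_class[is.na(i)]), collapse = ", "))
  classes$sigma_px[i]
}

cp_diameter_for <- function(classes, cell_class) {
  i <- match(cell_class, classes$cell_class)
  if (anyNA(i)) stop("unknown cell class: ",
                     paste(unique(cell_class[is.na(i)]), collapse = ", "))
  classes$diameter_px[i]
}

#' Read / write a class configuration as YAML
#'
#' The YAML layout maps class name to `{diameter_px, sigma_px}`.
#'
#' @param path file path.
#' @return `read_class_config` returns a `cp_class_config`.
#' @export
read_class_config <- function(path) {
  y <- yaml::read_yaml(path)
  class_config(names(y),
               diameter_px = vapply(y, function(e) e$diameter_px, numeric(1)),
               sigma_px = vapply(y, function(e) e$sigma_px, numeric(1)))
}

#' @rdname read_class_config
#' @param config a `cp_class_config`.
#' @export
write_class_config <- function(config, path) {
  y <- lapply(seq_len(nrow(config)), function(i) {
    list(diameter_px = config$diameter_px[i], sigma_px = config$sigma_px[i])
  })
  names(y) <- config$cell_class
  yaml::write_yaml(y, path)
  invisible(path)
}
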