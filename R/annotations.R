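#' Centre-point annotation sets
#'
#' An annotation set holds the single-click centre-point annotations of one
#' assessor (or the consensus) on one image tile. Coordinates are 0-based,
#' x rightwards and y downwards, in native tile pixels; sub-pixel values are
#' permitted. Points mark the centre of the whole cell, not the nucleus.
#'
#' @param tile_id tile identifier.
#' @param tile_width,tile_height tile dimensions in pixels.
#' @param annotations data frame with columns `x`, `y`, `cell_class`,
#'   `assessor_id` (missing columns are added; zero rows allowed).
#' @param classes character vector of admissible classes.
#' @return A `cp_annotations` object.
#' @export
annotation_set <- function(tile_id, tile_width, tile_height,
                           annotations = NULL, classes = cp_classes()) {
  if (is.null(annotations))
    annotations <- data.frame(x = numeric(0), y = numeric(0),
                              cell_class = character(0),
                              assessor_id = character(0),
                              stringsAsFactors = FALSE)
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  need <- c("x", "y", "cell_class", "assessor_id")
  miss <- setdiff(need, names(annotations))
  if ("assessor_id" %in% miss) annotations$assessor_id <- "unknown"
  miss <- setdiff(need, names(annotations))
  if (length(miss) > 0)
    stop("annotation_set: missing columns ", paste(miss, collapse = ", "))
  bad <- !(annotations$cell_class %in% classes)
  if (any(bad))
    stop("annotation_set: unknown cell class '",
         annotations$cell_class[which(bad)[1]], "' in row ", which(bad)[1])
  oob <- annotations$x < 0 | annotations$x >= tile_width |
         annotations$y < 0 | annotations$y >= tile_height
  if (any(oob))
    stop("annotation_set: coordinates outside tile bounds in row ",
         which(oob)[1])
  out <- list(tile_id = as.character(tile_id),
              tile_width = tile_width, tile_height = tile_height,
              annotations = annotations[, need],
              classes = classes)
  class(out) <- "cp_annotations"
  out
}

#' @export
print.cp_annotations <- function(x, ...) {
  cat(sprintf("<cp_annotations> tile %s (%dx%d), %d points, assessors: %s\n",
              x$tile_id, x$tile_width, x$tile_height, nrow(x$annotations),
              paste(unique(x$annotations$assessor_id), collapse = ", ")))
  invisible(x)
}

#' Read centre-point annotation tables
#'
#' Accepts the CSV dialect with header
#' `tile_id,x,y,cell_class,assessor_id` (an optional `score` column is kept)
#' or an equivalent JSON array of records. Rows are grouped into one
#' annotation set per (tile, assessor); row order is preserved within each
#' set.
#'
#' @param path CSV or JSON file.
#' @param tile_width,tile_height tile dimensions used for bounds validation.
#' @param classes admissible class labels.
#' @return A list of `cp_annotations`, one per (tile_id, assessor_id).
#' @export
read_annotations <- function(path, tile_width, tile_height,
                             classes = cp_classes()) {
  if (!file.exists(path)) stop("read_annotations: no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    if (length(df) == 0)
      df <- data.frame(tile_id = character(0), x = numeric(0),
                       y = numeric(0), cell_class = character(0),
                       assessor_id = character(0))
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("tile_id", "x", "y", "cell_class", "assessor_id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("read_annotations: missing column(s) ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(list())
  df$x <- as.numeric(df$x)
  df$y <- as.numeric(df$y)
  key <- paste(df$tile_id, df$assessor_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
                function(i) {
    annotation_set(df$tile_id[i[1]], tile_width, tile_height,
                   df[i, setdiff(names(df), "tile_id"), drop = FALSE],
                   classes = classes)
  })
  names(out) <- NULL
  out
}

#' Write annotation sets (or prediction tables) to CSV
#'
#' @param sets a `cp_annotations`, a list of them, or a data frame already in
#'   the flat schema.
#' @param path output CSV path.
#' @export
write_annotations <- function(sets, path) {
  df <- annotations_to_df(sets)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

annotations_to_df <- function(sets) {
  if (is.data.frame(sets)) return(sets)
  if (inherits(sets, "cp_annotations")) sets <- list(sets)
  parts <- lapply(sets, function(s) {
    if (nrow(s$annotations) == 0) return(NULL)
    cbind(data.frame(tile_id = s$tile_id, stringsAsFactors = FALSE),
          s$annotations)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0)
    return(data.frame(tile_id = character(0), x = numeric(0), y = numeric(0),
                      cell_class = character(0), assessor_id = character(0)))
  do.call(rbind, parts)
}

# Single-linkage clusters of 2-D points: connected components of the
# "pairwise distance <= radius" graph, via union-find over all pairs.
cluster_points_single <- function(x, y, radius) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    r2 <- radius^2
    for (i in seq_len(n - 1)) {
      d2 <- (x[(i + 1):n] - x[i])^2 + (y[(i + 1):n] - y[i])^2
      for (j in which(d2 <= r2) + i) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Greedy nearest-first clustering: points in input order join the first
# existing cluster whose running centroid is within radius, else start one.
cluster_points_greedy <- function(x, y, radius) {
  n <- length(x)
  lab <- integer(n)
  cx <- numeric(0); cy <- numeric(0); cn <- integer(0)
  for (i in seq_len(n)) {
    if (length(cx) > 0) {
      d2 <- (cx - x[i])^2 + (cy - y[i])^2
      k <- which.min(d2)
      if (d2[k] <= radius^2) {
        lab[i] <- k
        cx[k] <- (cx[k] * cn[k] + x[i]) / (cn[k] + 1)
        cy[k] <- (cy[k] * cn[k] + y[i]) / (cn[k] + 1)
        cn[k] <- cn[k] + 1L
        next
      }
    }
    cx <- c(cx, x[i]); cy <- c(cy, y[i]); cn <- c(cn, 1L)
    lab[i] <- length(cx)
  }
  lab
}

#' Merge multi-assessor annotations into a consensus set
#'
#' Clicks from all assessors on one tile are clustered by proximity
#' (default: single-linkage connected components of the "distance <=
#' dedup_radius" graph, with the 10 px radius used for duplicate
#' consolidation). Each cluster emits one consensus point at the centroid of
#' its members, classed by majority vote; clusters whose vote is tied are
#' flagged for expert review (`resolution = "flagged_tie"`), taking the tied
#' class that comes first in the configured class order as a deterministic
#' placeholder.
#'
#' @param sets list of at least two `cp_annotations` for the same tile.
#' @param dedup_radius merge radius in native pixels (default 10).
#' @param method `"single_linkage"` (default) or `"greedy"` nearest-first.
#' @return A `cp_consensus` with elements `consensus` (a `cp_annotations`
#'   with `assessor_id = "consensus"`), `conflicts` (per-cluster vote
#'   summary), `membership` (input row to cluster id), and `originals`.
#' @export
consolidate_consensus <- function(sets, dedup_radius = 10,
                                  method = c("single_linkage", "greedy")) {
  method <- match.arg(method)
  if (!is.list(sets) || length(sets) < 2)
    stop("consolidate_consensus: need at least 2 annotation sets")
  if (!all(vapply(sets, inherits, logical(1), "cp_annotations")))
    stop("consolidate_consensus: inputs must be cp_annotations")
  tid <- unique(vapply(sets, function(s) s$tile_id, character(1)))
  if (length(tid) != 1)
    stop("consolidate_consensus: mismatched tile ids: ",
         paste(tid, collapse = ", "))
  if (dedup_radius <= 0) stop("consolidate_consensus: dedup_radius must be > 0")
  ref <- sets[[1]]
  df <- do.call(rbind, lapply(sets, function(s) s$annotations))
  if (nrow(df) == 0) {
    empty <- annotation_set(tid, ref$tile_width, ref$tile_height,
                            classes = ref$classes)
    empty$annotations$assessor_id <- character(0)
    out <- list(consensus = empty,
                conflicts = data.frame(cluster = integer(0),
                                       n_members = integer(0),
                                       votes = character(0),
                                       resolution = character(0)),
                membership = integer(0), originals = sets)
    class(out) <- "cp_consensus"
    return(out)
  }
  lab <- switch(method,
                single_linkage = cluster_points_single(df$x, df$y,
                                                       dedup_radius),
                greedy = cluster_points_greedy(df$x, df$y, dedup_radius))
  ids <- sort(unique(lab))
  rows <- lapply(ids, function(k) {
    m <- df[lab == k, , drop = FALSE]
    votes <- table(m$cell_class)
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) {
      cls <- top
      res <- "majority"
    } else {
      # deterministic placeholder for the expert-review pass
      cls <- ref$classes[min(match(top, ref$classes))]
      res <- "flagged_tie"
    }
    list(x = mean(m$x), y = mean(m$y), cell_class = cls, n = nrow(m),
         votes = paste(sprintf("%s:%d", names(votes), as.integer(votes)),
                       collapse = ";"),
         resolution = res)
  })
  cons <- data.frame(
    x = vapply(rows, `[[`, numeric(1), "x"),
    y = vapply(rows, `[[`, numeric(1), "y"),
    cell_class = vapply(rows, `[[`, character(1), "cell_class"),
    assessor_id = "consensus", stringsAsFactors = FALSE)
  conflicts <- data.frame(
    cluster = ids,
    n_members = vapply(rows, `[[`, numeric(1), "n"),
    votes = vapply(rows, `[[`, character(1), "votes"),
    resolution = vapply(rows, `[[`, character(1), "resolution"),
    stringsAsFactors = FALSE)
  out <- list(consensus = annotation_set(tid, ref$tile_width,
                                         ref$tile_height, cons,
                                         classes = ref$classes),
              conflicts = conflicts, membership = lab, originals = sets)
  class(out) <- "cp_consensus"
  out
}

#' @export
print.cp_consensus <- function(x, ...) {
  cat(sprintf("<cp_consensus> tile %s: %d clusters (%d flagged ties)\n",
              x$consensus$tile_id, nrow(x$conflicts),
              sum(x$conflicts$resolution == "flagged_tie")))
  invisible(x)
}
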