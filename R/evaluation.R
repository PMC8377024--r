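#' Match predicted centres to ground truth at a distance threshold
#'
#' Per class, predictions sorted by descending score (ties keep input
#' order) greedily claim the nearest still-unmatched ground-truth point of
#' the same class within `delta * diameter_px(class)`. Remaining
#' predictions are false positives, remaining ground truths false
#' negatives. An optimal bipartite assignment (maximising true positives,
#' used as the test oracle) is available via `method = "optimal"`.
#'
#' @param predictions data frame `x, y, cell_class, score` (a `score`
#'   column is optional; uniform scores are assumed when absent, the
#'   human-assessor case).
#' @param ground_truth a `cp_annotations` or data frame `x, y, cell_class`.
#' @param delta distance threshold as a fraction of the class diameter
#'   (> 0).
#' @param classes `cp_class_config` providing the diameters.
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return A `cp_match`: list with `tp` (data frame of matched pairs with
#'   distances), `fp`, `fn` (row indices into predictions / ground truth),
#'   and per-prediction logical `is_tp` in input order.
#' @export
match_centres <- function(predictions, ground_truth, delta,
                          classes = default_class_config(),
                          method = c("greedy", "optimal")) {
  method <- match.arg(method)
  if (delta <= 0) stop("match_centres: delta must be > 0")
  gt <- if (inherits(ground_truth, "cp_annotations"))
    ground_truth$annotations else ground_truth
  pr <- as.data.frame(predictions)
  if (is.null(pr$score)) pr$score <- rep(1, nrow(pr))
  npr <- nrow(pr); ngt <- nrow(gt)
  is_tp <- logical(npr)
  gt_matched <- logical(ngt)
  pairs <- list()
  for (cl in unique(c(pr$cell_class, gt$cell_class))) {
    pi <- which(pr$cell_class == cl)
    gi <- which(gt$cell_class == cl)
    if (length(pi) == 0 || length(gi) == 0) next
    thr <- delta * cp_diameter_for(classes, cl)
    D <- sqrt(outer(pr$x[pi], gt$x[gi], "-")^2 +
                outer(pr$y[pi], gt$y[gi], "-")^2)
    if (method == "greedy") {
      ord <- pi[order(-pr$score[pi])]
      for (p in ord) {
        drow <- D[match(p, pi), ]
        drow[gt_matched[gi]] <- Inf
        j <- which.min(drow)
        if (length(j) == 1 && is.finite(drow[j]) && drow[j] <= thr) {
          g <- gi[j]
          gt_matched[g] <- TRUE
          is_tp[p] <- TRUE
          pairs[[length(pairs) + 1]] <-
            data.frame(pred = p, gt = g, distance = drow[j],
                       cell_class = cl, stringsAsFactors = FALSE)
        }
      }
    } else {
      # maximum-cardinality assignment within threshold, min total distance
      # among maximum matchings; exhaustive augmenting-path search
      adj <- D <= thr
      matchL <- rep(NA_integer_, length(pi))  # pred -> gt (local idx)
      matchR <- rep(NA_integer_, length(gi))
      try_kuhn <- function(u, seen) {
        for (v in which(adj[u, ])) {
          if (seen[v]) next
          seen[v] <- TRUE
          if (is.na(matchR[v]) ||
              Recall(matchR[v], seen)) {
            matchL[u] <<- v
            matchR[v] <<- u
            return(TRUE)
          }
        }
        FALSE
      }
      ord <- order(-pr$score[pi])
      for (u in ord) try_kuhn(u, rep(FALSE, length(gi)))
      for (u in which(!is.na(matchL))) {
        p <- pi[u]; g <- gi[matchL[u]]
        gt_matched[g] <- TRUE
        is_tp[p] <- TRUE
        pairs[[length(pairs) + 1]] <-
          data.frame(pred = p, gt = g, distance = D[u, matchL[u]],
                     cell_class = cl, stringsAsFactors = FALSE)
      }
    }
  }
  tp <- if (length(pairs) > 0) do.call(rbind, pairs) else
    data.frame(pred = integer(0), gt = integer(0), distance = numeric(0),
               cell_class = character(0), stringsAsFactors = FALSE)
  out <- list(tp = tp, fp = which(!is_tp), fn = which(!gt_matched),
              is_tp = is_tp, n_pred = npr, n_gt = ngt)
  class(out) <- "cp_match"
  out
}

# AP from pooled prediction flags. scores/is_tp in input order; n_gt total
# ground truths of the class. Interpolated PR area (precision at each
# recall level = max precision at any recall >= it). If all scores are
# equal (unscored assessor sets) this reduces to precision x recall at the
# single operating point.
ap_from_flags <- function(scores, is_tp, n_gt) {
  if (n_gt <= 0) return(NA_real_)
  if (length(scores) == 0) return(0)
  ord <- order(-scores)
  tp_cum <- cumsum(is_tp[ord])
  fp_cum <- cumsum(!is_tp[ord])
  prec <- tp_cum / (tp_cum + fp_cum)
  rec <- tp_cum / n_gt
  if (length(unique(scores)) == 1)
    return(prec[length(prec)] * rec[length(rec)])
  # interpolate: running max of precision from the right
  prec_i <- rev(cummax(rev(prec)))
  r_prev <- c(0, rec[-length(rec)])
  sum((rec - r_prev) * prec_i)
}

#' Evaluate predictions against ground truth over a tile set
#'
#' Matches per tile (score-descending greedy, see [match_centres()]), pools
#' matched flags over tiles, and reports AP, precision, recall, F1 and
#' TP/FP/FN counts per class and threshold, plus a class-agnostic "total
#' immune cell" row per threshold (all points re-matched ignoring class;
#' the match radius uses each ground-truth point's own class diameter).
#'
#' @param pred_sets list (one per tile) of prediction data frames
#'   `x, y, cell_class, score`.
#' @param gt_sets list (one per tile, same order) of `cp_annotations`.
#' @param classes `cp_class_config`.
#' @param deltas thresholds as fractions of the class diameter
#'   (default `c(0.1, 0.25, 0.5)`).
#' @return A `cp_eval_report` data frame with columns `cell_class, delta,
#'   AP, precision, recall, F1, TP, FP, FN, n_gt`.
#' @export
evaluate_detections <- function(pred_sets, gt_sets,
                                classes = default_class_config(),
                                deltas = c(0.1, 0.25, 0.5)) {
  stopifnot(length(pred_sets) == length(gt_sets))
  if (any(deltas <= 0)) stop("evaluate_detections: deltas must be > 0")
  rows <- list()
  all_classes <- classes$cell_class
  for (delta in deltas) {
    per_class_flags <- setNames(
      lapply(all_classes, function(cl)
        list(scores = numeric(0), is_tp = logical(0), n_gt = 0)),
      all_classes)
    tot <- list(scores = numeric(0), is_tp = logical(0), n_gt = 0)
    for (i in seq_along(pred_sets)) {
      pr <- as.data.frame(pred_sets[[i]])
      if (is.null(pr$score)) pr$score <- rep(1, nrow(pr))
      gt <- if (inherits(gt_sets[[i]], "cp_annotations"))
        gt_sets[[i]]$annotations else as.data.frame(gt_sets[[i]])
      m <- match_centres(pr, gt, delta, classes)
      for (cl in all_classes) {
        sel <- pr$cell_class == cl
        per_class_flags[[cl]]$scores <-
          c(per_class_flags[[cl]]$scores, pr$score[sel])
        per_class_flags[[cl]]$is_tp <-
          c(per_class_flags[[cl]]$is_tp, m$is_tp[sel])
        per_class_flags[[cl]]$n_gt <-
          per_class_flags[[cl]]$n_gt + sum(gt$cell_class == cl)
      }
      # class-agnostic "total immune cell" re-match: one pooled pseudo-
      # class; each ground-truth point keeps its own class diameter as
      # the match radius
      pr2 <- pr; gt2 <- gt
      pr2$cell_class <- rep("cell", nrow(pr2))
      gt2$cell_class <- rep("cell", nrow(gt2))
      m2 <- match_centres_total(pr2, gt2, gt$cell_class, delta, classes)
      tot$scores <- c(tot$scores, pr$score)
      tot$is_tp <- c(tot$is_tp, m2$is_tp)
      tot$n_gt <- tot$n_gt + nrow(gt)
    }
    for (cl in all_classes) {
      f <- per_class_flags[[cl]]
      rows[[length(rows) + 1]] <- cp_eval_row(cl, delta, f)
    }
    rows[[length(rows) + 1]] <- cp_eval_row("total_immune_cell", delta, tot)
  }
  rep <- do.call(rbind, rows)
  class(rep) <- c("cp_eval_report", "data.frame")
  rep
}

# class-agnostic greedy matching where the radius of each candidate pair is
# delta * diameter of the ground-truth point's class
match_centres_total <- function(pr, gt, gt_class, delta, classes) {
  npr <- nrow(pr); ngt <- nrow(gt)
  is_tp <- logical(npr)
  if (npr == 0 || ngt == 0)
    return(list(is_tp = is_tp, n_gt = ngt))
  thr <- delta * cp_diameter_for(classes, gt_class)
  gt_matched <- logical(ngt)
  D <- sqrt(outer(pr$x, gt$x, "-")^2 + outer(pr$y, gt$y, "-")^2)
  ord <- order(-pr$score)
  for (p in ord) {
    drow <- D[p, ] / thr  # normalised: admissible iff <= delta-scaled 1
    drow[gt_matched | D[p, ] > thr] <- Inf
    j <- which.min(drow)
    if (is.finite(drow[j])) {
      gt_matched[j] <- TRUE
      is_tp[p] <- TRUE
    }
  }
  list(is_tp = is_tp, n_gt = ngt)
}

cp_eval_row <- function(cl, delta, f) {
  tp <- sum(f$is_tp); fp <- sum(!f$is_tp); fn <- f$n_gt - tp
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (f$n_gt > 0) tp / f$n_gt else NA_real_
  data.frame(cell_class = cl, delta = delta,
             AP = ap_from_flags(f$scores, f$is_tp, f$n_gt),
             precision = prec, recall = rec,
             F1 = f1_score(tp, fp, fn),
             TP = tp, FP = fp, FN = fn, n_gt = f$n_gt,
             stringsAsFactors = FALSE)
}

#' F1 score from match counts
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`, defined as 0 when the denominator is 0.
#' Also callable on a `cp_match`.
#'
#' @param tp,fp,fn counts, or `tp` a `cp_match` object.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(tp, fp = NULL, fn = NULL) {
  if (inherits(tp, "cp_match")) {
    m <- tp
    tp <- nrow(m$tp); fp <- length(m$fp); fn <- length(m$fn)
  }
  den <- 2 * tp + fp + fn
  if (den == 0) return(0)
  2 * tp / den
}

#' Two-way absolute-agreement intraclass correlation, ICC(A,1)
#'
#' Single-rater, two-way, absolute-agreement ICC (McGraw--Wong A,1), the
#' agreement statistic that penalises systematic rater bias:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with `n` subjects,
#' `k` raters, and the two-way ANOVA mean squares for rows (subjects),
#' columns (raters) and error.
#'
#' @param ratings numeric `subjects x raters` matrix (no missing cells,
#'   at least 2 of each).
#' @return List with `icc`, the mean squares `msr`, `msc`, `mse`, `n`, `k`,
#'   and `degenerate` (TRUE when the matrix is constant, in which case
#'   `icc = 1` by convention).
#' @export
icc_a1 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("icc_a1: need at least 2 subjects and 2 raters")
  if (anyNA(ratings)) stop("icc_a1: missing cells are not supported")
  grand <- mean(ratings)
  rm_ <- rowMeans(ratings)
  cm <- colMeans(ratings)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm - grand)^2) / (k - 1)
  resid <- ratings - outer(rm_, rep(1, k)) -
    outer(rep(1, n), cm) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(den) < 1e-300) {
    return(list(icc = 1, msr = msr, msc = msc, mse = mse, n = n, k = k,
                degenerate = TRUE))
  }
  list(icc = (msr - mse) / den, msr = msr, msc = msc, mse = mse,
       n = n, k = k, degenerate = FALSE)
}

#' Differential immune cell count
#'
#' Pools centre points (consensus annotations or predictions) over a
#' cytospin's tiles into per-class counts and percentages of total immune
#' cells, with the categorical determinations used in asthma assessment:
#' eosinophilic if eosinophils exceed 3% and neutrophilic if neutrophils
#' exceed 61% (both strict inequalities, evaluated on unrounded
#' percentages).
#'
#' @param points a `cp_annotations`, a prediction/annotation data frame
#'   with a `cell_class` column, or a list of either (pooled).
#' @param classes character vector of classes to report.
#' @return A `cp_diff_count`: data frame `cell_class, count, percent` plus
#'   attributes `total`, `eosinophilic`, `neutrophilic` (flags are `NA`
#'   when there are no points).
#' @export
differential_count <- function(points, classes = cp_classes()) {
  dfs <- if (inherits(points, "cp_annotations")) list(points$annotations)
  else if (is.data.frame(points)) list(points)
  else lapply(points, function(p)
    if (inherits(p, "cp_annotations")) p$annotations else as.data.frame(p))
  cls <- unlist(lapply(dfs, function(d) d$cell_class))
  counts <- vapply(classes, function(cl) sum(cls == cl), numeric(1))
  total <- sum(counts)
  pct <- if (total > 0) 100 * counts / total else rep(NA_real_,
                                                      length(counts))
  out <- data.frame(cell_class = classes, count = unname(counts),
                    percent = unname(pct), stringsAsFactors = FALSE)
  eos <- if (total > 0) unname(pct["eosinophil"] > 3) else NA
  neu <- if (total > 0) unname(pct["neutrophil"] > 61) else NA
  structure(out, class = c("cp_diff_count", "data.frame"),
            total = total, eosinophilic = eos, neutrophilic = neu)
}

#' @export
print.cp_diff_count <- function(x, ...) {
  cat(sprintf("<differential count> total %d cells\n", attr(x, "total")))
  print.data.frame(transform(as.data.frame(x),
                             percent = round(percent, 1)))
  cat(sprintf("eosinophilic (>3%%): %s   neutrophilic (>61%%): %s\n",
              attr(x, "eosinophilic"), attr(x, "neutrophilic")))
  invisible(x)
}

#' Cytospin-level train/holdout split
#'
#' Splits tiles by cytospin so no tile of a held-out cytospin reaches
#' training (the grouping that prevents within-slide leakage). With 19
#' cytospins of 40 tiles and 2 held out this yields the published 680
#' training tiles (89.5%) and 80 holdout tiles (10.5%).
#'
#' @param cytospins named list: cytospin id -> character vector of tile
#'   ids. Groups must be disjoint.
#' @param holdout_ids cytospin ids to hold out.
#' @return List with `train`, `holdout` (tile id vectors) and `report`
#'   (counts and percentages, percentages to one decimal).
#' @export
dataset_split <- function(cytospins, holdout_ids) {
  all_tiles <- unlist(cytospins, use.names = FALSE)
  if (anyDuplicated(all_tiles))
    stop("dataset_split: cytospin tile groups overlap")
  unknown <- setdiff(holdout_ids, names(cytospins))
  if (length(unknown) > 0)
    stop("dataset_split: unknown cytospin id(s): ",
         paste(unknown, collapse = ", "))
  hold <- unlist(cytospins[names(cytospins) %in% holdout_ids],
                 use.names = FALSE)
  if (is.null(hold)) hold <- character(0)
  train <- setdiff(all_tiles, hold)
  n <- length(all_tiles)
  report <- data.frame(
    subset = c("train", "holdout"),
    n_cytospins = c(length(cytospins) - length(holdout_ids),
                    length(holdout_ids)),
    n_tiles = c(length(train), length(hold)),
    percent = round(100 * c(length(train), length(hold)) / n, 1))
  list(train = train, holdout = hold, report = report)
}
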