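cc16 <- default_class_config(scale = 1 / 16)

test_that("matching basics: identity, threshold edge, bookkeeping", {
  gt <- data.frame(x = c(10, 30), y = c(10, 30),
                   cell_class = c("neutrophil", "lymphocyte"))
  pr <- transform(gt, score = c(0.9, 0.8))
  m <- match_centres(pr, gt, 0.5, cc16)
  expect_equal(nrow(m$tp), 2)
  expect_length(m$fp, 0)
  expect_length(m$fn, 0)

  # strictly outside delta x diameter -> FP + FN
  thr <- 0.5 * cc16$diameter_px[cc16$cell_class == "neutrophil"]
  gt1 <- data.frame(x = 10, y = 10, cell_class = "neutrophil")
  pr1 <- data.frame(x = 10 + 1.01 * thr, y = 10,
                    cell_class = "neutrophil", score = 1)
  m <- match_centres(pr1, gt1, 0.5, cc16)
  expect_equal(nrow(m$tp), 0)
  expect_length(m$fp, 1)
  expect_length(m$fn, 1)

  # class mismatch never matches even at distance 0
  pr2 <- data.frame(x = 10, y = 10, cell_class = "lymphocyte", score = 1)
  m <- match_centres(pr2, gt1, 0.5, cc16)
  expect_equal(nrow(m$tp), 0)

  expect_error(match_centres(pr1, gt1, 0, cc16), "delta")
})

test_that("greedy matching tracks the exhaustive assignment oracle", {
  set.seed(50)
  deficits <- integer(0)
  for (trial in 1:100) {
    gt <- cp_random_scene(cc16)
    pr <- cp_random_scene(cc16)
    if (nrow(pr) > 0) pr$score <- runif(nrow(pr))
    mg <- match_centres(pr, gt, 0.5, cc16)
    opt <- oracle_max_tp(pr, gt, 0.5, cc16)
    expect_lte(nrow(mg$tp), opt)
    # in-package optimal matcher must reach the oracle maximum
    mo <- match_centres(pr, gt, 0.5, cc16, method = "optimal")
    expect_equal(nrow(mo$tp), opt)
    deficits <- c(deficits, opt - nrow(mg$tp))
    # bookkeeping invariants: TP + FN = GT, TP + FP = predictions
    expect_equal(nrow(mg$tp) + length(mg$fn), nrow(gt))
    expect_equal(nrow(mg$tp) + length(mg$fp), nrow(pr))
  }
  # documented greedy contract: rarely (and by at most 1) below optimal
  expect_lte(max(deficits), 1)
  expect_gte(mean(deficits == 0), 0.95)
})

test_that("AP equals hand-enumerated PR area on the worked case", {
  # ranked flags TP,FP,TP,TP,FP over 3 ground truths:
  # precisions 1, 1/2, 2/3, 3/4, 3/5 at recalls 1/3, 1/3, 2/3, 1, 1;
  # interpolated area = (1/3)(1) + (1/3)(3/4) + (1/3)(3/4) = 5/6
  ap <- cytopoint:::ap_from_flags(scores = c(0.9, 0.8, 0.7, 0.6, 0.5),
                                  is_tp = c(TRUE, FALSE, TRUE, TRUE,
                                            FALSE),
                                  n_gt = 3)
  expect_equal(ap, (1 + 3 / 4 + 3 / 4) / 3, tolerance = 1e-12)

  # perfect detector and empty detector
  expect_equal(cytopoint:::ap_from_flags(c(0.9, 0.8), c(TRUE, TRUE), 2), 1)
  expect_equal(cytopoint:::ap_from_flags(numeric(0), logical(0), 3), 0)

  # uniform scores reduce to precision x recall at one operating point
  expect_equal(cytopoint:::ap_from_flags(rep(1, 4),
                                         c(TRUE, TRUE, TRUE, FALSE), 6),
               (3 / 4) * (3 / 6))
})

test_that("evaluate_detections reports per class, delta and total", {
  gt <- annotation_set("t", 64, 64,
                       data.frame(x = c(10, 30, 50), y = c(10, 30, 50),
                                  cell_class = c("neutrophil",
                                                 "neutrophil",
                                                 "eosinophil"),
                                  assessor_id = "consensus"))
  pr <- data.frame(x = c(10, 30, 50), y = c(10, 30, 50),
                   cell_class = c("neutrophil", "neutrophil",
                                  "eosinophil"),
                   score = c(0.9, 0.8, 0.7))
  rep <- evaluate_detections(list(pr), list(gt), cc16)
  neut <- rep[rep$cell_class == "neutrophil", ]
  expect_equal(neut$AP, rep(1, 3))
  expect_equal(neut$F1, rep(1, 3))
  tot <- rep[rep$cell_class == "total_immune_cell", ]
  expect_equal(tot$AP, rep(1, 3))
  expect_true(all(is.na(rep$AP[rep$cell_class == "lymphocyte"])))

  # AP and F1 non-decreasing in delta for fixed predictions
  set.seed(60)
  gt2 <- cp_random_scene(cc16)
  pr2 <- gt2
  pr2$x <- pr2$x + rnorm(nrow(pr2), 0, 2)
  pr2$y <- pr2$y + rnorm(nrow(pr2), 0, 2)
  pr2$score <- runif(nrow(pr2))
  gts <- annotation_set("t", 128, 128,
                        transform(gt2, assessor_id = "consensus",
                                  x = pmin(gt2$x, 127),
                                  y = pmin(gt2$y, 127)))
  rep2 <- evaluate_detections(list(pr2), list(gts), cc16)
  tot2 <- rep2[rep2$cell_class == "total_immune_cell", ]
  expect_true(all(diff(tot2$AP) >= -1e-12))
  expect_true(all(diff(tot2$F1) >= -1e-12))
})

test_that("evaluate_detections handles tiles with zero predictions", {
  gt <- annotation_set("t", 64, 64,
                       data.frame(x = 10, y = 10,
                                  cell_class = "neutrophil",
                                  assessor_id = "consensus"))
  empty <- data.frame(tile_id = character(0), x = numeric(0),
                      y = numeric(0), cell_class = character(0),
                      score = numeric(0))
  rep <- evaluate_detections(list(empty), list(gt), cc16, deltas = 0.5)
  neut <- rep[rep$cell_class == "neutrophil", ]
  expect_equal(neut$AP, 0)
  expect_equal(neut$FN, 1)
  tot <- rep[rep$cell_class == "total_immune_cell", ]
  expect_equal(tot$AP, 0)

  # zero-prediction matching directly
  m <- match_centres(empty, gt, 0.5, cc16)
  expect_equal(nrow(m$tp), 0)
  expect_length(m$fn, 1)
})

test_that("informative scores beat permuted scores in expectation", {
  set.seed(61)
  # half the predictions are TP; give TPs systematically higher scores
  is_tp <- rep(c(TRUE, FALSE), each = 20)
  scores <- ifelse(is_tp, runif(40, 0.5, 1), runif(40, 0, 0.5))
  ap_inf <- cytopoint:::ap_from_flags(scores, is_tp, 25)
  perm <- replicate(100, cytopoint:::ap_from_flags(sample(scores), is_tp,
                                                   25))
  expect_gt(ap_inf, mean(perm))
})

test_that("F1 formula and edge cases", {
  expect_equal(f1_score(10, 0, 0), 1)
  expect_equal(f1_score(0, 3, 2), 0)
  expect_equal(f1_score(0, 0, 0), 0)
  expect_equal(f1_score(3, 2, 1), 6 / 9)
})

test_that("ICC(A,1) matches the from-scratch ANOVA oracle", {
  set.seed(70)
  for (i in 1:100) {
    m <- matrix(sample(0:30, 80, TRUE), 20, 4)
    if (stats::sd(m) == 0) next
    expect_equal(icc_a1(m)$icc, oracle_icc_a1(m), tolerance = 1e-10)
  }

  # identical raters on varying subjects: perfect agreement
  base <- c(1, 5, 9, 14)
  expect_equal(icc_a1(cbind(base, base, base))$icc, 1)

  # pure rater bias drops agreement below 1
  expect_lt(icc_a1(cbind(base, base + 3))$icc, 1)

  # degenerate constant matrix
  r <- icc_a1(matrix(2, 5, 3))
  expect_true(r$degenerate)
  expect_equal(r$icc, 1)

  expect_error(icc_a1(matrix(1, 1, 4)), "at least 2")
  expect_error(icc_a1(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("ICC invariances: common shift and subject relabeling", {
  set.seed(71)
  m <- matrix(rnorm(60, 10, 3), 15, 4)
  expect_equal(icc_a1(m)$icc, icc_a1(m + 100)$icc, tolerance = 1e-12)
  expect_equal(icc_a1(m)$icc, icc_a1(m[sample(15), ])$icc,
               tolerance = 1e-12)
})

test_that("differential counts, percentages and determinations", {
  mk <- function(counts) {
    data.frame(cell_class = rep(cp_classes(), counts))
  }
  dc <- differential_count(mk(c(45, 45, 5, 5)))
  expect_equal(dc$percent, c(45, 45, 5, 5))
  expect_true(attr(dc, "eosinophilic"))
  expect_false(attr(dc, "neutrophilic"))

  # strict boundary: 61/100 neutrophils is NOT neutrophilic
  dc <- differential_count(mk(c(30, 61, 4, 5)))
  expect_false(attr(dc, "neutrophilic"))
  expect_true(attr(dc, "eosinophilic"))  # 4% > 3%
  dc <- differential_count(mk(c(29, 62, 4, 5)))
  expect_true(attr(dc, "neutrophilic"))

  # 5 eosinophils of 100
  dc <- differential_count(mk(c(60, 30, 5, 5)))
  expect_equal(dc$percent[dc$cell_class == "eosinophil"], 5)
  expect_true(attr(dc, "eosinophilic"))

  # scale invariance: duplicating points preserves percentages and flags
  pts <- mk(c(12, 7, 1, 3))
  d1 <- differential_count(pts)
  d2 <- differential_count(rbind(pts, pts))
  expect_equal(d1$percent, d2$percent)
  expect_identical(attr(d1, "eosinophilic"), attr(d2, "eosinophilic"))

  # percentages sum to 100
  expect_equal(sum(d1$percent), 100, tolerance = 1e-9)

  # zero points: counts reported, flags absent
  d0 <- differential_count(mk(c(0, 0, 0, 0)))
  expect_equal(sum(d0$count), 0)
  expect_true(is.na(attr(d0, "eosinophilic")))
})

test_that("dataset_split reproduces the cytospin-level bookkeeping", {
  groups <- setNames(
    lapply(1:19, function(i) sprintf("cs%02d_t%03d", i, 1:40)),
    sprintf("cs%02d", 1:19))
  sp <- dataset_split(groups, c("cs03", "cs17"))
  expect_equal(length(sp$train), 680)
  expect_equal(length(sp$holdout), 80)
  expect_equal(sp$report$percent, c(89.5, 10.5))
  expect_equal(intersect(sp$train, sp$holdout), character(0))

  sp0 <- dataset_split(groups, character(0))
  expect_equal(length(sp0$train), 760)
  expect_equal(length(sp0$holdout), 0)

  expect_error(dataset_split(groups, "cs99"), "unknown")
  bad <- groups
  bad$cs01 <- c(bad$cs01, bad$cs02[1])
  expect_error(dataset_split(bad, "cs03"), "overlap")
})
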