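cc16 <- default_class_config(scale = 1 / 16)

test_that("encode places unit peaks and exact Gaussian falloff", {
  ann <- annotation_set("t", 64, 64,
                        data.frame(x = 20, y = 30,
                                   cell_class = "neutrophil",
                                   assessor_id = "a"))
  hm <- encode_targets(ann, cc16, 64, 1)
  expect_equal(hm[31, 21, 2], 1)
  expect_equal(max(hm[, , -2]), 0)

  # sigma' = 8: value at offset (8, 0) is exp(-1/2)
  cs <- class_config("neutrophil", diameter_px = 32, sigma_px = 8)
  ann <- annotation_set("t", 64, 64,
                        data.frame(x = 32, y = 32,
                                   cell_class = "neutrophil",
                                   assessor_id = "a"))
  h <- encode_targets(ann, cs, 64, 1)
  expect_equal(h[33, 41, 1], exp(-1 / 2), tolerance = 1e-12)
  expect_equal(h[33, 33, 1], 1)

  # truncation: strictly beyond 4 sigma the kernel is written as 0
  # (corner of the window is ~5.6 sigma away; exactly 4 sigma is kept)
  expect_equal(h[1, 1, 1], 0)
  expect_equal(h[33, 1, 1], exp(-8), tolerance = 1e-12)
})

test_that("overlapping kernels combine by per-pixel maximum", {
  cs <- class_config("neutrophil", diameter_px = 32, sigma_px = 8)
  ann <- annotation_set("t", 64, 64,
                        data.frame(x = c(29, 35), y = c(32, 32),
                                   cell_class = "neutrophil",
                                   assessor_id = "a"))
  h <- encode_targets(ann, cs, 64, 1)
  # brute-force per-pixel two-kernel oracle
  ker <- function(x, y, x0, y0) {
    v <- exp(-((x - x0)^2 + (y - y0)^2) / (2 * 8^2))
    ifelse(v < exp(-8), 0, v)
  }
  for (px in seq(0, 63, by = 3)) {
    for (py in seq(0, 63, by = 3)) {
      want <- max(ker(px, py, 29, 32), ker(px, py, 35, 32))
      if ((px == 29 || px == 35) && py == 32) want <- 1
      expect_equal(h[py + 1, px + 1, 1], want, tolerance = 1e-12)
    }
  }
})

test_that("encode validates geometry and rescales coordinates", {
  ann <- annotation_set("t", 64, 64,
                        data.frame(x = 40, y = 40,
                                   cell_class = "lymphocyte",
                                   assessor_id = "a"))
  expect_error(encode_targets(ann, cc16, 60, 1), "tile size")
  bad <- class_config(cp_classes(), diameter_px = rep(10, 4))
  bad$sigma_px <- c(-1, 1, 1, 1)
  expect_error(encode_targets(
    annotation_set("t", 64, 64,
                   data.frame(x = 1, y = 1,
                              cell_class = "macrophage_lineage",
                              assessor_id = "a")), bad, 64, 1), "sigma")

  # scale_factor 4: native (40, 40) lands on heatmap pixel (10, 10)
  ann4 <- annotation_set("t", 256, 256,
                         data.frame(x = 40, y = 40,
                                    cell_class = "lymphocyte",
                                    assessor_id = "a"))
  h <- encode_targets(ann4, default_class_config(scale = 1 / 4), 64, 4)
  expect_equal(h[11, 11, 4], 1)
  expect_equal(attr(h, "scale_factor"), 4)
})

test_that("decode extracts one peak per admissible cluster", {
  empty <- heatmap_tensor(array(0, c(32, 32, 4)), cc16, 1)
  expect_equal(nrow(decode_peaks(empty)), 0)

  iso <- cp_isolated_config()
  ann <- annotation_set("t", 64, 64,
                        data.frame(x = 30, y = 20,
                                   cell_class = "eosinophil",
                                   assessor_id = "a"))
  h <- encode_targets(ann, iso, 64, 1)
  # supra-threshold area of a sigma' = 1.5 kernel is <= 16 px (exhaustive)
  expect_lte(sum(unclass(h)[, , 3] > 0.5), 16)
  pk <- decode_peaks(h, classes = iso)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$x, 30)
  expect_equal(pk$y, 20)
  expect_equal(pk$score, 1)
  expect_equal(pk$cell_class, "eosinophil")

  # two kernels 30 px apart decode to two centres within 1 px
  ann2 <- annotation_set("t", 64, 64,
                         data.frame(x = c(15, 45), y = c(32, 32),
                                    cell_class = "eosinophil",
                                    assessor_id = "a"))
  pk2 <- decode_peaks(encode_targets(ann2, iso, 64, 1), classes = iso)
  pk2 <- pk2[order(pk2$x), ]
  expect_equal(nrow(pk2), 2)
  expect_true(all(abs(pk2$x - c(15, 45)) <= 1))
  expect_true(all(abs(pk2$y - 32) <= 1))
})

test_that("oversized clusters split at separated regional maxima", {
  cs <- class_config("neutrophil", diameter_px = 16, sigma_px = 4)
  ann <- annotation_set("t", 64, 64,
                        data.frame(x = c(20, 40), y = c(32, 32),
                                   cell_class = "neutrophil",
                                   assessor_id = "a"))
  h <- encode_targets(ann, cs, 64, 1)
  expect_gt(sum(unclass(h)[, , 1] > 0.5), 16)  # genuinely oversized
  pk <- decode_peaks(h, classes = cs)
  pk <- pk[order(pk$x), ]
  expect_equal(nrow(pk), 2)
  expect_true(all(abs(pk$x - c(20, 40)) <= 1))
  expect_equal(nrow(decode_peaks(h, classes = cs, oversized = "discard")),
               0)
})

test_that("round-trip recovers isolated planted centres with class", {
  iso <- cp_isolated_config()
  set.seed(5)
  for (trial in 1:10) {
    # centres > 6 sigma' apart (sigma' = 1.5 -> separation > 9)
    n <- 6
    repeat {
      x <- runif(n, 4, 59); y <- runif(n, 4, 59)
      if (min(dist(cbind(x, y))) > 10) break
    }
    cls <- sample(cp_classes(), n, TRUE)
    ann <- annotation_set("t", 64, 64,
                          data.frame(x = x, y = y, cell_class = cls,
                                     assessor_id = "a"))
    pk <- decode_peaks(encode_targets(ann, iso, 64, 1), classes = iso)
    expect_equal(nrow(pk), n)
    for (i in seq_len(n)) {
      d <- sqrt((pk$x - x[i])^2 + (pk$y - y[i])^2)
      j <- which.min(d)
      expect_lte(d[j], 1)
      expect_equal(pk$cell_class[j], cls[i])
    }
  }
})

test_that("decode threshold monotonicity and channel permutation", {
  # monotonicity on well-formed (encoded Gaussian) heatmaps: raising the
  # threshold never increases the number of decoded predictions
  iso <- cp_isolated_config()
  set.seed(9)
  ann <- annotation_set("t", 64, 64,
                        data.frame(x = runif(6, 6, 57),
                                   y = runif(6, 6, 57),
                                   cell_class = sample(cp_classes(), 6,
                                                       TRUE),
                                   assessor_id = "a"))
  hmono <- encode_targets(ann, iso, 64, 1)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9, 0.999),
                   function(th) nrow(decode_peaks(hmono, th,
                                                  classes = iso)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))

  vals <- array(runif(32 * 32 * 4)^3, c(32, 32, 4))
  hm <- heatmap_tensor(vals, cc16, 1)

  perm <- c(3, 1, 4, 2)
  hp <- heatmap_tensor(vals[, , perm], cc16[perm, ], 1)
  a <- decode_peaks(hm, classes = cc16)
  b <- decode_peaks(hp, classes = cc16[perm, ])
  key <- function(d) d[order(d$cell_class, d$x, d$y),
                       c("x", "y", "cell_class", "score")]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
})

test_that("channel maxima are 1 exactly on annotated channels", {
  ann <- annotation_set("t", 64, 64,
                        data.frame(x = c(10.3, 50), y = c(10.7, 50),
                                   cell_class = c("neutrophil",
                                                  "neutrophil"),
                                   assessor_id = "a"))
  h <- encode_targets(ann, cc16, 64, 1)
  expect_equal(max(h[, , 2]), 1)
  expect_equal(max(h[, , 1]), 0)
  expect_equal(max(h[, , 3]), 0)
})

test_that("heatmap TIFF persistence round-trips", {
  ann <- annotation_set("t", 64, 64,
                        data.frame(x = 22, y = 41,
                                   cell_class = "macrophage_lineage",
                                   assessor_id = "a"))
  hm <- encode_targets(ann, cc16, 64, 1)
  path <- tempfile(fileext = ".tif")
  write_heatmap(hm, path)
  back <- read_heatmap(path)
  expect_equal(unclass(back), unclass(hm), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(attr(back, "scale_factor"), 1)
  expect_equal(attr(back, "class_names"), cp_classes())
  # float32 persistence must keep exact 0/1 so the loss branch survives
  expect_equal(max(unclass(back)), 1)
})
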