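test_that("read_annotations parses, groups and validates", {
  csv <- tempfile(fileext = ".csv")
  header <- "tile_id,x,y,cell_class,assessor_id"

  writeLines(header, csv)
  expect_identical(read_annotations(csv, 64, 64), list())

  writeLines(c(header,
               "t1,10,20,neutrophil,a1",
               "t1,30,40,lymphocyte,a1",
               "t1,10,20,neutrophil,a2",
               "t2,5,5,eosinophil,a1"), csv)
  sets <- read_annotations(csv, 64, 64)
  expect_length(sets, 3)
  expect_equal(nrow(sets[[1]]$annotations), 2)
  expect_equal(sets[[1]]$annotations$cell_class,
               c("neutrophil", "lymphocyte"))

  writeLines(c(header, "t1,10,20,monocyte,a1"), csv)
  expect_error(read_annotations(csv, 64, 64), "monocyte")

  writeLines(c(header, "t1,64,20,neutrophil,a1"), csv)
  expect_error(read_annotations(csv, 64, 64), "bounds")

  writeLines(c("tile_id,x,y,assessor_id", "t1,1,2,a1"), csv)
  expect_error(read_annotations(csv, 64, 64), "cell_class")

  # JSON dialect agrees with CSV
  json <- tempfile(fileext = ".json")
  df <- data.frame(tile_id = "t1", x = c(1, 2), y = c(3, 4),
                   cell_class = "neutrophil", assessor_id = "a1")
  jsonlite::write_json(df, json, dataframe = "rows")
  sets <- read_annotations(json, 64, 64)
  expect_length(sets, 1)
  expect_equal(sets[[1]]$annotations$x, c(1, 2))
})

test_that("annotation CSV round-trips through write_annotations", {
  s <- annotation_set("t9", 64, 64,
                      data.frame(x = c(1.5, 10), y = c(2.5, 20),
                                 cell_class = c("eosinophil", "neutrophil"),
                                 assessor_id = "a1"))
  path <- tempfile(fileext = ".csv")
  write_annotations(s, path)
  back <- read_annotations(path, 64, 64)
  expect_equal(back[[1]]$annotations, s$annotations)
})

test_that("consensus merges clicks with majority vote at the centroid", {
  mk <- function(assessor, cls, x = 20, y = 20)
    annotation_set("t", 64, 64,
                   data.frame(x = x, y = y, cell_class = cls,
                              assessor_id = assessor))
  sets <- list(mk("a1", "neutrophil"), mk("a2", "neutrophil"),
               mk("a3", "neutrophil"), mk("a4", "lymphocyte"))
  cr <- consolidate_consensus(sets)
  expect_equal(nrow(cr$consensus$annotations), 1)
  expect_equal(cr$consensus$annotations$cell_class, "neutrophil")
  expect_equal(cr$consensus$annotations$x, 20)
  expect_equal(cr$conflicts$resolution, "majority")

  # two points 11 px apart stay separate at the 10 px radius
  sets <- list(mk("a1", "neutrophil", x = 20),
               mk("a2", "neutrophil", x = 31))
  cr <- consolidate_consensus(sets)
  expect_equal(nrow(cr$consensus$annotations), 2)

  # tied votes are flagged, not silently resolved
  sets <- list(mk("a1", "neutrophil"), mk("a2", "neutrophil"),
               mk("a3", "lymphocyte"), mk("a4", "lymphocyte"))
  cr <- consolidate_consensus(sets)
  expect_equal(cr$conflicts$resolution, "flagged_tie")

  expect_error(consolidate_consensus(sets[1]), "at least 2")
  bad <- mk("a1", "neutrophil")
  bad$tile_id <- "other"
  expect_error(consolidate_consensus(list(bad, mk("a2", "neutrophil"))),
               "tile ids")
})

test_that("clustering matches the exhaustive pairwise-graph oracle", {
  set.seed(41)
  for (trial in 1:50) {
    # planted clusters plus scattered singletons
    n_clust <- sample(1:6, 1)
    cx <- runif(n_clust, 30, 480)
    cy <- runif(n_clust, 30, 480)
    x <- y <- numeric(0)
    for (k in seq_len(n_clust)) {
      m <- sample(1:5, 1)
      x <- c(x, cx[k] + runif(m, -7, 7))
      y <- c(y, cy[k] + runif(m, -7, 7))
    }
    x <- c(x, runif(5, 0, 511)); y <- c(y, runif(5, 0, 511))
    got <- cytopoint:::cluster_points_single(x, y, 10)
    want <- oracle_cluster(x, y, 10)
    # same partition up to label names
    expect_equal(table(got)[as.character(got)],
                 table(want)[as.character(want)],
                 ignore_attr = TRUE)
    expect_true(all(tapply(want, got, function(v) length(unique(v))) == 1))
  }
})

test_that("consensus is permutation-invariant, idempotent and conserving", {
  set.seed(7)
  mkset <- function(a) {
    n <- 12
    annotation_set("t", 512, 512,
                   data.frame(x = runif(n, 0, 511), y = runif(n, 0, 511),
                              cell_class = sample(cp_classes(), n, TRUE),
                              assessor_id = a))
  }
  sets <- lapply(paste0("a", 1:4), mkset)
  cr1 <- consolidate_consensus(sets)
  cr2 <- consolidate_consensus(rev(sets))
  ord <- function(df) df[order(df$x, df$y), ]
  expect_equal(ord(cr1$consensus$annotations),
               ord(cr2$consensus$annotations), ignore_attr = TRUE)

  # count conservation: members across clusters = inputs
  expect_equal(sum(cr1$conflicts$n_members),
               sum(vapply(sets, function(s) nrow(s$annotations),
                          numeric(1))))

  # idempotence: merging the consensus with itself re-yields it
  c2 <- cr1$consensus
  cr3 <- consolidate_consensus(list(cr1$consensus, c2))
  expect_equal(ord(cr3$consensus$annotations)[, c("x", "y", "cell_class")],
               ord(cr1$consensus$annotations)[, c("x", "y", "cell_class")],
               ignore_attr = TRUE)
})

test_that("compute_class_config takes per-class medians, sigma = radius", {
  m <- data.frame(cell_class = rep("lymphocyte", 5), diameter_px = 61)
  others <- data.frame(cell_class = rep(setdiff(cp_classes(),
                                                "lymphocyte"), each = 1),
                       diameter_px = c(142, 104, 126))
  cc <- compute_class_config(rbind(m, others))
  expect_equal(cc$diameter_px[cc$cell_class == "lymphocyte"], 61)
  expect_equal(cc$sigma_px[cc$cell_class == "lymphocyte"], 30.5)

  m2 <- data.frame(cell_class = "neutrophil",
                   diameter_px = c(100, 104, 120))
  expect_equal(compute_class_config(rbind(m2, m, others))$diameter_px[
    cp_classes() == "neutrophil"], 104)

  # sort-based oracle on 1000 random draws
  set.seed(11)
  d <- rexp(1000, 1 / 100)
  big <- data.frame(cell_class = "macrophage_lineage", diameter_px = d)
  rest <- data.frame(cell_class = rep(setdiff(cp_classes(),
                                              "macrophage_lineage"), 2),
                     diameter_px = 50)
  got <- compute_class_config(rbind(big, rest))$diameter_px[1]
  sorted <- sort(d)
  expect_equal(got, (sorted[500] + sorted[501]) / 2)

  expect_error(compute_class_config(m), "macrophage_lineage")
})

test_that("class config YAML round-trips", {
  cc <- default_class_config()
  path <- tempfile(fileext = ".yaml")
  write_class_config(cc, path)
  expect_equal(read_class_config(path), cc, ignore_attr = TRUE)
})
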