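# Shared fixtures: the scaled-down 64-px synthetic world used by the fast
# tests, plus small independent oracles.

# 64-px world: self-similar rescale of the 1024-px tile defaults
cp_world64 <- function() scene_config(tile_size = 64)

# training-style dataset of n tiles from the 64-px world
cp_gen_dataset <- function(n, seed0, cfg = cp_world64()) {
  lapply(seq_len(n), function(i) {
    tl <- generate_tile(cfg, seed = seed0 + i)
    list(image = tl$image, annotations = tl$truth)
  })
}

# configuration for the isolated-centre round-trip world: uniform
# sigma' = 1.5 heatmap px, centres separated by > 6 sigma'
cp_isolated_config <- function() {
  class_config(cp_classes(), diameter_px = c(142, 104, 126, 61) / 16,
               sigma_px = rep(1.5, 4))
}

# independent clustering oracle: connected components of the
# "distance <= radius" graph via breadth-first search over the full
# pairwise adjacency matrix
oracle_cluster <- function(x, y, radius) {
  n <- length(x)
  adj <- outer(x, x, "-")^2 + outer(y, y, "-")^2 <= radius^2
  lab <- integer(n)
  comp <- 0
  for (i in seq_len(n)) {
    if (lab[i] != 0) next
    comp <- comp + 1
    queue <- i
    lab[i] <- comp
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & lab == 0)
      lab[nb] <- comp
      queue <- c(queue, nb)
    }
  }
  lab
}

# scalar per-pixel focal loss loop, the independent oracle for Eq-style
# vectorised implementations
oracle_focal_loop <- function(pred, target, alpha = 2, beta = 2,
                              eps = 1e-6) {
  p <- as.numeric(pred)
  y <- as.numeric(target)
  n_pos <- 0
  acc <- 0
  for (i in seq_along(p)) {
    pi <- min(max(p[i], eps), 1 - eps)
    if (y[i] == 1) {
      n_pos <- n_pos + 1
      acc <- acc + (1 - pi)^alpha * log(pi)
    } else {
      acc <- acc + (1 - y[i])^beta * pi^alpha * log(1 - pi)
    }
  }
  -acc / max(1, n_pos)
}

# exhaustive assignment oracle: maximum number of prediction/ground-truth
# pairs of equal class within threshold, by recursion over predictions
oracle_max_tp <- function(pr, gt, delta, classes) {
  total <- 0
  for (cl in unique(pr$cell_class)) {
    pi <- which(pr$cell_class == cl)
    gi <- which(gt$cell_class == cl)
    if (length(pi) == 0 || length(gi) == 0) next
    thr <- delta * classes$diameter_px[match(cl, classes$cell_class)]
    adj <- sqrt(outer(pr$x[pi], gt$x[gi], "-")^2 +
                  outer(pr$y[pi], gt$y[gi], "-")^2) <= thr
    best <- 0
    recurse <- function(u, used, count) {
      if (count + (length(pi) - u + 1) <= best) return(invisible(NULL))
      if (u > length(pi)) {
        best <<- max(best, count)
        return(invisible(NULL))
      }
      recurse(u + 1, used, count)  # leave prediction u unmatched
      for (v in which(adj[u, ] & !used)) {
        used[v] <- TRUE
        recurse(u + 1, used, count + 1)
        used[v] <- FALSE
      }
    }
    recurse(1, rep(FALSE, length(gi)), 0)
    total <- total + best
  }
  total
}

# independent two-way ANOVA mean squares via stats::aov
oracle_icc_a1 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(value = as.vector(m),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(value ~ subject + rater, data = df))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# a random detection scene: <= max_per points per class in a tile
cp_random_scene <- function(classes, tile = 64, max_per = 6) {
  rows <- list()
  for (cl in classes$cell_class) {
    np <- sample(0:max_per, 1)
    if (np == 0) next
    rows[[length(rows) + 1]] <-
      data.frame(x = runif(np, 0, tile - 1), y = runif(np, 0, tile - 1),
                 cell_class = cl, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(x = numeric(0), y = numeric(0),
                      cell_class = character(0)))
  do.call(rbind, rows)
}
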