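#' Training configuration
#'
#' Defaults follow the published recipe where one is stated: 60 epochs and
#' a fixed weight decay of 1e-5. Optimiser (Adam with decoupled weight
#' decay), one-cycle learning-rate schedule and batch size 8 are package
#' choices. Augmentations are the published set -- random rotation, warp
#' (small random shear), colour jitter, horizontal/vertical flips -- with
#' magnitudes as package defaults; geometric augmentations transform image
#' and annotations jointly and targets are re-encoded afterwards.
#'
#' @param epochs training epochs (default 60).
#' @param learning_rate peak learning rate of the one-cycle schedule.
#' @param weight_decay decoupled weight decay on convolution weights
#'   (default 1e-5).
#' @param batch_size minibatch size.
#' @param alpha focal-loss exponent passed to [focal_loss()].
#' @param augment list of augmentation settings: `rotation` (max degrees),
#'   `warp` (max shear fraction), `hflip`, `vflip` (logical),
#'   `color_jitter` (max relative gain), `enabled`.
#' @param seed integer; fixes initialisation, shuffling and augmentation
#'   draws.
#' @return A `cp_train_config`.
#' @export
train_config <- function(epochs = 60, learning_rate = 2e-3,
                         weight_decay = 1e-5, batch_size = 8, alpha = 2,
                         augment = list(), seed = 0) {
  aug <- modifyList(list(enabled = TRUE, rotation = 15, warp = 0.08,
                         hflip = TRUE, vflip = TRUE, color_jitter = 0.1),
                    augment)
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 weight_decay = weight_decay, batch_size = batch_size,
                 alpha = alpha, augment = aug, seed = seed),
            class = "cp_train_config")
}

# jointly transform an image (H x W x 3, [0,1]) and its centre points by a
# random affine map (rotation + shear + flips) about the image centre,
# nearest-neighbour sampling with edge clamping; points leaving the tile
# are dropped. Colour jitter perturbs channel gains and brightness.
augment_sample <- function(img, ann, aug) {
  H <- dim(img)[1]; W <- dim(img)[2]
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  th <- runif(1, -aug$rotation, aug$rotation) * pi / 180
  shx <- runif(1, -aug$warp, aug$warp)
  shy <- runif(1, -aug$warp, aug$warp)
  fx <- if (isTRUE(aug$hflip) && runif(1) < 0.5) -1 else 1
  fy <- if (isTRUE(aug$vflip) && runif(1) < 0.5) -1 else 1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Sh <- matrix(c(1, shy, shx, 1), 2, 2)
  A <- R %*% Sh %*% diag(c(fx, fy))
  Ai <- solve(A)
  # image: inverse-map each output pixel to a source pixel
  gx <- rep(0:(W - 1), each = H)
  gy <- rep(0:(H - 1), W)
  sx <- Ai[1, 1] * (gx - cx) + Ai[1, 2] * (gy - cy) + cx
  sy <- Ai[2, 1] * (gx - cx) + Ai[2, 2] * (gy - cy) + cy
  sxi <- pmin(pmax(round(sx), 0), W - 1) + 1
  syi <- pmin(pmax(round(sy), 0), H - 1) + 1
  out <- img
  for (ch in 1:3)
    out[, , ch] <- matrix(img[, , ch][cbind(syi, sxi)], H, W)
  if (aug$color_jitter > 0) {
    gain <- runif(3, 1 - aug$color_jitter, 1 + aug$color_jitter)
    off <- runif(1, -aug$color_jitter / 2, aug$color_jitter / 2)
    for (ch in 1:3)
      out[, , ch] <- pmin(pmax(out[, , ch] * gain[ch] + off, 0), 1)
  }
  if (nrow(ann) > 0) {
    px <- A[1, 1] * (ann$x - cx) + A[1, 2] * (ann$y - cy) + cx
    py <- A[2, 1] * (ann$x - cx) + A[2, 2] * (ann$y - cy) + cy
    keep <- px >= 0 & px < W & py >= 0 & py < H
    ann <- ann[keep, , drop = FALSE]
    ann$x <- px[keep]
    ann$y <- py[keep]
  }
  list(image = out, annotations = ann)
}

cp_one_cycle <- function(step, total, lr_max) {
  p <- step / max(1, total)
  warm <- 0.3
  if (p < warm) {
    lr_max * (0.25 + 0.75 * p / warm)
  } else {
    q <- (p - warm) / (1 - warm)
    lr_min <- 0.05 * lr_max
    lr_min + (lr_max - lr_min) * (1 + cos(pi * q)) / 2
  }
}

cp_batch_targets <- function(samples, classes, input_size, cfg, augmenting) {
  n <- length(samples)
  C <- nrow(classes)
  Tm <- matrix(0, n * input_size * input_size, C)
  imgs <- vector("list", n)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    ann <- s$annotations$annotations
    img <- s$image
    if (augmenting) {
      a <- augment_sample(img, ann, cfg$augment)
      img <- a$image
      ann <- a$annotations
    }
    native <- dim(img)[1]
    aset <- annotation_set(s$annotations$tile_id, native, native, ann,
                           classes = s$annotations$classes)
    tgt <- encode_targets(aset, classes, input_size,
                          scale_factor = native / input_size)
    rows <- ((i - 1) * input_size^2 + 1):(i * input_size^2)
    for (ch in seq_len(C))
      Tm[rows, ch] <- as.vector(t(unclass(tgt)[, , ch]))
    imgs[[i]] <- img
  }
  list(X = cp_images_to_batch(imgs, input_size), T = Tm)
}

#' Train the heatmap network
#'
#' Minibatch gradient descent on the penalty-reduced focal loss with Adam,
#' decoupled weight decay and a one-cycle learning-rate schedule. Geometric
#' augmentations are applied to image and annotations jointly, after which
#' the Gaussian targets are re-encoded from the transformed points. All
#' randomness (shuffling, augmentation) is fixed by `cfg$seed`.
#'
#' @param net a `cp_network` from [build_network()].
#' @param dataset non-empty list of samples, each
#'   `list(image = H x W x 3 array in [0,1], annotations = cp_annotations)`
#'   at native tile scale (`H` must be `input_size *` an integer factor).
#' @param cfg a [train_config()].
#' @param classes `cp_class_config` at the native scale of the images.
#' @param valid optional validation dataset (same shape) for per-epoch
#'   validation loss.
#' @return The trained `cp_network`, with `$history` a data frame
#'   `(epoch, train_loss, valid_loss)` (zero rows when `epochs = 0`).
#' @export
train_model <- function(net, dataset, cfg = train_config(),
                        classes = default_class_config(), valid = NULL) {
  stopifnot(inherits(net, "cp_network"), inherits(cfg, "cp_train_config"))
  if (!is.list(dataset) || length(dataset) == 0)
    stop("train_model: dataset is empty")
  S <- net$config$input_size
  net$classes <- classes
  net$history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                            valid_loss = numeric(0))
  if (cfg$epochs == 0) return(net)
  set.seed(cfg$seed)
  P <- list2env(net$params)
  St <- list2env(net$state)
  pnames <- names(net$params)
  M <- list2env(setNames(lapply(net$params, function(p) p * 0), pnames))
  V <- list2env(setNames(lapply(net$params, function(p) p * 0), pnames))
  decay_w <- grepl("\\.W$", pnames)
  nsteps <- 0
  steps_per_epoch <- ceiling(length(dataset) / cfg$batch_size)
  total_steps <- steps_per_epoch * cfg$epochs
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(length(dataset))
    epoch_losses <- numeric(0)
    for (bstart in seq(1, length(dataset), by = cfg$batch_size)) {
      idx <- ord[bstart:min(bstart + cfg$batch_size - 1, length(dataset))]
      bt <- cp_batch_targets(dataset[idx], classes, S, cfg,
                             augmenting = isTRUE(cfg$augment$enabled))
      fwd <- net_forward(net, bt$X, length(idx), P, St, train = TRUE)
      loss <- focal_loss(fwd$out, bt$T, alpha = cfg$alpha)
      if (!is.finite(loss))
        stop(sprintf(
          "train_model: non-finite loss at epoch %d (lr too high?)", epoch))
      epoch_losses <- c(epoch_losses, loss)
      dOut <- focal_loss_grad(fwd$out, bt$T, alpha = cfg$alpha)
      G <- list2env(setNames(lapply(pnames, function(nm) P[[nm]] * 0),
                             pnames))
      net_backward(net, fwd, dOut, P, G)
      nsteps <- nsteps + 1
      lr <- cp_one_cycle(nsteps, total_steps, cfg$learning_rate)
      for (k in seq_along(pnames)) {
        nm <- pnames[k]
        g <- G[[nm]]
        M[[nm]] <- b1 * M[[nm]] + (1 - b1) * g
        V[[nm]] <- b2 * V[[nm]] + (1 - b2) * g * g
        mhat <- M[[nm]] / (1 - b1^nsteps)
        vhat <- V[[nm]] / (1 - b2^nsteps)
        upd <- mhat / (sqrt(vhat) + adam_eps)
        if (decay_w[k]) upd <- upd + cfg$weight_decay * P[[nm]]
        P[[nm]] <- P[[nm]] - lr * upd
      }
    }
    vloss <- NA_real_
    if (!is.null(valid) && length(valid) > 0) {
      vlosses <- numeric(0)
      for (bstart in seq(1, length(valid), by = cfg$batch_size)) {
        idx <- bstart:min(bstart + cfg$batch_size - 1, length(valid))
        bt <- cp_batch_targets(valid[idx], classes, S, cfg,
                               augmenting = FALSE)
        fwd <- net_forward(net, bt$X, length(idx), P, St, train = FALSE)
        vlosses <- c(vlosses, focal_loss(fwd$out, bt$T, alpha = cfg$alpha))
      }
      vloss <- mean(vlosses)
    }
    net$history <- rbind(net$history,
                         data.frame(epoch = epoch,
                                    train_loss = mean(epoch_losses),
                                    valid_loss = vloss))
  }
  net$params <- mget(pnames, envir = P)
  net$state <- mget(names(net$state), envir = St)
  net
}

#' Predict heatmaps for a batch of tiles
#'
#' Tiles are block-mean downscaled to the network input size, standardised
#' as in training, and passed through the network in inference mode (batch
#' norm uses running moments, no augmentation), so repeated calls are
#' deterministic.
#'
#' @param net a trained `cp_network`.
#' @param tiles list of `H x W x 3` arrays in `[0,1]` at native scale.
#' @param classes `cp_class_config` attached to the returned heatmaps;
#'   defaults to the config the network was trained with.
#' @param batch_size forward batch size.
#' @return List of `cp_heatmap`, one per tile, `scale_factor` = native size
#'   / input size.
#' @export
predict_heatmaps <- function(net, tiles, classes = net$classes,
                             batch_size = 8) {
  stopifnot(inherits(net, "cp_network"))
  if (inherits(tiles, "array")) tiles <- list(tiles)
  bad <- vapply(tiles, function(t) length(dim(t)) != 3 || dim(t)[3] != 3,
                logical(1))
  if (any(bad)) stop("predict_heatmaps: tiles must be H x W x 3 arrays")
  S <- net$config$input_size
  C <- net$config$n_classes
  if (is.null(classes)) classes <- default_class_config()
  scale <- dim(tiles[[1]])[1] / S
  P <- list2env(net$params)
  St <- list2env(net$state)
  out <- vector("list", length(tiles))
  for (bstart in seq(1, length(tiles), by = batch_size)) {
    idx <- bstart:min(bstart + batch_size - 1, length(tiles))
    X <- cp_images_to_batch(tiles[idx], S)
    fwd <- net_forward(net, X, length(idx), P, St, train = FALSE)
    hms <- cp_batch_to_heatmaps(fwd$out, length(idx), S, C)
    for (i in seq_along(idx))
      out[[idx[i]]] <- heatmap_tensor(hms[[i]], classes, scale)
  }
  out
}

#' Save / load a network checkpoint
#'
#' Weights are serialized to a single RDS file with a JSON sidecar holding
#' the model configuration (runtime artifact; not a text interchange
#' format).
#'
#' @param net a `cp_network`.
#' @param path checkpoint path (`.rds`).
#' @return `load_network` returns the `cp_network`.
#' @export
save_network <- function(net, path) {
  saveRDS(net, path)
  jsonlite::write_json(net$config[c("input_size", "n_classes",
                                    "encoder_preset")],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "cp_network"))
  net
}
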