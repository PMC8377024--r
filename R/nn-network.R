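#' Model configuration
#'
#' Describes the fully convolutional encoder--decoder: a residual encoder
#' downsampling by 32 and a decoder of 5 upsampling blocks, each a sub-pixel
#' (pixel shuffle) x2 upsample followed by two 3x3 convolutions with batch
#' normalization, with skip connections from the matching encoder
#' resolutions. The head is a 3x3 convolution with logistic activation, so
#' the output is an `input_size x input_size x n_classes` heatmap with
#' values strictly in (0, 1).
#'
#' Presets: `"resnet34_like"` is a 34-layer residual encoder (widths
#' 64/128/256/512, basic blocks 3/4/6/3, strided convolutions for
#' downsampling); `"tiny"` is a 10-ish-layer residual encoder with base
#' width 16 sized so CPU training on 64-px tiles takes minutes.
#'
#' @param input_size square input side in px; must be divisible by 32
#'   (default 256).
#' @param n_classes number of heatmap channels C.
#' @param encoder_preset `"resnet34_like"` or `"tiny"`.
#' @return A `cp_model_config`.
#' @export
model_config <- function(input_size = 256, n_classes = 4,
                         encoder_preset = c("resnet34_like", "tiny")) {
  encoder_preset <- match.arg(encoder_preset)
  if (input_size %% 32 != 0)
    stop("model_config: input_size must be divisible by 32")
  structure(list(input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 encoder_preset = encoder_preset),
            class = "cp_model_config")
}

cp_make_arch <- function(config) {
  C <- config$n_classes
  if (config$encoder_preset == "tiny") {
    ew <- c(16L, 24L, 32L, 48L, 64L)
    stem <- list(conv_spec("stem1", 3L, 16L))
    stem_skip_after <- 1L
    stages <- list()
    prev <- 16L
    for (i in seq_along(ew)) {
      stages[[i]] <- list(
        down = conv_spec(sprintf("s%d.down", i), prev, ew[i], stride = 2),
        blocks = list(list(
          c1 = conv_spec(sprintf("s%d.b1.c1", i), ew[i], ew[i]),
          c2 = conv_spec(sprintf("s%d.b1.c2", i), ew[i], ew[i],
                         act = "none"))))
      prev <- ew[i]
    }
    skip_lab <- c("stage4", "stage3", "stage2", "stage1", "stem")
    skip_ch <- c(ew[4], ew[3], ew[2], ew[1], 16L)
    dw <- c(48L, 32L, 24L, 16L, 16L)
    bottom <- ew[5]
  } else {
    ew <- c(64L, 128L, 256L, 512L)
    nb <- c(3L, 4L, 6L, 3L)
    stem <- list(conv_spec("stem1", 3L, 64L, k = 7, stride = 2),
                 conv_spec("stem2", 64L, 64L, stride = 2))
    stem_skip_after <- 1L
    stages <- list()
    prev <- 64L
    for (i in seq_along(ew)) {
      down <- if (i == 1) NULL else
        conv_spec(sprintf("s%d.down", i), prev, ew[i], stride = 2)
      blocks <- lapply(seq_len(nb[i]), function(b) list(
        c1 = conv_spec(sprintf("s%d.b%d.c1", i, b), ew[i], ew[i]),
        c2 = conv_spec(sprintf("s%d.b%d.c2", i, b), ew[i], ew[i],
                       act = "none")))
      stages[[i]] <- list(down = down, blocks = blocks)
      prev <- ew[i]
    }
    skip_lab <- c("stage3", "stage2", "stage1", "stem", NA)
    skip_ch <- c(ew[3], ew[2], ew[1], 64L, 0L)
    dw <- c(256L, 128L, 64L, 64L, 32L)
    bottom <- ew[4]
  }
  decoder <- list()
  prev <- bottom
  for (j in 1:5) {
    cin <- prev %/% 4L + skip_ch[j]
    decoder[[j]] <- list(
      skip = skip_lab[j],
      c1 = conv_spec(sprintf("d%d.c1", j), cin, dw[j]),
      c2 = conv_spec(sprintf("d%d.c2", j), dw[j], dw[j]))
    prev <- dw[j]
  }
  head <- conv_spec("head", prev, C, bn = FALSE, act = "sigmoid",
                    bias = TRUE)
  list(stem = stem, stem_skip_after = stem_skip_after, stages = stages,
       decoder = decoder, head = head)
}

cp_all_specs <- function(arch) {
  out <- arch$stem
  for (st in arch$stages) {
    if (!is.null(st$down)) out <- c(out, list(st$down))
    for (b in st$blocks) out <- c(out, list(b$c1, b$c2))
  }
  for (d in arch$decoder) out <- c(out, list(d$c1, d$c2))
  c(out, list(arch$head))
}

#' Build the heatmap network
#'
#' Instantiates the encoder--decoder described by a [model_config()] with
#' He-initialised weights (head bias initialised to the logit of a 0.1
#' foreground prior, the usual stabiliser for focal-loss heatmap training).
#' Initialisation draws from the current R RNG stream; seed it for
#' reproducible builds.
#'
#' @param config a `cp_model_config`.
#' @return A `cp_network`: list with `config`, `arch`, `params` (named flat
#'   list of weight matrices/vectors), `state` (batch-norm running
#'   moments), `n_params`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "cp_model_config"))
  arch <- cp_make_arch(config)
  params <- list()
  state <- list()
  for (sp in cp_all_specs(arch)) {
    params <- conv_init(sp, params,
                        head_prior = if (sp$name == "head") 0.1 else NULL)
    state <- conv_state_init(sp, state)
  }
  net <- list(config = config, arch = arch, params = params, state = state,
              n_params = sum(vapply(params, length, numeric(1))))
  class(net) <- "cp_network"
  net
}

#' @export
print.cp_network <- function(x, ...) {
  cat(sprintf("<cp_network> %s, input %d, %d classes, %s parameters\n",
              x$config$encoder_preset, x$config$input_size,
              x$config$n_classes, format(x$n_params, big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param net a `cp_network`.
#' @return Total number of trainable scalars, enumerated over all weight
#'   tensors.
#' @export
count_params <- function(net) {
  sum(vapply(net$params, length, numeric(1)))
}

# Full forward pass. X: (n*S*S) x 3 matrix. P, S_ environments (params,
# state). Returns output matrix plus caches for backward.
net_forward <- function(net, X, n, P, S_, train = FALSE) {
  arch <- net$arch
  S <- net$config$input_size
  fm <- list(X = X, h = S, w = S)
  cache <- list(stem = list(), stages = list(), dec = list())
  skipmap <- list()
  for (i in seq_along(arch$stem)) {
    r <- unit_fwd(arch$stem[[i]], fm$X, n, fm$h, fm$w, P, S_, train)
    cache$stem[[i]] <- r$cache
    fm <- r
    if (i == arch$stem_skip_after)
      skipmap[["stem"]] <- list(X = fm$X, h = fm$h, w = fm$w)
  }
  for (s in seq_along(arch$stages)) {
    st <- arch$stages[[s]]
    sc <- list(blocks = list())
    if (!is.null(st$down)) {
      r <- unit_fwd(st$down, fm$X, n, fm$h, fm$w, P, S_, train)
      sc$down <- r$cache
      fm <- r
    }
    for (b in seq_along(st$blocks)) {
      bl <- st$blocks[[b]]
      xin <- fm$X
      r1 <- unit_fwd(bl$c1, xin, n, fm$h, fm$w, P, S_, train)
      r2 <- unit_fwd(bl$c2, r1$X, n, fm$h, fm$w, P, S_, train)
      out <- cp_relu(r2$X + xin)
      sc$blocks[[b]] <- list(c1 = r1$cache, c2 = r2$cache, out = out)
      fm$X <- out
    }
    cache$stages[[s]] <- sc
    skipmap[[paste0("stage", s)]] <- list(X = fm$X, h = fm$h, w = fm$w)
  }
  for (j in seq_along(arch$decoder)) {
    d <- arch$decoder[[j]]
    ps <- pixshuf_fwd(fm$X, n, fm$h, fm$w)
    dc <- list(ps = ps$cache, skip = d$skip)
    Z <- ps$X
    if (!is.na(d$skip)) {
      sk <- skipmap[[d$skip]]
      stopifnot(sk$h == ps$h, sk$w == ps$w)
      dc$n_ps <- ncol(Z)
      Z <- cbind(Z, sk$X)
    }
    r1 <- unit_fwd(d$c1, Z, n, ps$h, ps$w, P, S_, train)
    r2 <- unit_fwd(d$c2, r1$X, n, ps$h, ps$w, P, S_, train)
    dc$c1 <- r1$cache
    dc$c2 <- r2$cache
    cache$dec[[j]] <- dc
    fm <- list(X = r2$X, h = ps$h, w = ps$w)
  }
  r <- unit_fwd(arch$head, fm$X, n, fm$h, fm$w, P, S_, train)
  cache$head <- r$cache
  list(out = r$X, h = r$h, w = r$w, cache = cache, n = n)
}

# Backward pass: dOut is the gradient wrt the network output. Accumulates
# parameter gradients into environment G.
net_backward <- function(net, fwd, dOut, P, G) {
  arch <- net$arch
  n <- fwd$n
  cache <- fwd$cache
  d <- unit_bwd(arch$head, dOut, cache$head, P, G)
  dskip <- list()
  for (j in rev(seq_along(arch$decoder))) {
    dd <- arch$decoder[[j]]
    dc <- cache$dec[[j]]
    d <- unit_bwd(dd$c2, d, dc$c2, P, G)
    d <- unit_bwd(dd$c1, d, dc$c1, P, G)
    if (!is.na(dd$skip)) {
      dps <- d[, seq_len(dc$n_ps), drop = FALSE]
      dsk <- d[, -seq_len(dc$n_ps), drop = FALSE]
      lab <- dd$skip
      dskip[[lab]] <- if (is.null(dskip[[lab]])) dsk else dskip[[lab]] + dsk
    } else {
      dps <- d
    }
    d <- pixshuf_bwd(dps, dc$ps)
  }
  for (s in rev(seq_along(arch$stages))) {
    lab <- paste0("stage", s)
    if (!is.null(dskip[[lab]])) d <- d + dskip[[lab]]
    st <- arch$stages[[s]]
    sc <- cache$stages[[s]]
    for (b in rev(seq_along(st$blocks))) {
      bl <- st$blocks[[b]]
      bc <- sc$blocks[[b]]
      d <- cp_mask_pos(d, bc$out)
      d2 <- unit_bwd(bl$c2, d, bc$c2, P, G)
      d2 <- unit_bwd(bl$c1, d2, bc$c1, P, G)
      d <- d + d2  # residual shortcut
    }
    if (!is.null(st$down)) d <- unit_bwd(st$down, d, sc$down, P, G)
  }
  for (i in rev(seq_along(arch$stem))) {
    if (i == arch$stem_skip_after && !is.null(dskip[["stem"]]))
      d <- d + dskip[["stem"]]
    d <- unit_bwd(arch$stem[[i]], d, cache$stem[[i]], P, G)
  }
  invisible(d)
}

# image batch (list of H x W x 3 arrays in [0,1]) -> (n*S*S) x 3 matrix,
# standardised. Row order must match the heatmap pixel-major layout.
cp_images_to_batch <- function(images, input_size) {
  n <- length(images)
  X <- matrix(0, n * input_size * input_size, 3)
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (!identical(dim(img)[1:2], c(input_size, input_size)))
      img <- resize_block_mean(img, input_size)
    rows <- ((i - 1) * input_size * input_size + 1):
      (i * input_size * input_size)
    for (ch in 1:3) X[rows, ch] <- as.vector(t(img[, , ch]))
  }
  (X - 0.5) / 0.25
}

# (n*S*S) x C output matrix -> list of H x W x C arrays
cp_batch_to_heatmaps <- function(out, n, S, C) {
  lapply(seq_len(n), function(i) {
    rows <- ((i - 1) * S * S + 1):(i * S * S)
    arr <- array(0, c(S, S, C))
    for (ch in seq_len(C)) arr[, , ch] <- matrix(out[rows, ch], S, S,
                                                 byrow = TRUE)
    arr
  })
}

#' Block-mean downscaling of an image
#'
#' Downscales an `H x W x C` (or `H x W`) array by an integer factor using
#' the mean over each block, the appropriate antialiasing resize for the
#' 1024 -> 256 network input reduction.
#'
#' @param img numeric array.
#' @param out_size target side length; must divide the input side exactly.
#' @return The resized array.
#' @export
resize_block_mean <- function(img, out_size) {
  d <- dim(img)
  f <- d[1] / out_size
  if (f != round(f) || d[2] != d[1])
    stop("resize_block_mean: need square image and integer factor")
  f <- as.integer(f)
  if (f == 1L) return(img)
  nc <- if (length(d) == 3) d[3] else 1L
  out <- array(0, c(out_size, out_size, nc))
  for (ch in seq_len(nc)) {
    m <- if (length(d) == 3) img[, , ch] else img
    # average f x f blocks via two matrix contractions
    A <- matrix(0, out_size, d[1])
    for (i in seq_len(f)) A[cbind(seq_len(out_size),
                                  (seq_len(out_size) - 1) * f + i)] <- 1 / f
    out[, , ch] <- A %*% m %*% t(A)
  }
  if (length(d) == 2) out <- out[, , 1]
  out
}
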