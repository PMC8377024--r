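# Low-level differentiable layers.
#
# Feature maps are (N*h*w) x C matrices, pixel-major rows (x fastest, then
# y, then sample), matching the cp_im2col kernel. Convolutions run as
# im2col + BLAS matmul; backward recomputes the patch matrix from the
# cached layer input instead of caching it (memory stays O(activations)).

.cp_bcast <- function(v, nr) rep(v, each = nr)

conv_spec <- function(name, cin, cout, k = 3, stride = 1,
                      bn = TRUE, act = c("relu", "none", "sigmoid"),
                      bias = FALSE) {
  list(name = name, cin = cin, cout = cout, k = k, stride = stride,
       pad = (k - 1L) %/% 2L, bn = bn, act = match.arg(act), bias = bias)
}

conv_init <- function(spec, params, head_prior = NULL) {
  fan_in <- spec$cin * spec$k^2
  std <- if (is.null(head_prior)) sqrt(2 / fan_in) else 0.01
  params[[paste0(spec$name, ".W")]] <-
    matrix(rnorm(fan_in * spec$cout, sd = std), fan_in, spec$cout)
  if (spec$bias) {
    b0 <- if (is.null(head_prior)) 0 else qlogis(head_prior)
    params[[paste0(spec$name, ".b")]] <- rep(b0, spec$cout)
  }
  if (spec$bn) {
    params[[paste0(spec$name, ".gamma")]] <- rep(1, spec$cout)
    params[[paste0(spec$name, ".beta")]] <- rep(0, spec$cout)
  }
  params
}

conv_state_init <- function(spec, state) {
  if (spec$bn) {
    state[[paste0(spec$name, ".rm")]] <- rep(0, spec$cout)
    state[[paste0(spec$name, ".rv")]] <- rep(1, spec$cout)
  }
  state
}

# forward through conv [+ bias] [+ BN] [+ activation]; in training mode the
# patch matrix is cached for reuse in the backward pass.
unit_fwd <- function(spec, X, n, h, w, P, S, train,
                     bn_eps = 1e-5, bn_momentum = 0.1) {
  k <- spec$k; s <- spec$stride; pad <- spec$pad
  patches <- cp_im2col(X, n, h, w, k, s, pad)
  Z <- patches %*% P[[paste0(spec$name, ".W")]]
  ho <- (h + 2L * pad - k) %/% s + 1L
  wo <- (w + 2L * pad - k) %/% s + 1L
  if (spec$bias)
    Z <- cp_col_axpb(Z, rep(1, ncol(Z)), P[[paste0(spec$name, ".b")]])
  cache <- list(n = n, h = h, w = w)
  if (train) cache$patches <- patches
  if (spec$bn) {
    gamma <- P[[paste0(spec$name, ".gamma")]]
    beta <- P[[paste0(spec$name, ".beta")]]
    if (train) {
      mu <- colMeans(Z)
      va <- colMeans(Z * Z) - mu * mu
      va[va < 0] <- 0
      rm_k <- paste0(spec$name, ".rm"); rv_k <- paste0(spec$name, ".rv")
      S[[rm_k]] <- (1 - bn_momentum) * S[[rm_k]] + bn_momentum * mu
      S[[rv_k]] <- (1 - bn_momentum) * S[[rv_k]] + bn_momentum * va
    } else {
      mu <- S[[paste0(spec$name, ".rm")]]
      va <- S[[paste0(spec$name, ".rv")]]
    }
    invstd <- 1 / sqrt(va + bn_eps)
    xhat <- cp_col_axpb(Z, invstd, -mu * invstd)
    Z <- cp_col_axpb(xhat, gamma, beta)
    if (train) cache$xhat <- xhat
    cache$invstd <- invstd
    cache$bn_train <- train
  }
  if (spec$act == "relu") {
    Z <- cp_relu(Z)
    cache$out <- Z
  } else if (spec$act == "sigmoid") {
    Z <- 1 / (1 + exp(-Z))
    cache$out <- Z
  }
  list(X = Z, h = ho, w = wo, cache = cache)
}

# backward; accumulates parameter gradients into environment G and returns
# the gradient wrt the unit input.
unit_bwd <- function(spec, dY, cache, P, G) {
  nr <- nrow(dY)
  if (spec$act == "relu") {
    dY <- cp_mask_pos(dY, cache$out)
  } else if (spec$act == "sigmoid") {
    dY <- dY * cache$out * (1 - cache$out)
  }
  if (spec$bn) {
    gamma <- P[[paste0(spec$name, ".gamma")]]
    xhat <- cache$xhat
    gkey <- paste0(spec$name, ".gamma"); bkey <- paste0(spec$name, ".beta")
    G[[gkey]] <- G[[gkey]] + cp_colsum_prod(dY, xhat)
    G[[bkey]] <- G[[bkey]] + colSums(dY)
    dxhat <- cp_col_axpb(dY, gamma, rep(0, length(gamma)))
    if (isTRUE(cache$bn_train)) {
      m1 <- colSums(dxhat)
      m2 <- cp_colsum_prod(dxhat, xhat)
      t1 <- cp_col_axpb(dxhat, rep(nr, length(m1)), -m1)
      t2 <- cp_col_axpb(xhat, m2, rep(0, length(m2)))
      dY <- cp_col_axpb(t1 - t2, cache$invstd / nr, rep(0, length(m1)))
    } else {
      dY <- cp_col_axpb(dxhat, cache$invstd, rep(0, length(gamma)))
    }
  }
  if (spec$bias) {
    bkey <- paste0(spec$name, ".b")
    G[[bkey]] <- G[[bkey]] + colSums(dY)
  }
  patches <- cache$patches
  wkey <- paste0(spec$name, ".W")
  G[[wkey]] <- G[[wkey]] + crossprod(patches, dY)
  cp_col2im(dY %*% t(P[[wkey]]), cache$n, cache$h, cache$w,
            spec$cin, spec$k, spec$stride, spec$pad)
}

# Sub-pixel (pixel shuffle) x2 upsampling: C channels at h x w become C/4
# channels at 2h x 2w. Output channel c takes input channel 4(c-1)+q+1 at
# sub-position q = 2*dy + dx.
pixshuf_fwd <- function(X, n, h, w) {
  C <- ncol(X)
  stopifnot(C %% 4 == 0)
  Co <- C %/% 4L
  rows <- n * h * w
  i0 <- 0:(rows - 1)
  xx <- i0 %% w
  yy <- (i0 %/% w) %% h
  nn <- i0 %/% (h * w)
  out <- matrix(0, n * 4L * h * w, Co)
  ro <- vector("list", 4)
  for (q in 0:3) {
    dy <- q %/% 2L; dx <- q %% 2L
    ro[[q + 1]] <- (nn * (2L * h) + (2L * yy + dy)) * (2L * w) +
      (2L * xx + dx) + 1
    out[ro[[q + 1]], ] <- X[, 4L * (seq_len(Co) - 1L) + q + 1L]
  }
  list(X = out, h = 2L * h, w = 2L * w, cache = list(ro = ro, C = C))
}

pixshuf_bwd <- function(dY, cache) {
  Co <- ncol(dY)
  dX <- matrix(0, nrow(dY) %/% 4L, cache$C)
  for (q in 0:3) {
    dX[, 4L * (seq_len(Co) - 1L) + q + 1L] <- dY[cache$ro[[q + 1]], ]
  }
  dX
}
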