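#' Penalty-reduced focal loss for centre-point heatmaps
#'
#' Pixel-wise logistic loss over predicted heatmaps `Yhat` against Gaussian
#' targets `Y`:
#' \deqn{L = -\frac{1}{N}\sum_{xyc}
#'   \begin{cases}(1-\hat Y)^\alpha \log \hat Y & Y = 1\\
#'   (1-Y)^\beta \hat Y^\alpha \log(1-\hat Y) & \mathrm{otherwise}\end{cases}}
#' where `N` is the number of centre pixels (`Y == 1`, clamped to at least
#' 1). The focal exponent `alpha` down-weights easy pixels; the
#' `(1 - Y)^beta` factor reduces the penalty on background pixels near a
#' centre (which are Gaussian-weighted rather than 0). `beta = 2`
#' everywhere; `alpha` defaults to 2, the keypoint-detection convention.
#' Predictions are clamped to `[eps, 1 - eps]` before logarithms.
#'
#' @param pred,target numeric arrays of identical shape; `target` as built
#'   by [encode_targets()] (exact 1 at centre pixels).
#' @param alpha focal exponent (>= 0, default 2).
#' @param beta penalty-reduction exponent (default 2, the published
#'   setting).
#' @param eps clamp epsilon for the logarithms.
#' @return `focal_loss`: a non-negative scalar. `focal_loss_grad`: the
#'   gradient `dL/dYhat`, same shape as `pred` (zero outside the clamp
#'   range).
#' @export
focal_loss <- function(pred, target, alpha = 2, beta = 2, eps = 1e-6) {
  if (!identical(dim(pred), dim(target)) ||
      length(pred) != length(target))
    stop("focal_loss: shape mismatch between pred and target")
  p <- pmin(pmax(as.numeric(pred), eps), 1 - eps)
  y <- as.numeric(target)
  pos <- y == 1
  n <- max(1, sum(pos))
  lp <- sum((1 - p[pos])^alpha * log(p[pos]))
  ln <- sum((1 - y[!pos])^beta * p[!pos]^alpha * log(1 - p[!pos]))
  -(lp + ln) / n
}

#' @rdname focal_loss
#' @export
focal_loss_grad <- function(pred, target, alpha = 2, beta = 2, eps = 1e-6) {
  if (!identical(dim(pred), dim(target)) ||
      length(pred) != length(target))
    stop("focal_loss_grad: shape mismatch between pred and target")
  dims <- dim(pred)
  p_raw <- as.numeric(pred)
  inside <- p_raw > eps & p_raw < 1 - eps  # clamp blocks gradient outside
  p <- pmin(pmax(p_raw, eps), 1 - eps)
  y <- as.numeric(target)
  pos <- y == 1
  n <- max(1, sum(pos))
  g <- numeric(length(p))
  if (any(pos)) {
    pp <- p[pos]
    g[pos] <- -(-alpha * (1 - pp)^(alpha - 1) * log(pp) +
                  (1 - pp)^alpha / pp) / n
  }
  if (any(!pos)) {
    pn <- p[!pos]
    g[!pos] <- -((1 - y[!pos])^beta *
                   (alpha * pn^(alpha - 1) * log(1 - pn) -
                      pn^alpha / (1 - pn))) / n
  }
  g[!inside] <- 0
  if (!is.null(dims)) dim(g) <- dims
  g
}
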