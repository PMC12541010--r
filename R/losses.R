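#' Dice loss
#'
#' `1 - 2 * sum(P * G) / (sum(P) + sum(G) + eps)` for a predicted probability
#' grid `P` and binary ground truth `G`. Zero for perfect overlap, one for
#' disjoint nonempty masks.
#'
#' @param P numeric grid of predicted probabilities in `[0, 1]`.
#' @param G binary grid of the same shape.
#' @param eps smoothing constant guarding the empty-empty denominator.
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(P, G, eps = 1e-6) {
  if (!identical(dim(P) %||% length(P), dim(G) %||% length(G))) {
    stop_acunet("P and G shapes differ")
  }
  1 - 2 * sum(P * G) / (sum(P) + sum(G) + eps)
}

#' Binary cross-entropy loss
#'
#' `-sum(G * log(P) + (1 - G) * log(1 - P))`, with `P` clipped into
#' `[eps, 1 - eps]`; divided by the number of pixels when
#' `reduction = "mean"`.
#'
#' @inheritParams dice_loss
#' @param reduction `"sum"` (the printed form) or `"mean"`.
#' @param eps clipping constant.
#' @return scalar loss.
#' @export
cross_entropy_loss <- function(P, G, reduction = c("sum", "mean"), eps = 1e-12) {
  reduction <- match.arg(reduction)
  if (!identical(dim(P) %||% length(P), dim(G) %||% length(G))) {
    stop_acunet("P and G shapes differ")
  }
  Pc <- pmin(pmax(P, eps), 1 - eps)
  l <- -sum(G * log(Pc) + (1 - G) * log(1 - Pc))
  if (reduction == "mean") l / length(P) else l
}

#' Combined weighted Dice + cross-entropy loss
#'
#' `lambda_dice * L_dice + lambda_ce * L_ce`.
#'
#' @inheritParams dice_loss
#' @param weights a [loss_weights()].
#' @param reduction reduction passed to [cross_entropy_loss()].
#' @return scalar loss.
#' @export
combined_loss <- function(P, G, weights = loss_weights(), reduction = "sum") {
  weights$lambda_dice * dice_loss(P, G) +
    weights$lambda_ce * cross_entropy_loss(P, G, reduction = reduction)
}

#' Loss weights
#'
#' @param lambda_dice,lambda_ce nonnegative weights of the Dice and
#'   cross-entropy terms; they may not both be zero.
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_dice = 0.5, lambda_ce = 0.5) {
  if (lambda_dice < 0 || lambda_ce < 0) stop_acunet("loss weights must be >= 0")
  if (lambda_dice == 0 && lambda_ce == 0) {
    stop_acunet("lambda_dice and lambda_ce may not both be zero")
  }
  structure(list(lambda_dice = lambda_dice, lambda_ce = lambda_ce),
            class = "loss_weights")
}

# one-hot encode a BraTS label batch (H, W, N) -> (H, W, K, N)
onehot_labels <- function(masks) {
  d <- dim(masks)
  out <- array(0, c(d[1], d[2], length(CLASS_LABELS), d[3]))
  for (k in seq_along(CLASS_LABELS)) {
    out[, , k, ] <- as.numeric(masks == CLASS_LABELS[k])
  }
  out
}

# Multi-class training objective: mean over classes of the soft Dice loss
# plus the categorical cross-entropy (mean over pixels), weighted. Returns
# the loss and its gradient wrt the softmax probabilities.
training_loss <- function(probs, onehot, weights, eps = 1e-6) {
  K <- dim(probs)[3]
  npix <- prod(dim(probs)[c(1, 2, 4)])
  gP <- array(0, dim(probs))
  dice_total <- 0
  for (k in seq_len(K)) {
    Pk <- probs[, , k, ]
    Gk <- onehot[, , k, ]
    S <- sum(Pk) + sum(Gk) + eps
    I <- sum(Pk * Gk)
    dice_total <- dice_total + (1 - 2 * I / S)
    gP[, , k, ] <- gP[, , k, ] + weights$lambda_dice * (-2) * (Gk * S - I) / S^2 / K
  }
  Pc <- pmin(pmax(probs, 1e-12), 1)
  ce <- -sum(onehot * log(Pc)) / npix
  gP <- gP - weights$lambda_ce * onehot / Pc / npix
  loss <- weights$lambda_dice * dice_total / K + weights$lambda_ce * ce
  list(loss = loss, gP = gP)
}
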