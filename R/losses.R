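# Training objectives as standalone numerics: detection losses
# (Smooth-L1 box regression + Bernoulli class/confidence terms, summed)
# and segmentation losses (pixel-mean BCE + Dice). No gradients, no
# training loops: these are reference implementations for verification.

LOSS_EPS <- 1e-7

clip_prob <- function(p) pmin(pmax(p, LOSS_EPS), 1 - LOSS_EPS)

box_to_vec <- function(b) {
  if (inherits(b, "bounding_box") || (is.list(b) && !is.null(b$x_min))) {
    return(c(b$x_min, b$y_min, b$x_max, b$y_max))
  }
  as.numeric(b)
}

boxes_to_matrix <- function(boxes) {
  if (is.matrix(boxes)) return(boxes)
  do.call(rbind, lapply(boxes, box_to_vec))
}

smooth_l1 <- function(d) {
  a <- abs(d)
  ifelse(a <= 1, 0.5 * d^2, a - 0.5)
}

#' Smooth-L1 bounding-box regression loss
#'
#' Sum over paired boxes of the Smooth-L1 function applied elementwise
#' to the four coordinate differences (quadratic for |d| <= 1, linear
#' beyond).
#'
#' @param predicted,truth Paired boxes: a list of `bounding_box` /
#'   length-4 vectors, or an n x 4 matrix.
#' @return Non-negative scalar.
#' @examples
#' bbox_loss(matrix(c(0, 0, 1, 1.5), 1), matrix(c(0, 0, 1, 1), 1)) # 0.125
#' @export
bbox_loss <- function(predicted, truth) {
  p <- boxes_to_matrix(predicted)
  t_ <- boxes_to_matrix(truth)
  if (is.null(p) || is.null(t_) || !identical(dim(p), dim(t_))) {
    stop("pairing error: predicted and truth boxes must match in number",
         call. = FALSE)
  }
  if (any(!is.finite(p)) || any(!is.finite(t_))) {
    stop("box coordinates must be finite", call. = FALSE)
  }
  sum(smooth_l1(p - t_))
}

bernoulli_nll_sum <- function(y, p, what) {
  y <- as.numeric(y); p <- as.numeric(p)
  if (length(y) != length(p)) {
    stop("pairing error: ", what, " labels and predictions differ in length",
         call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) {
    stop(what, " labels must be binary (0/1)", call. = FALSE)
  }
  p <- clip_prob(p)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Classification loss (summed binary cross-entropy)
#'
#' Negative sum of Bernoulli log-likelihood terms over the paired class
#' labels and predicted probabilities (natural log; probabilities
#' clipped to `[1e-7, 1 - 1e-7]`).
#'
#' @param labels Binary ground-truth labels.
#' @param probs Predicted probabilities in `[0, 1]`.
#' @return Non-negative scalar.
#' @export
cls_loss <- function(labels, probs) bernoulli_nll_sum(labels, probs, "class")

#' Objectness-confidence loss (summed binary cross-entropy)
#'
#' Identical in form to [cls_loss()], applied to object-presence
#' confidences.
#'
#' @param labels Binary ground-truth confidences.
#' @param probs Predicted confidences in `[0, 1]`.
#' @return Non-negative scalar.
#' @export
conf_loss <- function(labels, probs) bernoulli_nll_sum(labels, probs, "confidence")

#' Total detection loss
#'
#' Weighted sum of the box-regression, classification and confidence
#' losses; all weights default to 1.
#'
#' @param bbox,cls,conf The three component losses (scalars).
#' @param lambda_bbox,lambda_cls,lambda_conf Non-negative weights.
#' @return Scalar total loss.
#' @export
det_total_loss <- function(bbox, cls, conf,
                           lambda_bbox = 1, lambda_cls = 1, lambda_conf = 1) {
  w <- c(lambda_bbox, lambda_cls, lambda_conf)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("configuration error: loss weights must be non-negative",
         call. = FALSE)
  }
  lambda_bbox * bbox + lambda_cls * cls + lambda_conf * conf
}

check_seg_inputs <- function(probs, labels) {
  if (length(probs) == 0) stop("empty input: no pixels", call. = FALSE)
  if (length(probs) != length(labels)) {
    stop("pairing error: probability and label grids differ in shape",
         call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be binary (0/1)", call. = FALSE)
  }
}

#' Binary cross-entropy segmentation loss (pixel mean)
#'
#' Mean (not sum) over pixels of the Bernoulli cross-entropy between
#' predicted probabilities and binary labels, probabilities clipped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param probs Predicted per-pixel probabilities (any shape).
#' @param labels Binary ground-truth labels, same shape.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(probs, labels) {
  check_seg_inputs(probs, labels)
  p <- clip_prob(as.numeric(probs))
  y <- as.numeric(labels)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Dice segmentation loss
#'
#' `1 - 2 sum(p y) / (sum(p) + sum(y))`, with a 1e-7 smoothing term in
#' numerator and denominator so the all-empty case is defined as 0.
#'
#' @inheritParams bce_loss
#' @return Scalar in `[0, 1]`.
#' @export
dice_loss <- function(probs, labels) {
  check_seg_inputs(probs, labels)
  p <- as.numeric(probs); y <- as.numeric(labels)
  1 - (2 * sum(p * y) + LOSS_EPS) / (sum(p) + sum(y) + LOSS_EPS)
}

#' Total segmentation loss
#'
#' `bce_loss + lambda * dice_loss`, `lambda` defaulting to 1.
#'
#' @inheritParams bce_loss
#' @param lambda Non-negative Dice weight.
#' @return Scalar total loss.
#' @export
seg_total_loss <- function(probs, labels, lambda = 1) {
  if (!is.finite(lambda) || lambda < 0) {
    stop("configuration error: lambda must be non-negative", call. = FALSE)
  }
  bce_loss(probs, labels) + lambda * dice_loss(probs, labels)
}
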