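#' Focal loss for binary labels
#'
#' For a predicted probability `p` of the positive class, the loss is
#' `-alpha * (1 - p)^gamma * log(p)` when `y = 1` and
#' `-(1 - alpha) * p^gamma * log(1 - p)` when `y = 0`. The modulating
#' factor down-weights well-classified examples; `alpha` balances the
#' positive/negative contributions. Inputs are clamped to
#' `[eps, 1 - eps]` before the logarithm.
#'
#' @param p Numeric vector/matrix of probabilities.
#' @param y Matching 0/1 labels.
#' @param alpha_balance Positive-class balance factor (default 0.25).
#' @param gamma Focusing exponent (default 2; must be >= 0).
#' @param eps Clamping constant for numerical stability.
#' @return Elementwise nonnegative losses, same shape as `p`.
#' @export
focal_loss <- function(p, y, alpha_balance = 0.25, gamma = 2, eps = 1e-7) {
  if (gamma < 0) stop("invalid configuration: gamma must be >= 0", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  pc <- pmin(pmax(p, eps), 1 - eps)
  out <- ifelse(y == 1,
                -alpha_balance * (1 - pc)^gamma * log(pc),
                -(1 - alpha_balance) * pc^gamma * log(1 - pc))
  if (!is.null(dim(p))) dim(out) <- dim(p)
  out
}

# d(focal)/dp, elementwise; used by the training tape.
focal_loss_grad <- function(p, y, alpha_balance = 0.25, gamma = 2, eps = 1e-7) {
  pc <- pmin(pmax(p, eps), 1 - eps)
  mod1 <- if (gamma > 0) gamma * (1 - pc)^(gamma - 1) else 0
  mod0 <- if (gamma > 0) gamma * pc^(gamma - 1) else 0
  g <- ifelse(y == 1,
              -alpha_balance * (-mod1 * log(pc) + (1 - pc)^gamma / pc),
              -(1 - alpha_balance) * (mod0 * log(1 - pc) - pc^gamma / (1 - pc)))
  g[p < eps | p > 1 - eps] <- 0
  if (!is.null(dim(p))) dim(g) <- dim(p)
  g
}

#' Per-class loss weights from previous-round accuracies
#'
#' Weights are proportional to the inverse of each class's accuracy in
#' the previous training round and normalized to sum to one, so classes
#' the model currently classifies poorly receive a larger share of the
#' loss. Accuracies are floored (default 0.05) to keep weights bounded
#' early in training.
#'
#' @param accuracies Length-N vector of per-class accuracies in (0, 1].
#' @param floor Lower bound applied to the accuracies.
#' @param rescale_n Multiply the normalized weights by N so the mean
#'   weight is 1 instead of 1/N?
#' @return An object of class `hrcc_class_weights`: a list with `w`
#'   (the weights) and `accuracy_source` (the floored accuracies).
#' @examples
#' class_weights(c(0.5, 1.0))$w   # 2/3, 1/3
#' @export
class_weights <- function(accuracies, floor = 0.05, rescale_n = FALSE) {
  if (!length(accuracies)) stop("empty accuracy vector", call. = FALSE)
  if (any(accuracies <= 0 | is.na(accuracies))) {
    warning("non-positive or missing accuracies floored to ", floor,
            call. = FALSE)
    accuracies[is.na(accuracies) | accuracies <= 0] <- floor
  }
  a <- pmax(accuracies, floor)
  inv <- 1 / a
  w <- inv / sum(inv)
  if (rescale_n) w <- w * length(w)
  structure(list(w = w, accuracy_source = a), class = "hrcc_class_weights")
}

uniform_weights <- function(n, rescale_n = FALSE) {
  class_weights(rep(1, n), rescale_n = rescale_n)
}

#' Weighted focal loss over a batch
#'
#' Mean over the batch of the class-weighted sum of per-entry focal
#' losses. With uniform weights this equals the plain summed focal loss
#' divided by the number of classes.
#'
#' @param P `(batch, N)` probability matrix.
#' @param Y `(batch, N)` 0/1 label matrix.
#' @param weights An `hrcc_class_weights`, a bare length-N weight
#'   vector, or `NULL` for uniform weights.
#' @inheritParams focal_loss
#' @return A single nonnegative number.
#' @export
weighted_focal_loss <- function(P, Y, weights = NULL, alpha_balance = 0.25,
                                gamma = 2, eps = 1e-7) {
  if (!identical(dim(P), dim(Y))) {
    stop("probability and label matrices must have identical shape",
         call. = FALSE)
  }
  n <- ncol(P)
  w <- if (is.null(weights)) rep(1 / n, n)
       else if (inherits(weights, "hrcc_class_weights")) weights$w
       else weights
  if (length(w) != n) stop("weight length must equal the class count",
                           call. = FALSE)
  fl <- focal_loss(P, Y, alpha_balance, gamma, eps)
  mean(fl %*% w)   # mean over batch of sum_i w_i FL_i
}

#' Epoch-end weight update schedule
#'
#' Returns uniform weights for the first epoch (no previous round
#' exists) and inverse-accuracy weights from [class_weights()]
#' afterwards.
#'
#' @param epoch_metrics Per-class accuracy vector from the last epoch,
#'   or `NULL`/empty on the first epoch.
#' @param n_classes Number of classes (used when metrics are missing).
#' @param ... Passed to [class_weights()].
#' @return An `hrcc_class_weights`.
#' @export
update_weights <- function(epoch_metrics, n_classes, ...) {
  if (is.null(epoch_metrics) || !length(epoch_metrics)) {
    if (!is.null(epoch_metrics)) {
      warning("empty epoch metrics; using uniform weights", call. = FALSE)
    }
    return(uniform_weights(n_classes))
  }
  class_weights(epoch_metrics, ...)
}

#' @export
print.hrcc_class_weights <- function(x, ...) {
  cat("<hrcc_class_weights> n =", length(x$w),
      " sum =", format(sum(x$w)), "\n")
  print(round(x$w, 4))
  invisible(x)
}
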