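#' ROC curve and area under it
#'
#' Builds the ROC by sweeping every distinct score as a threshold
#' (equal scores grouped, so ties produce a single vertex) and
#' integrates with the trapezoid rule. At each vertex the true-positive
#' rate is TP/(TP+FN) and the false-positive rate FP/(FP+TN).
#'
#' @param scores Numeric vector of predicted scores.
#' @param labels 0/1 vector of the same length; both classes must be
#'   present.
#' @param class Optional class name used in error messages.
#' @return An `hrcc_roc`: list with `points` (tibble `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels, class = NULL) {
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    stop("AUC undefined: only one class present",
         if (!is.null(class)) paste0(" for ", class), call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_last <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
  tp <- cumsum(y == 1)[grp_last]
  fp <- cumsum(y == 0)[grp_last]
  tpr <- c(0, tp / np); fpr <- c(0, fp / nn)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(
    points = tibble::tibble(threshold = c(Inf, s[grp_last]),
                            fpr = fpr, tpr = tpr),
    auc = auc), class = "hrcc_roc")
}

#' @export
print.hrcc_roc <- function(x, ...) {
  cat("<hrcc_roc> AUC =", format(x$auc, digits = 4),
      "(", nrow(x$points), "vertices )\n")
  invisible(x)
}

#' Thresholded confusion metrics
#'
#' Counts the per-class contingency table at a fixed decision threshold
#' and reports accuracy `(TP+TN)/(TP+FP+FN+TN)`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(FP+TN)` and F1 `2TP/(2TP+FP+FN)`,
#' plus the macro averages across classes. Metrics with a zero
#' denominator are reported as `NA` and excluded from the macro mean
#' with a warning.
#'
#' @param scores `(n, N)` score matrix (or a vector for one class).
#' @param labels Matching 0/1 matrix/vector.
#' @param threshold Decision threshold in (0, 1).
#' @return A tibble with one row per class (`class`, `tp`, `fp`, `tn`,
#'   `fn`, `accuracy`, `sensitivity`, `specificity`, `f1`); macro
#'   averages are attached as the `"macro"` attribute.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0, 1)", call. = FALSE)
  }
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1)
  if (is.null(dim(labels))) labels <- matrix(labels, ncol = 1)
  if (!all(dim(scores) == dim(labels))) stop("shape mismatch", call. = FALSE)
  cls <- colnames(scores) %||% paste0("class", seq_len(ncol(scores)))
  pred <- scores >= threshold
  rows <- lapply(seq_len(ncol(scores)), function(j) {
    y <- labels[, j]; p <- pred[, j]
    tp <- sum(p & y == 1); fp <- sum(p & y == 0)
    tn <- sum(!p & y == 0); fn <- sum(!p & y == 1)
    div <- function(num, den) if (den == 0) NA_real_ else num / den
    tibble::tibble(class = cls[j], tp = tp, fp = fp, tn = tn, fn = fn,
                   accuracy = div(tp + tn, tp + fp + fn + tn),
                   sensitivity = div(tp, tp + fn),
                   specificity = div(tn, fp + tn),
                   f1 = div(2 * tp, 2 * tp + fp + fn))
  })
  out <- dplyr::bind_rows(rows)
  mac <- colMeans(out[, c("accuracy", "sensitivity", "specificity", "f1")],
                  na.rm = TRUE)
  if (anyNA(out[, c("accuracy", "sensitivity", "specificity", "f1")])) {
    warning("undefined metric(s) excluded from the macro average",
            call. = FALSE)
  }
  attr(out, "macro") <- tibble::as_tibble(as.list(mac))
  attr(out, "threshold") <- threshold
  out
}

#' Full evaluation report
#'
#' Per-class ROC/AUC plus thresholded confusion metrics, macro-averaged
#' across classes.
#'
#' @param P `(n, N)` probability matrix.
#' @param Y `(n, N)` 0/1 label matrix.
#' @param class_names Optional class names.
#' @param threshold Decision threshold for the confusion metrics.
#' @return An `hrcc_metrics_report`: list with `per_class` tibble
#'   (class, auc, accuracy, sensitivity, specificity, f1), `mean_auc`,
#'   `macro` tibble, `threshold`, and the per-class `roc` curves.
#' @export
metrics_report <- function(P, Y, class_names = colnames(Y),
                           threshold = 0.5) {
  if (!all(dim(P) == dim(Y))) stop("shape mismatch", call. = FALSE)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(ncol(P)))
  colnames(P) <- colnames(Y) <- class_names
  rocs <- lapply(seq_len(ncol(P)), function(j) {
    tryCatch(roc_auc(P[, j], Y[, j], class = class_names[j]),
             error = function(e) NULL)
  })
  names(rocs) <- class_names
  aucs <- vapply(rocs, function(r) if (is.null(r)) NA_real_ else r$auc,
                 numeric(1))
  conf <- confusion_metrics(P, Y, threshold)
  per_class <- dplyr::bind_cols(tibble::tibble(class = class_names,
                                               auc = aucs),
                                conf[, c("accuracy", "sensitivity",
                                         "specificity", "f1")])
  structure(list(
    per_class = per_class,
    mean_auc = mean(aucs, na.rm = TRUE),
    macro = attr(conf, "macro"),
    threshold = threshold,
    roc = rocs), class = "hrcc_metrics_report")
}

#' @export
print.hrcc_metrics_report <- function(x, ...) {
  cat("<hrcc_metrics_report> mean AUC =", format(x$mean_auc, digits = 4),
      "at threshold", x$threshold, "\n")
  print(x$per_class, n = Inf)
  invisible(x)
}

#' Activation heatmap
#'
#' Takes the activations of the last (wide 1x1) convolutional layer of
#' the head, computes the absolute value at each position, the maximum
#' along the feature channels, normalizes the resulting map to
#' `[0, 1]` (a constant map degenerates to all zeros) and bilinearly
#' upsamples it to the input resolution. A gradient-weighted variant
#' multiplies the activations by the pooled gradient of the top class
#' score first.
#'
#' @param network An `hrcc_network`.
#' @param image A single `(h, w, 3)` image array (or `(h, w, 3, 1)`).
#' @param layer Activation source: `"head"` (the wide 1x1 head
#'   convolution, spatial side input/32 - the default) or `"stream1"`
#'   (the high-resolution branch output, side input/4, useful when the
#'   input is small and the head map degenerates to a single position).
#' @param gradient_weighted Weight channels by the class-score gradient?
#' @param class_index Class used for the gradient weighting (default:
#'   the highest-probability class).
#' @return An `(h, w)` matrix in `[0, 1]`.
#' @export
activation_heatmap <- function(network, image, layer = c("head", "stream1"),
                               gradient_weighted = FALSE,
                               class_index = NULL) {
  layer <- match.arg(layer)
  if (length(dim(image)) == 3) dim(image) <- c(dim(image), 1L)
  streams <- net_forward_nodes(network, image, training = FALSE)
  out <- net_head_nodes(network, streams, training = FALSE)
  act <- node_value(if (layer == "head") out$feat else streams[[1]])
  if (gradient_weighted) {
    probs <- t(node_value(out$probs))
    j <- class_index %||% which.max(probs[1, ])
    seed <- matrix(0, nrow(node_value(out$logits)), 1)
    seed[j, 1] <- 1
    src <- if (layer == "head") out$feat else streams[[1]]
    src$keep_grad <- TRUE
    params <- network_params(network)
    ad_backward(out$logits, seed = seed)
    zero_grad(params)
    gfeat <- src$gsaved %||% NULL
    # pooled channel weights from the gradient
    if (!is.null(gfeat)) {
      wch <- apply(gfeat, 3, mean)
      act <- sweep(act, 3, wch, `*`)
    }
  }
  m <- apply(abs(act[, , , 1, drop = FALSE]), c(1, 2), max)
  rng <- range(m)
  m <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  bilinear_resize(m, dim(image)[1], dim(image)[2])
}
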