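# Training: Adam on the (weighted) focal loss with per-epoch class
# weight updates from validation accuracy, patience-based early
# stopping, and a tidy per-epoch log.

adam_init <- function(params) {
  for (p in params) {
    p$m <- 0 * p$value
    p$vv <- 0 * p$value
  }
  invisible(params)
}

adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (p in params) {
    g <- p$grad
    if (is.null(g)) next
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$vv <- beta2 * p$vv + (1 - beta2) * g * g
    p$value <- p$value - lr * (p$m / bc1) / (sqrt(p$vv / bc2) + eps)
  }
  invisible(params)
}

# grayscale (H, W, n) stack -> normalized (H, W, 3, n) network input
stack_to_input <- function(images, idx, flip = NULL) {
  x <- images[, , idx, drop = FALSE]
  if (!is.null(flip)) {
    for (k in which(flip)) x[, , k] <- x[, rev(seq_len(dim(x)[2])), k]
  }
  d <- dim(x)
  out <- array(0, c(d[1], d[2], 3, d[3]))
  for (c in 1:3) out[, , c, ] <- x
  (out - 0.5) / 0.25
}

resolve_train_data <- function(data, n = NULL, seed = 1L) {
  if (inherits(data, "hrcc_synthetic_spec")) {
    if (is.null(n)) stop("give n when training from a synthetic spec",
                         call. = FALSE)
    data <- generate_synthetic_dataset(data, n, seed = seed)
  }
  if (inherits(data, "hrcc_synthetic")) {
    return(list(images = data$images, labels = data$labels, source = data))
  }
  if (is.list(data) && !is.null(data$images) && !is.null(data$labels)) {
    return(list(images = data$images, labels = data$labels, source = data))
  }
  stop("unsupported training data; give an hrcc_synthetic, a synthetic spec, ",
       "or list(images=, labels=)", call. = FALSE)
}

#' Train a network
#'
#' Minimises the focal loss (optionally class-reweighted) with Adam at
#' a constant learning rate. The data are split 7:2:1 into training,
#' test and validation parts; after every epoch the validation loss,
#' per-class validation accuracy at threshold 0.5 and validation mean
#' AUC are logged, and - for the weighted loss - the class weights for
#' the next epoch are recomputed from the inverse validation
#' accuracies (the first epoch uses uniform weights). Training stops
#' early when the validation loss has not improved by more than
#' `min_delta` for `patience` consecutive epochs. The best-validation
#' parameters are restored into the returned network. With a fixed
#' seed the whole trajectory is reproducible.
#'
#' @param config An [hrcc_config()] describing the architecture.
#' @param data An `hrcc_synthetic` dataset, an [synthetic_spec()] (with
#'   `n`), or a `list(images = (H, W, n) array, labels = (n, N) matrix)`.
#' @param n Number of images to generate when `data` is a spec.
#' @param epochs Maximum number of epochs (the published cap is 80).
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param loss `"wfl"` (class-weighted) or `"fl"` (plain focal loss).
#' @param alpha_balance,gamma Focal-loss constants.
#' @param weight_metric `"accuracy"` (per-class validation accuracy at
#'   0.5) or `"auc"` as the difficulty signal for the weights.
#' @param rescale_n Rescale class weights so their mean is 1.
#' @param patience,min_delta Early-stopping controls.
#' @param augment Random horizontal flips during training?
#' @param seed Seed controlling splitting, batching, augmentation and
#'   initialization.
#' @param checkpoint Optional path; the best network is saved there.
#' @param verbose Print one line per epoch?
#' @return An `hrcc_fit`: list with the trained `network`, per-epoch
#'   `log` tibble, `weights_history`, `val_accuracy` matrix, split
#'   indices, `best_epoch` and the arguments.
#' @export
train <- function(config, data, n = NULL, epochs = 15L, batch_size = 64L,
                  lr = 0.001, loss = c("wfl", "fl"), alpha_balance = 0.25,
                  gamma = 2, weight_metric = c("accuracy", "auc"),
                  rescale_n = FALSE, patience = 10L, min_delta = 1e-4,
                  augment = TRUE, seed = 1L, checkpoint = NULL,
                  verbose = FALSE) {
  loss <- match.arg(loss)
  weight_metric <- match.arg(weight_metric)
  stopifnot(inherits(config, "hrcc_config"))
  td <- resolve_train_data(data, n, seed = seed)
  n_img <- dim(td$images)[3]
  nc <- ncol(td$labels)
  if (nc != config$num_classes) {
    stop(sprintf(
      "configuration error: config has %d classes but labels have %d",
      config$num_classes, nc), call. = FALSE)
  }
  if (dim(td$images)[1] %% 32 != 0) {
    stop("image side must be a multiple of 32", call. = FALSE)
  }

  set.seed(seed)
  net <- build_network(config)
  params <- network_params(net)
  adam_init(params)

  idx <- sample(n_img)
  n_train <- floor(0.7 * n_img)
  n_test <- floor(0.2 * n_img)
  split <- list(train = idx[seq_len(n_train)],
                test = idx[n_train + seq_len(n_test)],
                val = idx[(n_train + n_test + 1):n_img])
  Yall <- td$labels

  w_cur <- uniform_weights(nc, rescale_n = rescale_n)
  wf <- if (loss == "wfl") NULL else rep(1 / nc, nc)
  log_rows <- list()
  weights_hist <- matrix(NA_real_, 0, nc)
  acc_hist <- matrix(NA_real_, 0, nc)
  best <- list(loss = Inf, epoch = 0L, values = NULL)
  stall <- 0L
  t_adam <- 0L

  eval_split <- function(which) {
    ii <- split[[which]]
    P <- matrix(0, length(ii), nc)
    bs <- max(batch_size, 64L)
    for (s in seq(1, length(ii), by = bs)) {
      jj <- ii[s:min(s + bs - 1, length(ii))]
      P[s:(s + length(jj) - 1), ] <- predict(net, stack_to_input(td$images, jj))
    }
    Y <- Yall[ii, , drop = FALSE]
    lw <- if (loss == "wfl") w_cur$w else wf
    list(P = P, Y = Y,
         loss = weighted_focal_loss(P, Y, lw, alpha_balance, gamma),
         acc = colMeans((P >= 0.5) == (Y == 1)),
         auc = mean(vapply(seq_len(nc), function(j) {
           tryCatch(roc_auc(P[, j], Y[, j])$auc, error = function(e) NA_real_)
         }, numeric(1)), na.rm = TRUE))
  }

  for (epoch in seq_len(epochs)) {
    ord <- sample(split$train)
    ep_loss <- 0; n_batches <- 0L
    for (s in seq(1, length(ord), by = batch_size)) {
      jj <- ord[s:min(s + batch_size - 1, length(ord))]
      flip <- if (augment) runif(length(jj)) < 0.5 else NULL
      xb <- stack_to_input(td$images, jj, flip)
      Yb <- Yall[jj, , drop = FALSE]
      tape_start()
      streams <- net_forward_nodes(net, xb, training = TRUE)
      out <- net_head_nodes(net, streams, training = TRUE)
      nodes <- tape_stop()
      P <- t(node_value(out$probs))
      lw <- if (loss == "wfl") w_cur$w else wf
      lval <- weighted_focal_loss(P, Yb, lw, alpha_balance, gamma)
      gP <- focal_loss_grad(P, Yb, alpha_balance, gamma) *
        rep(lw, each = nrow(P)) / nrow(P)
      zero_grad(params)
      ad_backward_tape(nodes, out$probs, t(gP))
      t_adam <- t_adam + 1L
      adam_step(params, lr, t_adam)
      ep_loss <- ep_loss + lval; n_batches <- n_batches + 1L
    }
    vl <- eval_split("val")
    acc_hist <- rbind(acc_hist, vl$acc)
    weights_hist <- rbind(weights_hist, w_cur$w)
    log_rows[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = ep_loss / n_batches,
      val_loss = vl$loss, val_mean_auc = vl$auc)
    if (verbose) {
      message(sprintf("epoch %2d  train %.5f  val %.5f  val AUC %.3f",
                      epoch, ep_loss / n_batches, vl$loss, vl$auc))
    }
    if (loss == "wfl") {
      difficulty <- if (weight_metric == "accuracy") vl$acc else {
        vapply(seq_len(nc), function(j) {
          tryCatch(roc_auc(vl$P[, j], vl$Y[, j])$auc,
                   error = function(e) NA_real_)
        }, numeric(1))
      }
      w_cur <- update_weights(difficulty, nc, rescale_n = rescale_n)
    }
    if (vl$loss < best$loss - min_delta) {
      best <- list(loss = vl$loss, epoch = epoch,
                   values = lapply(params, function(p) p$value),
                   bn = lapply(network_bn_layers(net), function(b) {
                     list(mean = b$running_mean, var = b$running_var)
                   }))
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }

  if (!is.null(best$values)) {
    for (nm in names(params)) params[[nm]]$value <- best$values[[nm]]
    bns <- network_bn_layers(net)
    for (nm in names(best$bn)) {
      bns[[nm]]$running_mean <- best$bn[[nm]]$mean
      bns[[nm]]$running_var <- best$bn[[nm]]$var
    }
  }
  if (!is.null(checkpoint)) save_checkpoint(net, checkpoint)

  fit <- structure(list(
    network = net, config = config,
    log = dplyr::bind_rows(log_rows),
    weights_history = weights_hist,
    val_accuracy = acc_hist,
    split = split, best_epoch = best$epoch,
    loss = loss, seed = seed,
    data = td$source), class = "hrcc_fit")
  fit
}

#' @export
print.hrcc_fit <- function(x, ...) {
  cat("<hrcc_fit>", x$loss, "loss,", nrow(x$log), "epochs, best epoch",
      x$best_epoch, "\n")
  print(utils::tail(x$log, 3))
  invisible(x)
}

#' Evaluate a trained network
#'
#' Deterministic evaluation-mode pass over a data split followed by a
#' full metrics report.
#'
#' @param fit An `hrcc_fit` (or an `hrcc_network` plus explicit data).
#' @param split One of `"val"`, `"test"`, `"train"` when `fit` carries
#'   its data.
#' @param images,labels Explicit data overriding the stored split.
#' @param threshold Decision threshold.
#' @return An `hrcc_metrics_report`.
#' @export
evaluate <- function(fit, split = "val", images = NULL, labels = NULL,
                     threshold = 0.5) {
  net <- if (inherits(fit, "hrcc_fit")) fit$network else fit
  if (is.null(images)) {
    stopifnot(inherits(fit, "hrcc_fit"))
    src <- fit$data
    ii <- fit$split[[split]]
    images <- src$images[, , ii, drop = FALSE]
    labels <- src$labels[ii, , drop = FALSE]
  }
  if (ncol(labels) != net$config$num_classes) {
    stop("class-count mismatch between network and labels", call. = FALSE)
  }
  nc <- ncol(labels)
  P <- matrix(0, dim(images)[3], nc)
  for (s in seq(1, nrow(P), by = 64)) {
    jj <- s:min(s + 63, nrow(P))
    P[jj, ] <- predict(net, stack_to_input(images, jj))
  }
  metrics_report(P, labels, class_names = colnames(labels),
                 threshold = threshold)
}
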