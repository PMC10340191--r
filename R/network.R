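#' Build a parallel multi-resolution network
#'
#' Instantiates the network described by a configuration: a stem of two
#' stride-2 3x3 convolutions, a stage of residual bottleneck units on
#' the high-resolution branch, three further stages that each add one
#' lower-resolution branch (3x3 stride-2 convolution) and run residual
#' multi-scale blocks per branch, a dense cross-resolution fusion layer
#' after each stage, and a progressive downsample-concatenate head that
#' ends in two linear layers and independent per-class logistic outputs.
#'
#' @param config An [hrcc_config()].
#' @param seed Optional integer; when given, parameter initialization is
#'   reproducible.
#' @return An object of class `hrcc_network`.
#' @examples
#' net <- build_network(hrcc_profile("mini"), seed = 1)
#' p <- predict(net, array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2)))
#' dim(p)
#' @export
build_network <- function(config, seed = NULL) {
  stopifnot(inherits(config, "hrcc_config"))
  if (!is.null(seed)) set.seed(seed)
  w <- config$branch_widths
  net <- new.env(parent = emptyenv())
  net$config <- config

  net$stem <- list(
    conv1 = make_conv(3L, config$stem_width, stride = 2L),
    bn1 = make_bn(config$stem_width),
    conv2 = make_conv(config$stem_width, config$stem_width, stride = 2L),
    bn2 = make_bn(config$stem_width)
  )
  net$stage1 <- lapply(seq_len(config$stage1_blocks), function(i) {
    make_bottleneck(if (i == 1) config$stem_width else w[1], w[1])
  })
  net$transitions <- lapply(2:4, function(s) make_transition(w[s - 1], w[s]))
  net$stages <- lapply(2:4, function(s) {
    dyn_br <- config$dynamic_branches[[s - 1]]
    modules <- lapply(seq_len(config$modules_per_stage[s - 1]), function(m) {
      lapply(seq_len(s), function(b) {
        lapply(seq_len(config$blocks_per_module), function(blk) {
          make_block(w[b],
                     dynamic = config$use_dynamic && b %in% dyn_br,
                     n_experts = config$num_experts,
                     attention = config$use_attention,
                     ca_reduction = config$ca_reduction)
        })
      })
    })
    list(modules = modules, fusion = make_fusion(w, s))
  })
  net$head <- list(
    steps = lapply(1:3, function(k) {
      list(down = make_conv(w[k], w[k + 1], stride = 2L),
           down_bn = make_bn(w[k + 1]),
           fuse = make_conv(2L * w[k + 1], w[k + 1], k = 1L, pad = 0L),
           fuse_bn = make_bn(w[k + 1]))
    }),
    conv = make_conv(w[4], config$head_hidden[1], k = 1L, pad = 0L),
    conv_bn = make_bn(config$head_hidden[1]),
    fc1 = make_linear(config$head_hidden[1], config$head_hidden[2]),
    fc2 = make_linear(config$head_hidden[2], config$num_classes, out_sd = 0.01)
  )
  class(net) <- "hrcc_network"
  net
}

check_images <- function(images, config) {
  d <- dim(images)
  if (length(d) != 4 || d[3] != 3) {
    stop("images must be a (height, width, 3, batch) array", call. = FALSE)
  }
  if (d[1] != d[2]) stop("input images must be square", call. = FALSE)
  if (d[1] %% 32 != 0) {
    stop("input side must be a multiple of 32", call. = FALSE)
  }
  invisible(d)
}

# Full tape forward pass; returns node lists so training can backprop.
net_forward_nodes <- function(net, images, training = FALSE) {
  check_images(images, net$config)
  x <- ad_const(images)
  st <- net$stem
  x <- op_relu(fwd_bn(st$bn1, fwd_conv(st$conv1, x, training), training))
  x <- op_relu(fwd_bn(st$bn2, fwd_conv(st$conv2, x, training), training))
  for (b in net$stage1) x <- fwd_bottleneck(b, x, training)
  streams <- list(x)
  for (s in 2:4) {
    streams[[s]] <- fwd_transition(net$transitions[[s - 1]],
                                   streams[[s - 1]], training)
    stage <- net$stages[[s - 1]]
    for (mod in stage$modules) {
      for (b in seq_along(streams)) {
        for (blk in mod[[b]]) streams[[b]] <- fwd_block(blk, streams[[b]], training)
      }
    }
    streams <- fwd_fusion(stage$fusion, streams, training)
  }
  streams
}

net_head_nodes <- function(net, streams, training = FALSE) {
  hd <- net$head
  rep_node <- streams[[1]]
  for (k in 1:3) {
    s <- hd$steps[[k]]
    rep_node <- op_relu(fwd_bn(s$down_bn, fwd_conv(s$down, rep_node, training),
                               training))
    rep_node <- op_concat_c(list(rep_node, streams[[k + 1]]))
    rep_node <- op_relu(fwd_bn(s$fuse_bn, fwd_conv(s$fuse, rep_node, training),
                               training))
  }
  feat <- op_relu(fwd_bn(hd$conv_bn, fwd_conv(hd$conv, rep_node, training),
                         training))
  pooled <- op_gap(feat)
  h <- op_relu(fwd_linear(hd$fc1, pooled, training))
  logits <- fwd_linear(hd$fc2, h, training)
  list(probs = op_sigmoid(logits), logits = logits, feat = feat)
}

#' Run the backbone and return the feature pyramid
#'
#' Performs a deterministic evaluation-mode pass through stem, stages
#' and per-stage fusion, returning the four parallel feature streams.
#' For an input of side S the streams have sides S/4, S/8, S/16, S/32
#' and the configured branch widths.
#'
#' @param network An `hrcc_network`.
#' @param images A `(height, width, 3, batch)` numeric array.
#' @return An `hrcc_pyramid`: a list of four `(h, w, c, batch)` arrays.
#' @export
forward_features <- function(network, images) {
  streams <- net_forward_nodes(network, images, training = FALSE)
  new_pyramid(lapply(streams, node_value))
}

new_pyramid <- function(streams) {
  structure(streams, class = "hrcc_pyramid")
}

#' @export
print.hrcc_pyramid <- function(x, ...) {
  cat("<hrcc_pyramid>", length(x), "streams:",
      paste(vapply(x, function(s) paste(dim(s)[1:3], collapse = "x"),
                   character(1)), collapse = ", "), "\n")
  invisible(x)
}

#' Cross-resolution fusion of a feature pyramid
#'
#' Applies a dense exchange: every stream receives additive
#' contributions from every other stream after resolution adaptation
#' (repeated stride-2 convolutions downward, stride-2 transposed
#' convolutions upward). Stream shapes are unchanged.
#'
#' @param pyramid An `hrcc_pyramid` with at least 2 streams.
#' @param fusion Optionally a fusion layer to apply (e.g. from a built
#'   network); when `NULL`, a freshly initialized fusion over the
#'   pyramid's widths is created.
#' @return An `hrcc_pyramid` of identical shapes.
#' @export
fuse_branches <- function(pyramid, fusion = NULL) {
  if (length(pyramid) < 2) stop("need at least 2 streams", call. = FALSE)
  widths <- vapply(pyramid, function(s) dim(s)[3], integer(1))
  sides <- vapply(pyramid, function(s) dim(s)[1], integer(1))
  if (any(sides[-1] * 2L != sides[-length(sides)])) {
    stop("stream resolutions must halve from stream to stream", call. = FALSE)
  }
  if (is.null(fusion)) fusion <- make_fusion(widths, length(pyramid))
  nodes <- lapply(pyramid, ad_const)
  out <- fwd_fusion(fusion, nodes, training = FALSE)
  new_pyramid(lapply(out, node_value))
}

#' Classification head on a full feature pyramid
#'
#' Progressively downsamples the running representation, concatenates it
#' with the next stream and fuses with a 1x1 convolution (head widths
#' equal to branch widths 2-4), then applies the wide 1x1 convolution,
#' global average pooling, two linear layers and the per-class logistic.
#'
#' @param network An `hrcc_network`.
#' @param pyramid An `hrcc_pyramid` with all 4 streams.
#' @return A `(batch, num_classes)` probability matrix in (0, 1).
#' @export
classify_head <- function(network, pyramid) {
  if (length(pyramid) != 4) stop("head requires a 4-stream pyramid", call. = FALSE)
  nodes <- lapply(pyramid, ad_const)
  out <- net_head_nodes(network, nodes, training = FALSE)
  t(node_value(out$probs))
}

#' Predict class probabilities
#'
#' @param object An `hrcc_network`.
#' @param images A `(height, width, 3, batch)` array.
#' @param ... Unused.
#' @return A `(batch, num_classes)` matrix of independent per-class
#'   probabilities.
#' @export
predict.hrcc_network <- function(object, images, ...) {
  streams <- net_forward_nodes(object, images, training = FALSE)
  out <- net_head_nodes(object, streams, training = FALSE)
  t(node_value(out$probs))
}

#' @export
print.hrcc_network <- function(x, ...) {
  cat("<hrcc_network>\n")
  print(x$config)
  cat("  parameters:", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

network_params <- function(net) {
  out <- list()
  grab <- function(obj, name) {
    if (inherits(obj, "hrcc_layer")) {
      out <<- c(out, layer_params(obj, paste0(name, ".")))
    } else if (is.list(obj)) {
      for (i in seq_along(obj)) {
        nm <- if (!is.null(names(obj)) && nzchar(names(obj)[i])) names(obj)[i]
              else as.character(i)
        grab(obj[[i]], paste0(name, ".", nm))
      }
    }
  }
  grab(net$stem, "stem")
  grab(net$stage1, "stage1")
  grab(net$transitions, "transition")
  grab(net$stages, "stage")
  grab(net$head, "head")
  out
}

# Named list of BN layers, for checkpointing running statistics.
network_bn_layers <- function(net) {
  out <- list()
  grab <- function(obj, name) {
    if (inherits(obj, "hrcc_layer")) {
      if (obj$kind == "bn") out[[name]] <<- obj
      for (field in ls(obj)) {
        v <- get(field, envir = obj)
        if (inherits(v, "hrcc_layer") || is.list(v)) {
          grab(v, paste0(name, ".", field))
        }
      }
    } else if (is.list(obj)) {
      for (i in seq_along(obj)) {
        nm <- if (!is.null(names(obj)) && nzchar(names(obj)[i])) names(obj)[i]
              else as.character(i)
        grab(obj[[i]], paste0(name, ".", nm))
      }
    }
  }
  grab(net$stem, "stem")
  grab(net$stage1, "stage1")
  grab(net$transitions, "transition")
  grab(net$stages, "stage")
  grab(net$head, "head")
  out
}

#' Save or load a network checkpoint
#'
#' A checkpoint stores the configuration, every trainable parameter and
#' the batch-normalization running statistics. Loading rebuilds the
#' network from the stored configuration and verifies, when `config` is
#' supplied, that it equals the stored one.
#'
#' @param network An `hrcc_network`.
#' @param path File path (RDS format).
#' @export
save_checkpoint <- function(network, path) {
  params <- network_params(network)
  bns <- network_bn_layers(network)
  obj <- list(
    config = network$config,
    params = lapply(params, function(p) p$value),
    bn_stats = lapply(bns, function(b) {
      list(mean = b$running_mean, var = b$running_var)
    })
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @param path Checkpoint path written by `save_checkpoint()`.
#' @param config Optional `hrcc_config` that must match the stored one.
#' @return `load_checkpoint()` returns the restored `hrcc_network`.
#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, config = NULL) {
  obj <- readRDS(path)
  if (!is.null(config) && !identical(unclass(config), unclass(obj$config))) {
    stop("checkpoint was produced by a different configuration", call. = FALSE)
  }
  net <- build_network(obj$config)
  params <- network_params(net)
  if (!setequal(names(params), names(obj$params))) {
    stop("checkpoint parameter names do not match the architecture",
         call. = FALSE)
  }
  for (nm in names(params)) params[[nm]]$value <- obj$params[[nm]]
  bns <- network_bn_layers(net)
  for (nm in names(obj$bn_stats)) {
    bns[[nm]]$running_mean <- obj$bn_stats[[nm]]$mean
    bns[[nm]]$running_var <- obj$bn_stats[[nm]]$var
  }
  net
}
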