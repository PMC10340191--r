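#' Per-sample routing weights for dynamic convolution
#'
#' Routes each sample to a mixture over expert kernels: global average
#' pooling over space, one fully connected layer to `n` outputs, and an
#' elementwise logistic. Every weight is therefore strictly inside
#' (0, 1) and mixtures need not sum to one.
#'
#' @param x A `(height, width, channels, batch)` feature map.
#' @param weights A `(channels, n)` matrix of routing weights.
#' @param bias Length-`n` routing bias.
#' @return A `(batch, n)` matrix of routing weights.
#' @export
routing_weights <- function(x, weights, bias = rep(0, ncol(weights))) {
  d <- dim(x)
  if (length(d) != 4) stop("x must be a 4-axis feature map", call. = FALSE)
  n <- ncol(weights)
  if (n < 1) stop("invalid configuration: need at least one expert", call. = FALSE)
  if (nrow(weights) != d[3]) {
    stop(sprintf("routing expects %d channels, got %d", nrow(weights), d[3]),
         call. = FALSE)
  }
  dim(x) <- c(d[1] * d[2], d[3] * d[4])
  pooled <- matrix(colMeans(x), d[3], d[4])            # (C, batch)
  z <- crossprod(weights, pooled) + bias               # (n, batch)
  t(1 / (1 + exp(-z)))
}

#' Dynamic (conditionally parameterized) convolution
#'
#' Convolves each sample with its own aggregated kernel
#' `sum_i alpha_i W_i`. The activation of the surrounding block is not
#' applied here. By linearity of convolution the result equals the
#' alpha-weighted sum of the per-expert convolutions; the implementation
#' aggregates kernels first so only one convolution is evaluated per
#' sample.
#'
#' @param x A `(height, width, channels, batch)` feature map.
#' @param experts A `(k, k, in_channels, out_channels, n)` expert bank.
#' @param alphas A `(batch, n)` routing-weight matrix.
#' @param stride,pad Convolution geometry.
#' @return The `(h', w', out_channels, batch)` pre-activation output.
#' @export
condconv_forward <- function(x, experts, alphas, stride = 1L, pad = 1L) {
  d <- dim(x)
  if (length(d) != 4) stop("x must be a 4-axis feature map", call. = FALSE)
  ed <- dim(experts)
  if (length(ed) != 5) stop("experts must be a 5-axis array", call. = FALSE)
  if (!is.matrix(alphas) || nrow(alphas) != d[4] || ncol(alphas) != ed[5]) {
    stop(sprintf("alphas must be a (%d x %d) matrix, one row per sample",
                 d[4], ed[5]), call. = FALSE)
  }
  nn_condconv_fwd(x, experts, alphas, stride, pad)
}

#' Residual multi-scale attention block
#'
#' `msa_block()` creates one block at a given width: dynamic (or plain)
#' 3x3 convolution, batch normalization, rectified-linear activation, a
#' second convolution and normalization, coordinate attention, identity
#' skip, final rectified-linear activation. `msa_block_forward()` runs
#' it on an array.
#'
#' @param width Channel width of the block.
#' @param dynamic Use dynamic convolutions?
#' @param n_experts Experts per dynamic convolution.
#' @param attention Apply coordinate attention before the skip?
#' @param ca_reduction Reduction of the attention transform.
#' @return `msa_block()` returns a block object; `msa_block_forward()`
#'   the transformed `(height, width, channels, batch)` array.
#' @export
msa_block <- function(width, dynamic = TRUE, n_experts = 3L,
                      attention = TRUE, ca_reduction = 32L) {
  make_block(width, dynamic = dynamic, n_experts = n_experts,
             attention = attention, ca_reduction = ca_reduction)
}

#' @param block A block created by `msa_block()`.
#' @param x Input feature map whose channel count equals `width`.
#' @param training Use batch statistics (and update running ones)?
#' @rdname msa_block
#' @export
msa_block_forward <- function(block, x, training = FALSE) {
  d <- dim(x)
  if (length(d) != 4 || d[3] != block$width) {
    stop(sprintf("block width %d does not match input channels %s",
                 block$width, paste(d[3], collapse = "")), call. = FALSE)
  }
  node_value(fwd_block(block, ad_const(x), training))
}
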