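#' Directional pooling for coordinate attention
#'
#' Pools a feature map separately along each spatial direction: `z_h`
#' holds per-row means (over width) and `z_w` per-column means (over
#' height), per channel and sample. These one-dimensional summaries
#' retain position along one axis while aggregating the other.
#'
#' @param x A `(height, width, channels, batch)` feature map.
#' @return A list with `z_h` of shape `(height, 1, channels, batch)` and
#'   `z_w` of shape `(1, width, channels, batch)`.
#' @export
directional_pool <- function(x) {
  d <- dim(x)
  if (length(d) != 4 || d[1] < 1 || d[2] < 1) {
    stop("x must be a 4-axis feature map with non-empty spatial axes",
         call. = FALSE)
  }
  list(z_h = node_value(op_pool_rows(ad_const(x))),
       z_w = node_value(op_pool_cols(ad_const(x))))
}

#' Directional attention maps
#'
#' Concatenates the two pooled summaries along the spatial axis, applies
#' the shared 1x1 convolution to the reduced width, batch normalization
#' and hard-swish, splits back into the two directions, restores the
#' channel count with per-direction 1x1 convolutions, and maps to (0, 1)
#' gates with the logistic function.
#'
#' @param summaries A list as returned by [directional_pool()].
#' @param ca A coordinate-attention layer (e.g. `coord_attention(c, r)`).
#' @param training Use batch statistics in the normalization?
#' @return A list with gate maps `g_h` `(height, 1, channels, batch)`
#'   and `g_w` `(1, width, channels, batch)`, all entries in (0, 1).
#' @export
attention_maps <- function(summaries, ca, training = FALSE) {
  zh <- ad_const(summaries$z_h)
  zw <- ad_const(summaries$z_w)
  H <- dim(summaries$z_h)[1]
  W <- dim(summaries$z_w)[2]
  f <- op_concat_h(zh, op_transpose_hw(zw))
  f <- fwd_conv(ca$conv_sq, f, training)
  f <- op_hardswish(fwd_bn(ca$bn, f, training))
  fh <- op_slice_h(f, 1, H)
  fw <- op_slice_h(f, H + 1, H + W)
  list(g_h = node_value(op_sigmoid(fwd_conv(ca$conv_h, fh, training))),
       g_w = node_value(op_transpose_hw(
         op_sigmoid(fwd_conv(ca$conv_w, fw, training)))))
}

#' Create a coordinate-attention layer
#'
#' @param channels Channel count of the maps it will gate.
#' @param reduction Channel reduction of the shared transform; when the
#'   channel count is not divisible, the reduced width is rounded down
#'   (floored at 1) with a warning.
#' @return A coordinate-attention layer usable with [attention_maps()]
#'   and inside blocks.
#' @export
coord_attention <- function(channels, reduction = 32L) {
  if (channels %% reduction != 0) {
    warning(sprintf(
      "channels (%d) not divisible by reduction (%d); using floor width %d",
      channels, reduction, max(1L, channels %/% reduction)), call. = FALSE)
  }
  make_ca(channels, reduction)
}

#' Reweight a feature map with directional gates
#'
#' Elementwise `y(h, w, c) = x(h, w, c) * g_h(h, c) * g_w(w, c)`, the
#' row gate broadcast over width and the column gate over height.
#'
#' @param x A `(height, width, channels, batch)` feature map.
#' @param maps A list with `g_h` and `g_w` as from [attention_maps()].
#' @return The gated feature map, same shape as `x`.
#' @export
reweight <- function(x, maps) {
  d <- dim(x)
  if (dim(maps$g_h)[3] != d[3] || dim(maps$g_w)[3] != d[3]) {
    stop("gate channel count does not match the feature map", call. = FALSE)
  }
  node_value(op_reweight(ad_const(x), ad_const(maps$g_h), ad_const(maps$g_w)))
}
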