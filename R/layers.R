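# Layer constructors and forward passes. A layer is a mutable environment
# holding `hrcc_param` objects plus shape metadata used by the profiler.
# Weight layout follows src/ops.cpp: maps (H, W, C, N), kernels
# (k, k, Cin, Cout); transposed convolutions store the adjoint kernel.

new_layer <- function(.kind, ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- .kind
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("hrcc_layer_", .kind), "hrcc_layer")
  e
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

make_conv <- function(ci, co, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                      bias = FALSE, transposed = FALSE) {
  wdim <- if (transposed) c(k, k, co, ci) else c(k, k, ci, co)
  l <- new_layer("conv", ci = ci, co = co, k = k, stride = stride, pad = pad,
                 transposed = transposed,
                 w = new_param(he_init(wdim, k * k * ci)))
  if (bias) l$b <- new_param(rep(0, co))
  l
}

make_bn <- function(c) {
  new_layer("bn", c = c,
            gamma = new_param(rep(1, c)), beta = new_param(rep(0, c)),
            running_mean = rep(0, c), running_var = rep(1, c))
}

make_linear <- function(ci, co, out_sd = NULL) {
  sd <- if (is.null(out_sd)) sqrt(2 / ci) else out_sd
  new_layer("linear", ci = ci, co = co,
            w = new_param(array(stats::rnorm(ci * co, 0, sd), dim = c(ci, co))),
            b = new_param(rep(0, co)))
}

make_condconv <- function(ci, co, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                          n_experts = 3L) {
  new_layer("condconv", ci = ci, co = co, k = k, stride = stride, pad = pad,
            n_experts = n_experts,
            experts = new_param(he_init(c(k, k, ci, co, n_experts),
                                        k * k * ci)),
            route_w = new_param(array(stats::rnorm(ci * n_experts, 0, 0.01),
                                      dim = c(ci, n_experts))),
            route_b = new_param(rep(0, n_experts)))
}

make_ca <- function(c, reduction) {
  cr <- max(1L, c %/% reduction)
  new_layer("ca", c = c, cr = cr, reduction = reduction,
            conv_sq = make_conv(c, cr, k = 1L, pad = 0L),
            bn = make_bn(cr),
            conv_h = make_conv(cr, c, k = 1L, pad = 0L, bias = TRUE),
            conv_w = make_conv(cr, c, k = 1L, pad = 0L, bias = TRUE))
}

make_block <- function(width, dynamic = FALSE, n_experts = 3L,
                       attention = TRUE, ca_reduction = 32L) {
  mk <- function() {
    if (dynamic) make_condconv(width, width, n_experts = n_experts)
    else make_conv(width, width)
  }
  new_layer("block", width = width, dynamic = dynamic,
            conv1 = mk(), bn1 = make_bn(width),
            conv2 = mk(), bn2 = make_bn(width),
            ca = if (attention) make_ca(width, ca_reduction) else NULL)
}

make_bottleneck <- function(ci, width) {
  mid <- max(4L, width %/% 4L)
  new_layer("bottleneck", ci = ci, width = width, mid = mid,
            conv1 = make_conv(ci, mid, k = 1L, pad = 0L), bn1 = make_bn(mid),
            conv2 = make_conv(mid, mid), bn2 = make_bn(mid),
            conv3 = make_conv(mid, width, k = 1L, pad = 0L), bn3 = make_bn(width),
            proj = if (ci != width) make_conv(ci, width, k = 1L, pad = 0L),
            proj_bn = if (ci != width) make_bn(width))
}

make_transition <- function(ci, co) {
  new_layer("transition", conv = make_conv(ci, co, stride = 2L), bn = make_bn(co))
}

# Dense cross-resolution exchange among `nb` branches. paths[[j]][[k]]
# adapts stream j to stream k's resolution/width, one stride-2 step per
# resolution gap (convolutions downward, transposed convolutions upward).
make_fusion <- function(widths, nb) {
  paths <- vector("list", nb)
  for (j in seq_len(nb)) {
    paths[[j]] <- vector("list", nb)
    for (k in seq_len(nb)) {
      if (j == k) next
      steps <- list()
      if (j < k) {
        for (l in j:(k - 1)) {
          steps[[length(steps) + 1]] <-
            list(conv = make_conv(widths[l], widths[l + 1], stride = 2L),
                 bn = make_bn(widths[l + 1]))
        }
      } else {
        for (l in j:(k + 1)) {
          steps[[length(steps) + 1]] <-
            list(conv = make_conv(widths[l], widths[l - 1], stride = 2L,
                                  transposed = TRUE),
                 bn = make_bn(widths[l - 1]))
        }
      }
      paths[[j]][[k]] <- steps
    }
  }
  new_layer("fusion", widths = widths, nb = nb, paths = paths)
}

# ---- forward passes --------------------------------------------------------

fwd_conv <- function(l, x, training) {
  y <- if (l$transposed) {
    d <- dim(x$v)
    op_convt(x, ad_leaf(l$w), l$stride, l$pad,
             c(d[1] * l$stride, d[2] * l$stride))
  } else {
    op_conv(x, ad_leaf(l$w), l$stride, l$pad)
  }
  if (!is.null(l$b)) y <- op_bias4(y, ad_leaf(l$b)) else y
}

fwd_bn <- function(l, x, training) {
  op_batchnorm(x, ad_leaf(l$gamma), ad_leaf(l$beta), l, training)
}

fwd_linear <- function(l, x, training) op_linear(x, ad_leaf(l$w), ad_leaf(l$b))

fwd_routing <- function(l, x, training) {
  pooled <- op_gap(x)                                 # (C, N)
  z <- op_linear(pooled, ad_leaf(l$route_w), ad_leaf(l$route_b))
  a <- op_sigmoid(z)                                  # (n, N)
  op_tmat(a)                                          # (N, n)
}

op_tmat <- function(x) {
  ad_node(t(x$v), parents = list(x), backward = function(g) list(t(g)))
}

fwd_condconv <- function(l, x, training) {
  alphas <- fwd_routing(l, x, training)
  op_condconv(x, ad_leaf(l$experts), alphas, l$stride, l$pad)
}

fwd_block_conv <- function(l, x, training) {
  if (l$kind == "condconv") fwd_condconv(l, x, training)
  else fwd_conv(l, x, training)
}

fwd_ca <- function(l, x, training) {
  d <- dim(x$v)
  zh <- op_pool_rows(x)                               # (H, 1, C, N)
  zw <- op_transpose_hw(op_pool_cols(x))              # (W, 1, C, N)
  f <- op_concat_h(zh, zw)                            # (H + W, 1, C, N)
  f <- fwd_conv(l$conv_sq, f, training)
  f <- op_hardswish(fwd_bn(l$bn, f, training))
  fh <- op_slice_h(f, 1, d[1])
  fw <- op_slice_h(f, d[1] + 1, d[1] + d[2])
  gh <- op_sigmoid(fwd_conv(l$conv_h, fh, training))  # (H, 1, C, N)
  gw <- op_transpose_hw(op_sigmoid(fwd_conv(l$conv_w, fw, training)))
  op_reweight(x, gh, gw)
}

fwd_block <- function(l, x, training) {
  y <- op_relu(fwd_bn(l$bn1, fwd_block_conv(l$conv1, x, training), training))
  y <- fwd_bn(l$bn2, fwd_block_conv(l$conv2, y, training), training)
  if (!is.null(l$ca)) y <- fwd_ca(l$ca, y, training)
  op_relu(op_add(y, x))
}

fwd_bottleneck <- function(l, x, training) {
  y <- op_relu(fwd_bn(l$bn1, fwd_conv(l$conv1, x, training), training))
  y <- op_relu(fwd_bn(l$bn2, fwd_conv(l$conv2, y, training), training))
  y <- fwd_bn(l$bn3, fwd_conv(l$conv3, y, training), training)
  sc <- if (is.null(l$proj)) x else
    fwd_bn(l$proj_bn, fwd_conv(l$proj, x, training), training)
  op_relu(op_add(y, sc))
}

fwd_transition <- function(l, x, training) {
  op_relu(fwd_bn(l$bn, fwd_conv(l$conv, x, training), training))
}

fwd_fusion_path <- function(steps, x, training) {
  for (i in seq_along(steps)) {
    x <- fwd_bn(steps[[i]]$bn, fwd_conv(steps[[i]]$conv, x, training), training)
    if (i < length(steps)) x <- op_relu(x)
  }
  x
}

# Additive exchange; each output stream is its input plus every adapted
# other stream. No trailing activation, so severed cross paths leave a
# stream bit-identical.
fwd_fusion <- function(l, streams, training) {
  out <- vector("list", l$nb)
  for (k in seq_len(l$nb)) {
    acc <- streams[[k]]
    for (j in seq_len(l$nb)) {
      if (j == k) next
      acc <- op_add(acc, fwd_fusion_path(l$paths[[j]][[k]], streams[[j]], training))
    }
    out[[k]] <- acc
  }
  out
}

# ---- parameter traversal ---------------------------------------------------

layer_params <- function(l, prefix = "") {
  out <- list()
  grab <- function(obj, name) {
    if (inherits(obj, "hrcc_param")) {
      out[[paste0(prefix, name)]] <<- obj
    } else if (inherits(obj, "hrcc_layer")) {
      out <<- c(out, layer_params(obj, paste0(prefix, name, ".")))
    } else if (is.list(obj)) {
      for (i in seq_along(obj)) {
        nm <- if (!is.null(names(obj)) && nzchar(names(obj)[i])) names(obj)[i]
              else as.character(i)
        grab(obj[[i]], paste0(name, ".", nm))
      }
    }
  }
  for (field in setdiff(ls(l), c("kind", "running_mean", "running_var"))) {
    grab(get(field, envir = l), field)
  }
  out
}

n_layer_params <- function(l) {
  sum(vapply(layer_params(l), function(p) length(p$value), numeric(1)))
}
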