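# Minimal reverse-mode tape over coarse-grained array operations.
#
# A node is an environment holding the forward value (`v`), its parents,
# and a backward closure returning one gradient per parent. Trainable
# parameters are free-standing environments (`new_param()`) that
# accumulate gradients across backward passes until `zero_grad()`.

.node_counter <- new.env(parent = emptyenv())
.node_counter$i <- 0L

# Optional tape: when recording, nodes are stored in creation order,
# which is already a topological order, so the training loop can run
# backward without a graph search.
.tape <- new.env(parent = emptyenv())
.tape$on <- FALSE

tape_start <- function() {
  .tape$on <- TRUE
  .tape$nodes <- vector("list", 4096L)
  .tape$n <- 0L
  invisible(NULL)
}

tape_stop <- function() {
  .tape$on <- FALSE
  nodes <- .tape$nodes[seq_len(.tape$n)]
  .tape$nodes <- NULL
  nodes
}

ad_node <- function(value, parents = list(), backward = NULL, param = NULL) {
  e <- new.env(parent = emptyenv())
  .node_counter$i <- .node_counter$i + 1L
  e$id <- .node_counter$i
  e$v <- value
  e$parents <- parents
  e$bw <- backward
  e$param <- param
  class(e) <- "hrcc_node"
  if (.tape$on) {
    n <- .tape$n + 1L
    if (n > length(.tape$nodes)) {
      .tape$nodes <- c(.tape$nodes, vector("list", length(.tape$nodes)))
    }
    .tape$nodes[[n]] <- e
    .tape$n <- n
  }
  e
}

# Backward over an explicit topologically ordered node list (from
# `tape_stop()`); nodes unreachable from the seeded root carry no
# gradient and are skipped.
ad_backward_tape <- function(nodes, root, seed) {
  root$g <- seed
  for (i in rev(seq_along(nodes))) {
    nd <- nodes[[i]]
    g <- nd$g
    if (is.null(g)) next
    if (!is.null(nd$param)) {
      nd$param$grad <- if (is.null(nd$param$grad)) g else nd$param$grad + g
    }
    if (!is.null(nd$bw)) {
      gs <- nd$bw(g)
      ps <- nd$parents
      for (j in seq_along(ps)) {
        p <- ps[[j]]
        if (!inherits(p, "hrcc_node") || is.null(gs[[j]])) next
        p$g <- if (is.null(p$g)) gs[[j]] else p$g + gs[[j]]
      }
    }
    if (isTRUE(nd$keep_grad)) nd$gsaved <- g
    nd$g <- NULL
  }
  invisible(root)
}

#' @noRd
new_param <- function(value, name = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$name <- name
  class(e) <- "hrcc_param"
  e
}

ad_leaf <- function(param) {
  ad_node(param$value, param = param)
}

ad_const <- function(value) ad_node(value)

node_value <- function(x) if (inherits(x, "hrcc_node")) x$v else x

# Reverse-mode sweep from a scalar root. Accumulates into each
# parameter's `grad` field.
ad_backward <- function(root, seed = 1) {
  order <- vector("list", 256L)
  n_ord <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top$node
    key <- as.character(nd$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = nd, stage = 2L)
      for (p in nd$parents) {
        if (inherits(p, "hrcc_node") && is.null(seen[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- nd
    }
  }
  order <- order[seq_len(n_ord)]
  root$g <- seed
  for (i in rev(seq_len(n_ord))) {
    nd <- order[[i]]
    g <- nd$g
    if (is.null(g)) next
    if (!is.null(nd$param)) {
      nd$param$grad <- if (is.null(nd$param$grad)) g else nd$param$grad + g
    }
    if (!is.null(nd$bw)) {
      gs <- nd$bw(g)
      for (j in seq_along(nd$parents)) {
        p <- nd$parents[[j]]
        if (!inherits(p, "hrcc_node") || is.null(gs[[j]])) next
        p$g <- if (is.null(p$g)) gs[[j]] else p$g + gs[[j]]
      }
    }
    if (isTRUE(nd$keep_grad)) nd$gsaved <- g
    nd$g <- NULL
  }
  invisible(root)
}

zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

# ---- array ops -------------------------------------------------------------

op_conv <- function(x, w, stride = 1L, pad = 1L) {
  xv <- x$v; wv <- w$v
  H <- dim(xv)[1]; W <- dim(xv)[2]
  k <- dim(wv)[1]
  y <- nn_conv_fwd(xv, wv, stride, pad)
  ad_node(y, parents = list(x, w), backward = function(g) {
    list(nn_conv_bwd_data(g, wv, stride, pad, H, W),
         nn_conv_bwd_weight(xv, g, k, stride, pad))
  })
}

# Transposed convolution as the adjoint of a strided convolution; the
# weight is stored in the adjoint convolution's (k, k, Cout, Cin) layout.
# `out_hw` fixes the output size (stride-2 output padding is implied).
op_convt <- function(x, w, stride, pad, out_hw) {
  xv <- x$v; wv <- w$v
  k <- dim(wv)[1]
  y <- nn_conv_bwd_data(xv, wv, stride, pad, out_hw[1], out_hw[2])
  ad_node(y, parents = list(x, w), backward = function(g) {
    list(nn_conv_fwd(g, wv, stride, pad),
         nn_conv_bwd_weight(g, xv, k, stride, pad))
  })
}

op_condconv <- function(x, experts, alphas, stride = 1L, pad = 1L) {
  xv <- x$v; ev <- experts$v; av <- alphas$v
  y <- nn_condconv_fwd(xv, ev, av, stride, pad)
  ad_node(y, parents = list(x, experts, alphas), backward = function(g) {
    gr <- nn_condconv_bwd(xv, ev, av, g, stride, pad)
    list(gr$dx, gr$dexperts, gr$dalphas)
  })
}

op_bias4 <- function(x, b) {
  # b: length-C vector added per channel of a (H, W, C, N) map
  d <- dim(x$v)
  y <- x$v + rep(rep(b$v, each = d[1] * d[2]), times = d[4])
  ad_node(y, parents = list(x, b), backward = function(g) {
    gs <- g
    dim(gs) <- c(d[1] * d[2], d[3], d[4])
    list(g, rowSums(colSums(gs)))
  })
}

op_relu <- function(x) {
  keep <- x$v > 0
  ad_node(x$v * keep, parents = list(x),
          backward = function(g) list(g * keep))
}

op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$v))
  ad_node(s, parents = list(x), backward = function(g) list(g * s * (1 - s)))
}

op_hardswish <- function(x) {
  # x * relu6(x + 3) / 6
  v <- x$v
  r6 <- pmin(pmax(v + 3, 0), 6)
  ad_node(v * r6 / 6, parents = list(x), backward = function(g) {
    d <- r6 / 6 + v * ((v > -3 & v < 3) / 6)
    list(g * d)
  })
}

op_add <- function(x, y) {
  ad_node(x$v + y$v, parents = list(x, y), backward = function(g) list(g, g))
}

op_scale <- function(x, s) {
  ad_node(x$v * s, parents = list(x), backward = function(g) list(g * s))
}

# Per-channel vector expanded over one (H*W, C) tile; arithmetic with a
# full (HW, C, N) array then recycles it exactly over the batch axis.
ch_rep <- function(v, hw, n) rep(v, each = hw)

# per-channel mean over axes 1 and 3 of an (HW, C, N) array
colMeans2_ <- function(a) rowMeans(colMeans(a))

op_batchnorm <- function(x, gamma, beta, layer, training, eps = 1e-5,
                         momentum = 0.1) {
  d <- dim(x$v)
  C <- d[3]
  hw <- d[1] * d[2]
  xm <- x$v
  dim(xm) <- c(hw, C, d[4])
  if (training) {
    mu <- colMeans2_(xm)
    ctr <- xm - ch_rep(mu, hw, d[4])
    var_b <- colMeans2_(ctr * ctr)
    m <- hw * d[4]
    layer$running_mean <- (1 - momentum) * layer$running_mean + momentum * mu
    layer$running_var <- (1 - momentum) * layer$running_var +
      momentum * var_b * m / max(1, m - 1)
    inv <- 1 / sqrt(var_b + eps)
    xhat <- ctr * ch_rep(inv, hw, d[4])
    y <- xhat * ch_rep(gamma$v, hw, d[4]) + ch_rep(beta$v, hw, d[4])
    dim(y) <- d
    ad_node(y, parents = list(x, gamma, beta), backward = function(g) {
      dim(g) <- c(hw, C, d[4])
      dbeta <- rowSums(colSums(g))
      gx <- g * xhat
      dgamma <- rowSums(colSums(gx))
      gh <- g * ch_rep(gamma$v, hw, d[4])
      dx <- (gh - ch_rep(colMeans2_(gh), hw, d[4]) -
               xhat * ch_rep(colMeans2_(gh * xhat), hw, d[4])) *
        ch_rep(inv, hw, d[4])
      dim(dx) <- d
      list(dx, dgamma, dbeta)
    })
  } else {
    inv <- 1 / sqrt(layer$running_var + eps)
    scl <- gamma$v * inv
    shift <- beta$v - layer$running_mean * scl
    y <- xm * ch_rep(scl, hw, d[4]) + ch_rep(shift, hw, d[4])
    dim(y) <- d
    ad_node(y, parents = list(x, gamma, beta), backward = function(g) {
      dim(g) <- c(hw, C, d[4])
      dbeta <- rowSums(colSums(g))
      xhat <- (xm - ch_rep(layer$running_mean, hw, d[4])) * ch_rep(inv, hw, d[4])
      dgamma <- rowSums(colSums(g * xhat))
      dx <- g * ch_rep(scl, hw, d[4])
      dim(dx) <- d
      list(dx, dgamma, dbeta)
    })
  }
}

op_gap <- function(x) {
  d <- dim(x$v)
  xm <- x$v
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  y <- matrix(colMeans(xm), d[3], d[4])
  ad_node(y, parents = list(x), backward = function(g) {
    dx <- rep(g, each = d[1] * d[2]) / (d[1] * d[2])
    dim(dx) <- d
    list(dx)
  })
}

op_linear <- function(x, w, b) {
  # x: (F, N) feature matrix; w: (F, O); b: length O
  y <- crossprod(w$v, x$v) + b$v
  ad_node(y, parents = list(x, w, b), backward = function(g) {
    list(w$v %*% g, x$v %*% t(g), rowSums(g))
  })
}

op_concat_c <- function(xs) {
  ds <- lapply(xs, function(x) dim(x$v))
  cs <- vapply(ds, `[`, integer(1), 3)
  y <- array(0, c(ds[[1]][1], ds[[1]][2], sum(cs), ds[[1]][4]))
  off <- 0L
  for (i in seq_along(xs)) {
    y[, , off + seq_len(cs[i]), ] <- xs[[i]]$v
    off <- off + cs[i]
  }
  ad_node(y, parents = xs, backward = function(g) {
    out <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- g[, , off + seq_len(cs[i]), , drop = FALSE]
      off <- off + cs[i]
    }
    out
  })
}

op_concat_h <- function(x1, x2) {
  d1 <- dim(x1$v); d2 <- dim(x2$v)
  y <- array(0, c(d1[1] + d2[1], d1[2], d1[3], d1[4]))
  y[seq_len(d1[1]), , , ] <- x1$v
  y[d1[1] + seq_len(d2[1]), , , ] <- x2$v
  ad_node(y, parents = list(x1, x2), backward = function(g) {
    list(g[seq_len(d1[1]), , , , drop = FALSE],
         g[d1[1] + seq_len(d2[1]), , , , drop = FALSE])
  })
}

op_slice_h <- function(x, from, to) {
  d <- dim(x$v)
  idx <- from:to
  ad_node(x$v[idx, , , , drop = FALSE], parents = list(x), backward = function(g) {
    dx <- array(0, d)
    dx[idx, , , ] <- g
    list(dx)
  })
}

op_transpose_hw <- function(x) {
  ad_node(aperm(x$v, c(2, 1, 3, 4)), parents = list(x),
          backward = function(g) list(aperm(g, c(2, 1, 3, 4))))
}

op_pool_rows <- function(x) {
  # per-row mean over width: (H, W, C, N) -> (H, 1, C, N)
  d <- dim(x$v)
  m <- aperm(x$v, c(1, 3, 4, 2))
  dim(m) <- c(d[1] * d[3] * d[4], d[2])
  y <- array(rowMeans(m), dim = c(d[1], 1, d[3], d[4]))
  ad_node(y, parents = list(x), backward = function(g) {
    list(x_expand_w(g / d[2], d[2]))
  })
}

op_pool_cols <- function(x) {
  # per-column mean over height: (H, W, C, N) -> (1, W, C, N)
  d <- dim(x$v)
  m <- x$v
  dim(m) <- c(d[1], d[2] * d[3] * d[4])
  y <- array(colMeans(m), dim = c(1, d[2], d[3], d[4]))
  ad_node(y, parents = list(x), backward = function(g) {
    list(x_expand_h(g / d[1], d[1]))
  })
}

op_reweight <- function(x, gh, gw) {
  # y(h, w, c, n) = x * gh(h, 1, c, n) * gw(1, w, c, n)
  d <- dim(x$v)
  ghf <- x_expand_w(gh$v, d[2])
  gwf <- x_expand_h(gw$v, d[1])
  y <- x$v * ghf * gwf
  ad_node(y, parents = list(x, gh, gw), backward = function(g) {
    gx <- g * x$v
    dgh <- gx * gwf
    dgw <- gx * ghf
    m <- aperm(dgh, c(1, 3, 4, 2))
    dim(m) <- c(d[1] * d[3] * d[4], d[2])
    dgh_s <- array(rowSums(m), dim = dim(gh$v))
    dim(dgw) <- c(d[1], d[2] * d[3] * d[4])
    dgw_s <- array(colSums(dgw), dim = dim(gw$v))
    list(g * ghf * gwf, dgh_s, dgw_s)
  })
}

x_expand_w <- function(a, W) a[, rep(1, W), , , drop = FALSE]
x_expand_h <- function(a, H) a[rep(1, H), , , , drop = FALSE]
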