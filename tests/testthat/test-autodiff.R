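# Finite-difference checks of the reverse-mode core on small arrays.

num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

grad_of <- function(build, x0) {
  # build(x_node) must return a node; seeding with ones makes the test
  # functional sum(out^2)'s gradient land on the retained input node
  xn <- hrccnet:::ad_const(x0)
  xn$keep_grad <- TRUE
  out <- build(xn)
  seed <- if (is.null(dim(out$v))) 1 else array(1, dim(out$v))
  hrccnet:::ad_backward(out, seed = seed)
  xn$gsaved
}

test_that("convolution and transposed convolution gradients are exact", {
  set.seed(1)
  x <- rand_map(5, 5, 2, 2)
  w <- hrccnet:::new_param(array(rnorm(9 * 2 * 3, 0, 0.5), c(3, 3, 2, 3)))
  f <- function(xa) sum(hrccnet:::nn_conv_fwd(xa, w$value, 2L, 1L)^2)
  gx <- grad_of(function(xn) {
    y <- hrccnet:::op_conv(xn, hrccnet:::ad_leaf(w), 2L, 1L)
    hrccnet:::ad_node(y$v^2, list(y), function(g) list(2 * g * y$v))
  }, x)
  expect_equal(gx, num_grad(f, x), tolerance = 1e-6)

  wt <- hrccnet:::new_param(array(rnorm(9 * 3 * 2, 0, 0.5), c(3, 3, 2, 3)))
  ft <- function(xa) {
    sum(hrccnet:::nn_conv_bwd_data(xa, wt$value, 2L, 1L, 10L, 10L)^2)
  }
  x2 <- rand_map(5, 5, 3, 1)
  expect_equal(grad_of(function(xn) {
    y <- hrccnet:::op_convt(xn, hrccnet:::ad_leaf(wt), 2L, 1L, c(10L, 10L))
    hrccnet:::ad_node(y$v^2, list(y), function(g) list(2 * g * y$v))
  }, x2), num_grad(ft, x2), tolerance = 1e-6)
})

test_that("dynamic-convolution gradients agree with finite differences", {
  set.seed(2)
  x <- rand_map(4, 4, 2, 3)
  experts <- hrccnet:::new_param(array(rnorm(9 * 2 * 2 * 3, 0, 0.5),
                                       c(3, 3, 2, 2, 3)))
  alphas0 <- matrix(runif(9), 3, 3)
  # gradient w.r.t. the input
  f <- function(xa) {
    sum(hrccnet:::nn_condconv_fwd(xa, experts$value, alphas0, 1L, 1L)^2)
  }
  gx <- grad_of(function(xn) {
    a <- hrccnet:::ad_const(alphas0)
    y <- hrccnet:::op_condconv(xn, hrccnet:::ad_leaf(experts), a, 1L, 1L)
    hrccnet:::ad_node(y$v^2, list(y), function(g) list(2 * g * y$v))
  }, x)
  expect_equal(gx, num_grad(f, x), tolerance = 1e-6)
  # gradient w.r.t. the routing weights
  fa <- function(av) {
    sum(hrccnet:::nn_condconv_fwd(x, experts$value, av, 1L, 1L)^2)
  }
  ga <- grad_of(function(an) {
    y <- hrccnet:::op_condconv(hrccnet:::ad_const(x),
                               hrccnet:::ad_leaf(experts), an, 1L, 1L)
    hrccnet:::ad_node(y$v^2, list(y), function(g) list(2 * g * y$v))
  }, alphas0)
  expect_equal(ga, num_grad(fa, alphas0), tolerance = 1e-6)
  # gradient w.r.t. the expert bank
  hrccnet:::zero_grad(list(experts))
  yn <- hrccnet:::op_condconv(hrccnet:::ad_const(x),
                              hrccnet:::ad_leaf(experts),
                              hrccnet:::ad_const(alphas0), 1L, 1L)
  sq <- hrccnet:::ad_node(yn$v^2, list(yn), function(g) list(2 * g * yn$v))
  hrccnet:::ad_backward(sq, seed = array(1, dim(sq$v)))
  fe <- function(ev) sum(hrccnet:::nn_condconv_fwd(x, ev, alphas0, 1L, 1L)^2)
  expect_equal(experts$grad, num_grad(fe, experts$value), tolerance = 1e-5)
})

test_that("batch normalization gradients are exact in both modes", {
  set.seed(3)
  x <- rand_map(3, 3, 4, 5)
  # a fixed random projection keeps the test functional well-conditioned
  # (the normalized squares alone are nearly invariant in x)
  R <- rand_map(3, 3, 4, 5)
  for (training in c(TRUE, FALSE)) {
    bn <- hrccnet:::make_bn(4L)
    bn$gamma$value <- runif(4, 0.5, 1.5)
    bn$beta$value <- rnorm(4)
    bn$running_mean <- rnorm(4, 0, 0.1)
    bn$running_var <- runif(4, 0.5, 1.5)
    rm0 <- bn$running_mean; rv0 <- bn$running_var
    f <- function(xa) {
      bn$running_mean <- rm0; bn$running_var <- rv0
      y <- hrccnet:::op_batchnorm(hrccnet:::ad_const(xa),
                                  hrccnet:::ad_leaf(bn$gamma),
                                  hrccnet:::ad_leaf(bn$beta), bn, training)
      sum(y$v * R)
    }
    gx <- grad_of(function(xn) {
      bn$running_mean <- rm0; bn$running_var <- rv0
      y <- hrccnet:::op_batchnorm(xn, hrccnet:::ad_leaf(bn$gamma),
                                  hrccnet:::ad_leaf(bn$beta), bn, training)
      hrccnet:::ad_node(sum(y$v * R), list(y), function(g) list(g * R))
    }, x)
    expect_equal(gx, num_grad(f, x), tolerance = 1e-6,
                 label = paste("bn training =", training))
  }
})

test_that("coordinate-attention composite gradient matches finite differences", {
  set.seed(4)
  ca <- hrccnet:::make_ca(4L, 2L)
  x <- rand_map(4, 5, 4, 2)
  f <- function(xa) {
    y <- hrccnet:::fwd_ca(ca, hrccnet:::ad_const(xa), FALSE)
    sum(y$v^2)
  }
  gx <- grad_of(function(xn) {
    y <- hrccnet:::fwd_ca(ca, xn, FALSE)
    hrccnet:::ad_node(y$v^2, list(y), function(g) list(2 * g * y$v))
  }, x)
  expect_equal(gx, num_grad(f, x), tolerance = 1e-5)
})

test_that("tape-ordered backward equals the graph-search backward", {
  set.seed(5)
  net <- build_network(mini_config(num_classes = 3L), seed = 6)
  x <- array(rnorm(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  Y <- matrix(rbinom(12, 1, 0.5), 4, 3)
  params <- hrccnet:::network_params(net)
  run <- function(use_tape) {
    hrccnet:::zero_grad(params)
    if (use_tape) hrccnet:::tape_start()
    streams <- hrccnet:::net_forward_nodes(net, x, training = FALSE)
    out <- hrccnet:::net_head_nodes(net, streams, training = FALSE)
    nodes <- if (use_tape) hrccnet:::tape_stop()
    P <- t(hrccnet:::node_value(out$probs))
    g <- t(hrccnet:::focal_loss_grad(P, Y))
    if (use_tape) hrccnet:::ad_backward_tape(nodes, out$probs, g)
    else hrccnet:::ad_backward(out$probs, seed = g)
    lapply(params, function(p) p$grad)
  }
  expect_equal(run(TRUE), run(FALSE), tolerance = 1e-14)
})
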