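test_that("configuration validation names the offending field", {
  expect_error(hrcc_config(branch_widths = c(48, 96, 191, 384)),
               "branch_widths")
  expect_error(hrcc_config(modules_per_stage = c(4, 4)), "modules_per_stage")
  expect_error(hrcc_config(num_classes = 0), "num_classes")
  expect_error(hrcc_config(input_size = 100), "input_size")
  expect_error(hrcc_config(dynamic_branches = list(1, 1:4, 1:4)),
               "dynamic_branches")
  # the literal published profile keeps its printed widths and schedule
  t1 <- hrcc_profile("table1")
  expect_identical(t1$branch_widths, c(48L, 96L, 192L, 384L))
  expect_identical(t1$modules_per_stage, c(4L, 4L, 4L))
  expect_identical(t1$blocks_per_module, 4L)
})

test_that("configuration files round-trip through YAML and JSON", {
  cfg <- hrcc_profile("mini", num_classes = 6L)
  fy <- withr::local_tempfile(fileext = ".yaml")
  fj <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, fy)
  write_config(cfg, fj)
  expect_equal(unclass(read_config(fy)), unclass(cfg))
  expect_equal(unclass(read_config(fj)), unclass(cfg))
  # a profile name plus overrides
  f2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(profile = "mini", num_classes = 6), f2)
  expect_equal(read_config(f2)$num_classes, 6L)
})

test_that("the resolution and channel ladders hold for 224 and 256 inputs", {
  net <- build_network(mini_config(), seed = 1)
  for (S in c(224L, 256L)) {
    x <- array(rnorm(S * S * 3), c(S, S, 3, 1))
    pyr <- forward_features(net, x)
    sides <- vapply(pyr, function(s) dim(s)[1], integer(1))
    chans <- vapply(pyr, function(s) dim(s)[3], integer(1))
    expect_identical(sides, as.integer(S / 4 / c(1, 2, 4, 8)))
    expect_identical(chans, net$config$branch_widths)
    expect_identical(sides, vapply(pyr, function(s) dim(s)[2], integer(1)))
  }
})

test_that("forward passes are deterministic and per-sample independent", {
  net <- build_network(mini_config(num_classes = 5L), seed = 2)
  set.seed(3)
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  x[, , , 2] <- x[, , , 1]                     # identical pair
  pyr <- forward_features(net, x)
  for (s in pyr) expect_identical(s[, , , 1], s[, , , 2])
  p1 <- predict(net, x)
  p2 <- predict(net, x)
  expect_identical(p1, p2)                     # evaluation-mode determinism
  expect_identical(p1[1, ], p1[2, ])
  expect_identical(dim(p1), c(2L, 5L))
  expect_true(all(p1 > 0 & p1 < 1))
  expect_error(predict(net, array(0, c(32, 32, 1, 2))), "3")
  expect_error(predict(net, array(0, c(32, 48, 3, 2))), "square")
})

test_that("classification head meets its widths and degenerate output", {
  cfg <- mini_config()
  net <- build_network(cfg, seed = 4)
  # progressive head fuses to the widths of branches 2-4
  for (k in 1:3) {
    expect_equal(net$head$steps[[k]]$fuse$co, cfg$branch_widths[k + 1])
    expect_equal(net$head$steps[[k]]$fuse$ci, 2L * cfg$branch_widths[k + 1])
  }
  # (with the published widths that is 96/192/384)
  expect_identical(hrcc_profile("table1")$branch_widths[2:4] ,
                   c(96L, 192L, 384L))
  # zeroed final linear layer -> every probability exactly 0.5
  fill_params(net$head$fc2, 0)
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  expect_equal(as.vector(predict(net, x)), rep(0.5, 2 * cfg$num_classes))
  pyr <- forward_features(net, x)
  expect_equal(as.vector(classify_head(net, pyr)),
               rep(0.5, 2 * cfg$num_classes))
  expect_error(classify_head(net, pyr[1:3]), "4-stream")
})

test_that("cross-resolution fusion keeps shapes and severs cleanly", {
  set.seed(5)
  streams <- list(rand_map(8, 8, 4, 2), rand_map(4, 4, 8, 2),
                  rand_map(2, 2, 16, 2), rand_map(1, 1, 32, 2))
  pyr <- hrccnet:::new_pyramid(streams)
  fusion <- hrccnet:::make_fusion(c(4L, 8L, 16L, 32L), 4L)
  out <- fuse_branches(pyr, fusion)
  for (k in 1:4) expect_identical(dim(out[[k]]), dim(pyr[[k]]))
  # deterministic: fusing the same input twice is bit-identical
  out2 <- fuse_branches(pyr, fusion)
  expect_identical(out, out2)
  # exchange paths are live: outputs differ from inputs
  expect_gt(max(abs(out[[1]] - pyr[[1]])), 1e-6)
  # path-ablation oracle: zero every path feeding stream 1 -> no-op there
  for (j in 2:4) {
    for (step in fusion$paths[[j]][[1]]) {
      fill_params(step$conv, 0)
      fill_params(step$bn, 0)
    }
  }
  out3 <- fuse_branches(pyr, fusion)
  expect_equal(out3[[1]], pyr[[1]], tolerance = 0)
  expect_gt(max(abs(out3[[2]] - pyr[[2]])), 1e-6)   # other streams still fused

  # two-stream pyramid in, two-stream out with unchanged shapes
  p2 <- hrccnet:::new_pyramid(streams[1:2])
  o2 <- fuse_branches(p2)
  expect_identical(lapply(o2, dim), lapply(p2, dim))
  expect_error(fuse_branches(hrccnet:::new_pyramid(list(streams[[1]]))),
               "2 streams")
  bad <- hrccnet:::new_pyramid(list(rand_map(8, 8, 4, 1), rand_map(3, 3, 8, 1)))
  expect_error(fuse_branches(bad), "halve")
})

test_that("every trainable array receives gradient from one synthetic batch", {
  net <- build_network(mini_config(num_classes = 4L), seed = 6)
  set.seed(7)
  x <- array(rnorm(32 * 32 * 3 * 8), c(32, 32, 3, 8))
  Y <- matrix(rbinom(8 * 4, 1, 0.5), 8, 4)
  params <- hrccnet:::network_params(net)
  hrccnet:::zero_grad(params)
  hrccnet:::tape_start()
  streams <- hrccnet:::net_forward_nodes(net, x, training = TRUE)
  out <- hrccnet:::net_head_nodes(net, streams, training = TRUE)
  nodes <- hrccnet:::tape_stop()
  P <- t(hrccnet:::node_value(out$probs))
  g <- hrccnet:::focal_loss_grad(P, Y)
  hrccnet:::ad_backward_tape(nodes, out$probs, t(g))
  norms <- vapply(params, function(p) {
    if (is.null(p$grad)) 0 else sum(abs(p$grad))
  }, numeric(1))
  expect_true(all(norms > 0))                 # no dead branches
})

test_that("checkpoints round-trip parameters, statistics and config", {
  net <- build_network(mini_config(num_classes = 3L), seed = 8)
  set.seed(9)
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  p0 <- predict(net, x)
  ck <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, ck)
  net2 <- load_checkpoint(ck)
  expect_identical(predict(net2, x), p0)
  expect_equal(unclass(net2$config), unclass(net$config))
  # loading against a different configuration is refused
  expect_error(load_checkpoint(ck, config = mini_config(num_classes = 5L)),
               "different configuration")
})
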