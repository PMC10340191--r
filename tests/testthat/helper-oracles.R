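# Independent oracles used across the suite.

# Plain-loop 2-D convolution (stride/pad), NCHW-free reference:
# x (H, W, Cin, N), w (k, k, Cin, Cout).
conv_oracle <- function(x, w, stride = 1L, pad = 1L) {
  d <- dim(x); kd <- dim(w)
  k <- kd[1]
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1L
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1L
  y <- array(0, c(Ho, Wo, kd[4], d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(kd[4])) {
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- 0
      for (ci in seq_len(d[3])) for (ki in seq_len(k)) for (kj in seq_len(k)) {
        h <- (ho - 1) * stride - pad + ki
        wdx <- (wo - 1) * stride - pad + kj
        if (h >= 1 && h <= d[1] && wdx >= 1 && wdx <= d[2]) {
          acc <- acc + x[h, wdx, ci, n] * w[ki, kj, ci, co]
        }
      }
      y[ho, wo, co, n] <- acc
    }
  }
  y
}

# Pairwise Mann-Whitney statistic: P(score_pos > score_neg) + 0.5 ties.
auc_mann_whitney <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

rand_map <- function(H, W, C, N, sd = 1) {
  array(rnorm(H * W * C * N, 0, sd), c(H, W, C, N))
}

# Set every trainable parameter of a layer (recursively) to a constant.
fill_params <- function(layer, value = 0) {
  for (p in hrccnet:::layer_params(layer)) {
    p$value <- p$value * 0 + value
  }
  invisible(layer)
}

mini_config <- function(...) hrcc_profile("mini", ...)
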