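test_that("ROC/AUC covers perfect, uninformative and tied rankings", {
  r1 <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r1$auc, 1.0)
  r0 <- roc_auc(rep(0.4, 10), rep(c(0, 1), 5))
  expect_equal(r0$auc, 0.5)
  expect_error(roc_auc(runif(5), rep(1, 5), class = "Edema"), "Edema")
})

test_that("AUC equals the pairwise Mann-Whitney statistic", {
  set.seed(1)
  for (rep in 1:5) {
    scores <- round(runif(200), 2)   # rounding forces ties
    labels <- rbinom(200, 1, 0.4)
    expect_lt(abs(roc_auc(scores, labels)$auc -
                    auc_mann_whitney(scores, labels)), 1e-10)
  }
})

test_that("AUC is invariant under monotone transforms and complements", {
  set.seed(2)
  scores <- rnorm(150)
  labels <- rbinom(150, 1, 0.5)
  a <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a, tolerance = 1e-12)
  expect_equal(roc_auc(qlogis(plogis(scores)), labels)$auc, a,
               tolerance = 1e-9)
  expect_equal(roc_auc(-scores, labels)$auc + a, 1, tolerance = 1e-12)
})

test_that("AUC agrees with an established implementation", {
  set.seed(3)
  scores <- round(runif(300), 2)
  labels <- rbinom(300, 1, 0.3)
  ours <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("confusion metrics reproduce the contingency arithmetic", {
  # TP=8, FN=2, TN=5, FP=5 at threshold 0.5
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.9, 5), rep(0.1, 5))
  labels <- c(rep(1, 10), rep(0, 10))
  m <- confusion_metrics(scores, labels)
  expect_equal(m$tp, 8); expect_equal(m$fn, 2)
  expect_equal(m$tn, 5); expect_equal(m$fp, 5)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$accuracy, 0.65)
  expect_equal(m$f1, 16 / 23, tolerance = 1e-12)
  # perfect predictions
  mp <- confusion_metrics(c(0.9, 0.9, 0.1), c(1, 1, 0))
  expect_equal(unlist(mp[, c("accuracy", "sensitivity", "specificity", "f1")]),
               rep(1, 4), ignore_attr = TRUE)
  expect_error(confusion_metrics(scores, labels, threshold = 1.5), "threshold")
})

test_that("multi-class confusion metrics match a counting oracle", {
  set.seed(4)
  P <- matrix(runif(40 * 14), 40, 14)
  Y <- matrix(rbinom(40 * 14, 1, 0.3), 40, 14)
  m <- confusion_metrics(P, Y, threshold = 0.5)
  for (j in sample(14, 5)) {
    tp <- fp <- tn <- fn <- 0
    for (i in 1:40) {
      pred <- P[i, j] >= 0.5
      if (pred && Y[i, j] == 1) tp <- tp + 1
      if (pred && Y[i, j] == 0) fp <- fp + 1
      if (!pred && Y[i, j] == 0) tn <- tn + 1
      if (!pred && Y[i, j] == 1) fn <- fn + 1
    }
    expect_equal(unlist(m[j, c("tp", "fp", "tn", "fn")]),
                 c(tp = tp, fp = fp, tn = tn, fn = fn))
  }
})

test_that("degenerate denominators become NA and warn in the macro mean", {
  # no negatives for the class -> specificity undefined
  expect_warning(m <- confusion_metrics(c(0.9, 0.8), c(1, 1)), "undefined")
  expect_true(is.na(m$specificity))
  expect_false(is.na(attr(m, "macro")$sensitivity))
})

test_that("sensitivity equals TPR and 1 - specificity equals FPR at vertices", {
  set.seed(5)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.5)
  r <- roc_auc(scores, labels)
  pts <- r$points[is.finite(r$points$threshold), ]
  for (k in sample(nrow(pts), 5)) {
    # predictions positive at score >= threshold reproduce the vertex
    thr <- pts$threshold[k]
    tp <- sum(scores >= thr & labels == 1)
    fp <- sum(scores >= thr & labels == 0)
    expect_equal(tp / sum(labels == 1), pts$tpr[k], tolerance = 1e-12)
    expect_equal(fp / sum(labels == 0), pts$fpr[k], tolerance = 1e-12)
  }
})

test_that("metrics report aggregates per-class results", {
  set.seed(6)
  P <- matrix(runif(60 * 3), 60, 3)
  Y <- matrix(rbinom(60 * 3, 1, 0.4), 60, 3)
  colnames(Y) <- c("A", "B", "C")
  rep <- metrics_report(P, Y)
  expect_equal(rep$mean_auc, mean(rep$per_class$auc), tolerance = 1e-12)
  expect_identical(rep$per_class$class, c("A", "B", "C"))
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(nrow(glance(rep)), 1L)
})

test_that("activation heatmaps are normalized, sized and degenerate-safe", {
  set.seed(7)
  net <- build_network(mini_config(), seed = 1)
  img <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  hm <- activation_heatmap(net, img, layer = "stream1")
  expect_identical(dim(hm), c(32L, 32L))
  expect_true(all(hm >= 0 & hm <= 1))
  expect_true(any(hm > 0))
  # zeroed head convolution -> constant activations -> all-zero map
  net0 <- build_network(mini_config(), seed = 1)
  fill_params(net0$head$conv, 0)
  fill_params(net0$head$conv_bn, 0)
  hm0 <- activation_heatmap(net0, img, layer = "head")
  expect_equal(max(abs(hm0)), 0)
  # gradient-weighted variant stays a valid map
  hmg <- activation_heatmap(net, img, layer = "stream1",
                            gradient_weighted = TRUE)
  expect_true(all(hmg >= 0 & hmg <= 1))
})
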