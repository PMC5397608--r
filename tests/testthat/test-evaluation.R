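test_that("labels follow the strict gap rule with overrides", {
  df <- data.frame(antibody = c("a", "b", "c", "d"),
                   gap = c(18.9, 0.5, 5.0, NA))
  labelled <- label_records(df, forced = c(d = 1L))
  expect_equal(labelled$label, c(1L, 0L, 0L, 1L))
  expect_error(label_records(df), "no gap")
  expect_error(label_records(df, forced = c(zz = 1L)), "unknown")
  # gap derived from melting and onset temperatures
  df2 <- data.frame(antibody = "x", t_m = 70, t_agg = 55)
  expect_equal(label_records(df2)$gap, 15)
  expect_equal(label_records(df2)$label, 1L)
})

test_that("ROC endpoints behave on separable toy cases", {
  r <- roc_curve(c(2, 3, 1), c(1, 1, 0))
  expect_equal(r$auc, 1)
  expect_equal(max(r$points$tpr - r$points$fpr), 1)
  expect_equal(roc_curve(c(1, 2), c(1, 0))$auc, 0)
  expect_error(roc_curve(c(1, 2), c(1, 1)), "positive.*negative")
})

test_that("pair-counting AUC equals the brute-force count", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(6:25, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(1:8, n, replace = TRUE)     # plenty of ties
    expect_equal(roc_curve(scores, labels)$auc,
                 auc_bruteforce(scores, labels))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(32)
  for (rep in 1:20) {
    labels <- c(0, 1, sample(0:1, 18, replace = TRUE))
    scores <- stats::rnorm(20)
    ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                                 direction = "<")))
    expect_equal(roc_curve(scores, labels)$auc, ref)
  }
})

test_that("MCC matches hand arithmetic and its symmetries", {
  expect_equal(mcc(c(1, 2, 9, 10), c(0, 0, 1, 1), 5), 1)
  # TP=3, FN=1, TN=5, FP=0
  scores <- c(10, 10, 10, 1, 0, 0, 0, 0, 0)
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0, 0)
  expect_equal(mcc(scores, labels, 5), 15 / sqrt(360))
  # everything predicted positive: degenerate table scores 0
  expect_equal(mcc(scores, labels, -1), 0)
  # simultaneous flip of labels and predictions leaves MCC unchanged
  set.seed(33)
  for (rep in 1:20) {
    s <- stats::rnorm(12)
    l <- c(0, 1, sample(0:1, 10, replace = TRUE))
    m1 <- mcc(s, l, 0)
    m2 <- mcc(-s, 1 - l, -0 + 1e-12)
    expect_equal(m1, m2, tolerance = 1e-9)
    expect_gte(m1, -1); expect_lte(m1, 1)
  }
  expect_error(mcc(1:3, c(1, 1, 1), 2), "both classes")
})

test_that("Pearson correlation is exact on affine relations", {
  x <- c(1, 4, 9, 2)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  set.seed(34)
  y <- stats::rnorm(4)
  expect_equal(pearson(x, y), pearson(10 * x + 3, y))
  expect_error(pearson(c(1, 1, 1), y[1:3]), "variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("the published wild-type panel separates perfectly", {
  b <- mab_benchmark(include_mutants = FALSE)
  expect_equal(nrow(b), 9L)
  pos <- b$solubis_score[b$label == 1]
  neg <- b$solubis_score[b$label == 0]
  expect_equal(min(pos), 93)
  expect_equal(max(neg), 71)
  expect_equal(roc_curve(b$solubis_score, b$label)$auc, 1)
  # any threshold in (71, 93] classifies without error
  for (thr in c(72, 80, 93)) {
    expect_equal(mcc(b$solubis_score, b$label, thr), 1)
    pred <- as.integer(b$solubis_score >= thr)
    expect_equal(sum(pred == 1 & b$label == 0), 0L)  # no false positives
    expect_equal(sum(pred == 0 & b$label == 1), 0L)  # no false negatives
  }
})

test_that("score versus thermal gap reproduces the published correlation", {
  b <- mab_benchmark(include_mutants = FALSE)
  keep <- !is.na(b$gap)
  r <- pearson(b$solubis_score[keep], b$gap[keep])
  expect_equal(round(r, 2), 0.89)
  # robust to how the sub-degree gaps are encoded
  for (enc in c(0, 0.9)) {
    g <- b$gap; g[g == 0.5] <- enc
    expect_gte(round(pearson(b$solubis_score[keep], g[keep]), 2), 0.88)
  }
})
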