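test_that("AUC endpoints: perfect separation gives 1, constant scores 0.5", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.4), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(1, 0), 5))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.5, 0.7, 0.4), c(1, 1, 0, 0))$auc, 0.75)
})

test_that("rank-based AUC equals brute-force pairwise AUC, ties included", {
  set.seed(21)
  for (k in 1:25) {
    n <- sample(10:500, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(roc_auc(scores, labels)$auc,
                 brute_force_auc(scores, labels))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  scores <- c(rnorm(80, 1), rnorm(120))
  labels <- rep(c(1, 0), c(80, 120))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels)$auc, ref)
})

test_that("the ROC curve is a valid monotone path from (0,0) to (1,1)", {
  set.seed(23)
  scores <- round(runif(300), 2)
  labels <- rbinom(300, 1, 0.3)
  r <- roc_auc(scores, labels)
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$thresholds) <= 0))
  # trapezoidal area under the threshold-sweep curve equals the rank AUC
  trap <- sum(diff(r$fpr) * (r$tpr[-1] + r$tpr[-length(r$tpr)]) / 2)
  expect_equal(trap, r$auc)
})

test_that("reversing the labels maps AUC to its complement", {
  set.seed(24)
  scores <- runif(200)
  labels <- rbinom(200, 1, 0.5)
  expect_equal(roc_auc(scores, labels)$auc,
               1 - roc_auc(scores, 1 - labels)$auc)
})

test_that("a single-class input is rejected", {
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
  expect_error(roc_auc(runif(5), rep(0, 5)), "both classes")
  expect_error(roc_auc(runif(5), c(1, 0, 1)), "equal length")
})

test_that("the cumulative curve is the ECDF", {
  cc <- cumulative_curve(c(0.2, 0.4, 0.6, 0.8))
  expect_equal(cc$score[min(which(cc$fraction >= 0.5))], 0.4)
  expect_equal(cc$fraction[nrow(cc)], 1)
  expect_true(all(diff(cc$fraction) >= 0))
  cc2 <- cumulative_curve(rep(0.3, 5))
  expect_true(all(cc2$score == 0.3))
})

test_that("quantile cutoffs interpolate order statistics", {
  expect_equal(unname(quantile_cutoffs(1:5, 0.5)), 3)
  expect_equal(unname(quantile_cutoffs(7, c(0.25, 0.5, 0.75))),
               rep(7, 3))
  q <- quantile_cutoffs(runif(100))
  expect_true(all(diff(q) >= 0))
})

test_that("the optimal cutoff maximizes Youden's J", {
  # perfectly separated classes reach J = 1
  r <- optimal_cutoff(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$J, 1)
  expect_true(r$threshold > 0.2 && r$threshold <= 0.8)
  expect_match(r$note, "discouraged")

  # hand case, checked against an exhaustive scan
  scores <- c(0.9, 0.5, 0.7, 0.4); labels <- c(1, 1, 0, 0)
  r2 <- optimal_cutoff(scores, labels)
  scan <- vapply(sort(unique(scores)), function(t) {
    pred <- scores >= t
    sum(pred & labels == 1) / 2 - sum(pred & labels == 0) / 2
  }, numeric(1))
  expect_equal(r2$J, max(scan))

  # scores independent of labels: J stays near zero
  set.seed(25)
  js <- replicate(40, {
    s <- runif(1000); l <- rbinom(1000, 1, 0.5)
    optimal_cutoff(s, l)$J
  })
  expect_lt(max(js), 0.15)
  expect_error(optimal_cutoff(runif(5), rep(1, 5)), "both classes")
})
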