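test_that("Cronbach's alpha matches a covariance-identity oracle", {
  # independent route: alpha = k/(k-1) * (1 - tr(C) / sum(C)), C = cov matrix
  x <- matrix(c(1, 0, 1, 0,
                1, 1, 0, 0,
                1, 0, 1, 1), 4, 3)
  C <- cov(x)
  oracle <- ncol(x) / (ncol(x) - 1) * (1 - sum(diag(C)) / sum(C))
  res <- cronbach_alpha(x)
  expect_equal(res$alpha, oracle, tolerance = 1e-12)
  expect_equal(res$n_items, 3)
  expect_identical(res$reliable, oracle > 0.7)
})

test_that("perfectly parallel items give alpha = 1", {
  v <- c(1, 0, 1, 1, 0)
  x <- cbind(v, v, v, v)
  expect_equal(cronbach_alpha(x)$alpha, 1, tolerance = 1e-12)
})

test_that("alpha on 2 items equals its closed form", {
  set.seed(41)
  for (i in 1:10) {
    x <- matrix(rbinom(40, 1, 0.5), 20, 2)
    if (sd(rowSums(x)) == 0 || any(apply(x, 2, sd) == 0)) next
    closed <- 2 * (1 - (var(x[, 1]) + var(x[, 2])) / var(rowSums(x)))
    expect_equal(cronbach_alpha(x)$alpha, closed, tolerance = 1e-12)
  }
})

test_that("alpha is undefined for degenerate input", {
  expect_error(cronbach_alpha(matrix(1, 5, 3)), "zero variance")
  expect_error(cronbach_alpha(matrix(0:1, 4, 1)), "at least 2 items")
})

test_that("point-biserial correlations match a direct Pearson computation", {
  set.seed(7)
  score <- rnorm(80, 70, 15)
  hi <- as.integer(score > median(score))     # strongly aligned item
  noise <- rbinom(80, 1, 0.5)
  x <- cbind(hi = hi, noise = noise)
  res <- point_biserial_all(x, score)
  expect_equal(res$r_pb[1], cor(hi, score), tolerance = 1e-12)
  expect_equal(res$strength[1], "high")
  expect_lt(res$p_value[1], 1e-6)
  expect_equal(res$r_pb[2], cor(noise, score), tolerance = 1e-12)
})

test_that("strength bands are half-open with inclusive lower bounds", {
  expect_equal(correlation_strength(c(0, 0.19, 0.2, 0.49, 0.5, 1)),
               c("weak", "weak", "medium", "medium", "high", "high"))
  expect_equal(correlation_strength(-0.3), "medium")  # bands on |r|
})

test_that("constant items are flagged undefined, not dropped", {
  x <- cbind(ok = c(0, 1, 0, 1), flat = c(1, 1, 1, 1))
  res <- point_biserial_all(x, c(10, 20, 15, 25))
  expect_equal(nrow(res), 2)
  expect_true(res$undefined[res$item_id == "flat"])
  expect_equal(res$strength[res$item_id == "flat"], "undefined")
})

test_that("Pearson correlation handles affine and degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_with_ci(x, 2 * x + 3)$r, 1)
  expect_equal(pearson_with_ci(x, -x)$r, -1)
  expect_error(pearson_with_ci(x, rep(1, 5)), "constant")
  expect_error(pearson_with_ci(1:3, 1:3), "at least 4")
})

test_that("the Fisher-z interval matches its closed form at n = 158", {
  set.seed(99)
  # bivariate normal with rho = 0.9 at the development-cohort size
  n <- 158
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- z1
  y <- 0.9 * z1 + sqrt(1 - 0.81) * z2
  res <- pearson_with_ci(x, y)
  closed <- tanh(atanh(res$r) + c(-1.96, 1.96) / sqrt(n - 3))
  expect_equal(res$ci95, closed, tolerance = 1e-12)
  # at rho = 0.9 the interval is about as wide as the published 0.87-0.93
  expect_lt(diff(res$ci95), 0.10)
  expect_gt(diff(res$ci95), 0.03)
  expect_lt(res$p_value, 0.001)
})

test_that("the packaged level pairs reproduce the published confusion matrix", {
  lv <- dev_cohort_levels()
  cm <- confusion_levels(lv$true, lv$predicted)
  expect_equal(unclass(cm),
               matrix(c(28, 2, 0, 11, 26, 14, 0, 5, 72), 3,
                      dimnames = list(true = fhl_levels(),
                                      predicted = fhl_levels())),
               ignore_attr = "class")
  expect_equal(sum(cm), 158)
})

test_that("confusion matrices validate their level labels", {
  expect_error(confusion_levels(c("inadequate", "great"), c("marginal", "marginal")),
               "unknown true level: 'great'")
  expect_error(confusion_levels("marginal", c("marginal", "adequate")),
               "equal length")
  cm <- confusion_levels(rep("adequate", 4), rep("adequate", 4))
  expect_equal(unname(diag(unclass(cm))), c(0L, 0L, 4L))
})

test_that("one-vs-rest accuracies reproduce the published 92/80/88", {
  lv <- dev_cohort_levels()
  cm <- confusion_levels(lv$true, lv$predicted)
  expect_equal(one_vs_rest_accuracy(cm, "inadequate"), 92L)  # 145/158
  expect_equal(one_vs_rest_accuracy(cm, "marginal"), 80L)    # 126/158
  expect_equal(one_vs_rest_accuracy(cm, "adequate"), 88L)    # 139/158
})

test_that("ordinal error counts reproduce the published 126/32/0 split", {
  lv <- dev_cohort_levels()
  cm <- confusion_levels(lv$true, lv$predicted)
  expect_equal(off_by_k(cm), c("0" = 126L, "1" = 32L, "2" = 0L))
})

test_that("off-by-k is structurally consistent on arbitrary matrices", {
  cm1 <- confusion_levels(rep(fhl_levels(), c(3, 2, 4)),
                          rep(fhl_levels(), c(3, 2, 4)))
  expect_equal(off_by_k(cm1), c("0" = 9L, "1" = 0L, "2" = 0L))

  set.seed(5)
  for (i in 1:10) {
    tt <- sample(fhl_levels(), 30, replace = TRUE)
    pp <- sample(fhl_levels(), 30, replace = TRUE)
    cm <- confusion_levels(tt, pp)
    ks <- off_by_k(cm)
    expect_equal(sum(ks), sum(cm))
    # corners are the off-by-two cells
    expect_equal(unname(ks["2"]), cm[1, 3] + cm[3, 1])
    # one-vs-rest error counts at the extremes cover each corner twice
    err <- function(lv) sum(cm) - round(one_vs_rest_accuracy(cm, lv) / 100 * sum(cm))
    expect_gte(err("inadequate") + err("adequate") + 1,  # rounding slack
               2 * unname(ks["2"]))
  }
})
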