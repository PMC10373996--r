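test_that("integer-trimmed least squares recovers an exact integer model", {
  X <- binary_design(30, 2)
  y <- 23 + 7 * X[, 1] + 2 * X[, 2]
  fit <- fit_integer_mlr(X, y)
  expect_equal(fit$trimmed_intercept, 23L)
  expect_equal(unname(fit$trimmed_coefficients), c(7L, 2L))
  expect_equal(fit$trimmed_rmse, 0)
  expect_false(fit$rank_deficient)
})

test_that("a constant response gives zero weights and a rounded mean intercept", {
  X <- binary_design(20, 2)
  y <- rep(41.3, 20)
  fit <- fit_integer_mlr(X, y)
  expect_equal(unname(fit$trimmed_coefficients), c(0L, 0L))
  expect_equal(fit$trimmed_intercept, 41L)
})

test_that("trimming recovers integers from sub-half coefficient noise", {
  X <- binary_design(40, 3)
  # float generating coefficients within 0.5 of integers; the exact float
  # fit recovers them, so round-half-away must restore the integers
  beta <- c(23.3, 6.8, 2.4, -1.3)
  y <- beta[1] + as.numeric(X %*% beta[-1])
  fit <- fit_integer_mlr(X, y)
  expect_equal(fit$coefficients, c(x1 = 6.8, x2 = 2.4, x3 = -1.3),
               tolerance = 1e-8)
  expect_equal(fit$trimmed_intercept, 23L)
  expect_equal(unname(fit$trimmed_coefficients), c(7L, 2L, -1L))
})

test_that("rank-deficient designs are solved with a flagged pseudo-inverse", {
  X <- cbind(binary_design(20, 2), x3 = 1)  # constant column
  y <- 5 + X[, 1]
  fit <- fit_integer_mlr(X, y)
  expect_true(fit$rank_deficient)
  expect_length(fit$trimmed_coefficients, 3)
  expect_true(all(is.finite(fit$coefficients)))
  expect_error(fit_integer_mlr(X[1:3, ], y[1:3]), "more participants")
})

test_that("LOOCV is perfect on a noiseless integer-generated response", {
  X <- binary_design(25, 2)
  y <- 10 + 4 * X[, 1] + 3 * X[, 2]
  cv <- loocv_evaluate(X, y)
  expect_equal(cv$pearson_r, 1, tolerance = 1e-12)
  expect_equal(cv$rmse, 0)
  expect_equal(cv$trimmed_intercept, 10L)
  expect_equal(unname(cv$trimmed_coefficients), c(4L, 3L))
})

test_that("LOOCV correlation is near zero when y is independent of X", {
  set.seed(303)
  X <- matrix(rbinom(60 * 3, 1, 0.5), 60, dimnames = list(NULL, paste0("x", 1:3)))
  y <- rnorm(60, 50, 10)
  cv <- loocv_evaluate(X, y)
  expect_lt(abs(cv$pearson_r), 0.4)
})

test_that("minimal LOOCV produces one pooled prediction per fold", {
  X <- matrix(c(0, 1, 1), 3, 1, dimnames = list(NULL, "x1"))
  y <- c(1, 2, 3)
  cv <- loocv_evaluate(X, y)
  expect_length(cv$predictions, 3)
  expect_true(is.na(cv$pearson_r))  # n < 4: CI and r are not reported
})

test_that("LOOCV agrees with an independently coded lm() route", {
  co <- recovery_cohort(seed = 5, n = 60)
  X <- co$responses[, unlist(co$sets[c("s2", "s3")])]
  cv <- loocv_evaluate(X, co$full)
  oracle <- oracle_loocv(X, co$full)
  expect_equal(unname(cv$predictions), oracle$predictions, tolerance = 1e-8)
  expect_equal(cv$rmse, oracle$rmse, tolerance = 1e-8)
  expect_equal(cv$pearson_r, oracle$r, tolerance = 1e-8)
})

test_that("combination enumeration matches a power-set oracle", {
  sets <- list(s1 = "a", s2 = "b", s3 = c("c", "d"))
  combos <- enumerate_combinations(sets, 2)
  expect_equal(combos, list(c("s1", "s2"), "s3"))
  expect_equal(enumerate_combinations(sets, 0), list())
  expect_equal(enumerate_combinations(sets, 99), list())

  # larger instance: compare counts with a naive power-set filter
  sizes <- c(1, 1, 2, 2, 3, 3, 4, 5, 1, 2, 6, 4)
  big <- setNames(lapply(seq_along(sizes), function(i) {
    paste0("i", i, "_", seq_len(sizes[i]))
  }), sprintf("t%02d", seq_along(sizes)))
  naive_count <- function(target) {
    ids <- names(big)
    sum(vapply(0:(2^length(ids) - 1), function(mask) {
      sel <- ids[bitwAnd(mask, 2^(seq_along(ids) - 1)) > 0]
      sum(lengths(big[sel])) == target
    }, logical(1)))
  }
  for (target in c(1, 4, 7, 12, 20)) {
    expect_length(enumerate_combinations(big, target), naive_count(target))
  }
})

test_that("search finds a determining set and stops at the quality goal", {
  # one 2-item set alone determines y exactly
  bank <- item_bank(data.frame(
    item_id = paste0("R", 1:6), part = "reading", position = 1:6,
    set_id = c("g1", "g2", "g2", "g3", "g4", "g4")))
  sets <- group_items(bank)
  set.seed(17)
  resp <- matrix(rbinom(40 * 6, 1, 0.5), 40, dimnames = list(NULL, paste0("R", 1:6)))
  y <- 30 + 10 * resp[, "R2"] + 20 * resp[, "R3"]
  res <- exhaustive_search(sets, resp, y, goal = quality_goal(0.999))
  expect_true(res$goal_met)
  last <- res$curve[[length(res$curve)]]
  expect_equal(last$item_count, 2)
  expect_equal(last$sets, "g2")
  expect_equal(last$cv$pearson_r, 1, tolerance = 1e-9)
  expect_equal(res$final_model$intercept, 30L)
  expect_equal(res$final_model$weights, c(R2 = 10L, R3 = 20L))
  expect_equal(res$pass_used, "reading_only")
})

test_that("an unreachable goal returns the full curve and no model", {
  co <- recovery_cohort(seed = 3, n = 50)
  # continuous noise makes r = 1 strictly unattainable for any subset
  set.seed(3)
  y <- co$full + rnorm(length(co$full), sd = 2)
  res <- exhaustive_search(co$sets, co$responses, y,
                           goal = quality_goal(1))
  expect_false(res$goal_met)
  expect_null(res$final_model)
  curve <- performance_curve(res)
  expect_gt(nrow(curve), 1)
  # accounting identity: item_count equals the sizes of that row's sets
  sizes <- vapply(strsplit(curve$sets, ";"), function(s) {
    sum(lengths(co$sets[s]))
  }, numeric(1))
  expect_equal(curve$item_count, sizes)
})

test_that("search winners equal the naive power-set oracle per item count", {
  co <- recovery_cohort(seed = 9, n = 45)
  res <- exhaustive_search(co$sets, co$responses, co$full,
                           goal = quality_goal(0.9),
                           config = search_config(exact = TRUE))
  oracle <- oracle_search(co$sets, co$responses, co$full, r_min = 0.9)
  for (entry in res$curve) {
    ow <- oracle[[as.character(entry$item_count)]]
    expect_equal(sort(entry$sets), sort(ow$sets))
    expect_equal(entry$cv$pearson_r, ow$r, tolerance = 1e-8)
    expect_equal(entry$cv$rmse, ow$rmse, tolerance = 1e-8)
  }
})

test_that("screened and exact modes agree on the packaged instances", {
  co <- recovery_cohort(seed = 13, n = 60)
  exact <- exhaustive_search(co$sets, co$responses, co$full,
                             config = search_config(exact = TRUE))
  screened <- exhaustive_search(co$sets, co$responses, co$full,
                                config = search_config(screen_top = 3))
  expect_equal(performance_curve(exact), performance_curve(screened))
  expect_equal(exact$final_model, screened$final_model)
})

test_that("the search is deterministic", {
  co <- recovery_cohort(seed = 2, n = 50)
  r1 <- exhaustive_search(co$sets, co$responses, co$full)
  r2 <- exhaustive_search(co$sets, co$responses, co$full)
  expect_identical(r1, r2)
})

test_that("the numeracy fallback pass engages only when reading items fail", {
  # y driven entirely by a numeracy item: the reading-only pass cannot
  # reach the goal, the fallback pass can
  bank <- item_bank(data.frame(
    item_id = c("R1", "R2", "N1"),
    part = c("reading", "reading", "numeracy"),
    position = c(1L, 2L, 1L),
    set_id = c("g1", "g1", NA)))
  sets <- group_items(bank)
  set.seed(23)
  resp <- matrix(rbinom(40 * 3, 1, 0.5), 40,
                 dimnames = list(NULL, c("R1", "R2", "N1")))
  y <- 40 + 30 * resp[, "N1"]
  res <- exhaustive_search(sets, resp, y, goal = quality_goal(0.95),
                           numeracy_items = "N1")
  expect_true(res$goal_met)
  expect_equal(res$pass_used, "with_numeracy")
  expect_equal(res$final_model$weights[["N1"]], 30L)
})

test_that("float OLS never fits worse in-sample than the trimmed model", {
  for (seed in 1:5) {
    co <- recovery_cohort(seed = seed, n = 40)
    for (combo in list("s2", c("s2", "s3"), c("s1", "s4"))) {
      X <- co$responses[, unlist(co$sets[combo]), drop = FALSE]
      fit <- fit_integer_mlr(X, co$full)
      expect_lte(fit$rmse, fit$trimmed_rmse + 1e-12)
    }
  }
})

test_that("in-sample RMSE is non-increasing under combination supersets", {
  for (seed in 1:5) {
    co <- recovery_cohort(seed = seed, n = 40)
    nested <- list("s1", c("s1", "s2"), c("s1", "s2", "s3"),
                   c("s1", "s2", "s3", "s4"))
    rmse <- vapply(nested, function(combo) {
      X <- co$responses[, unlist(co$sets[combo]), drop = FALSE]
      fit_integer_mlr(X, co$full)$rmse
    }, numeric(1))
    expect_true(all(diff(rmse) <= 1e-10))
  }
})
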