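#' Quality goal for the short-form search
#'
#' The search accepts the smallest model whose pooled leave-one-out Pearson
#' correlation with the full-length score reaches `r_min` (default 0.9, the
#' conventional bar for a very strong correlation). By default numeracy
#' items are excluded so the short form needs no trained interviewer; the
#' search falls back to a pass that admits numeracy sets only if no
#' reading-only model meets the goal. Set `numeracy_allowed = TRUE` to admit
#' numeracy sets from the start.
#'
#' @param r_min correlation threshold in `(0, 1]`.
#' @param numeracy_allowed admit numeracy sets in the first pass?
#' @return Object of class `quality_goal`.
#' @export
quality_goal <- function(r_min = 0.9, numeracy_allowed = FALSE) {
  if (!(r_min > 0 && r_min <= 1)) stop("r_min must be in (0, 1]")
  structure(list(r_min = r_min, numeracy_allowed = isTRUE(numeracy_allowed)),
            class = "quality_goal")
}

#' Search configuration
#'
#' @param screen_top with screening enabled, the number of candidate
#'   combinations per item count that receive the exact integer-trimmed
#'   LOOCV after the closed-form PRESS screen (see Details).
#' @param exact disable the PRESS screen and run exact LOOCV on every
#'   combination.
#' @param trim `"round"` (round half away from zero) or `"truncate"`.
#' @param max_item_count optional cap on the model sizes scanned.
#'
#' @details The exhaustive search over all set combinations at every item
#' count implies on the order of 1e5 LOOCV evaluations for the canonical
#' 19-set bank. The default two-stage mode therefore screens every
#' combination with the closed-form leave-one-out error of the float
#' least-squares fit (the PRESS statistic, computed from leverage values)
#' and runs the exact integer-trimmed LOOCV only on the `screen_top` best
#' candidates per item count. `exact = TRUE` forces full integer LOOCV
#' everywhere; both modes agree on all packaged test instances.
#'
#' @return Object of class `search_config`.
#' @export
search_config <- function(screen_top = 50, exact = FALSE,
                          trim = c("round", "truncate"),
                          max_item_count = NULL) {
  trim <- match.arg(trim)
  stopifnot(screen_top >= 1)
  structure(list(screen_top = as.integer(screen_top), exact = isTRUE(exact),
                 trim = trim, max_item_count = max_item_count),
            class = "search_config")
}

#' Integer-trimmed multiple linear regression
#'
#' Fits ordinary least squares of `y` on the binary predictors `X` (with
#' intercept) and trims every coefficient, including the intercept, to an
#' integer so the resulting rule can be scored by hand. A rank-deficient
#' design (e.g. a constant column) is solved with the Moore-Penrose
#' pseudo-inverse, keeping the coefficient vector at full length, and is
#' flagged rather than an error so cross-validation folds never change
#' shape.
#'
#' @param X numeric matrix (participants x items).
#' @param y numeric response (full-length scores).
#' @param trim trimming rule, `"round"` (half away from zero) or
#'   `"truncate"`.
#' @return List of class `integer_mlr` with elements `intercept`,
#'   `coefficients` (float solution), `trimmed_intercept`,
#'   `trimmed_coefficients`, `fitted`, `rmse` (in-sample, float fit),
#'   `trimmed_fitted`, `trimmed_rmse`, and `rank_deficient`.
#' @export
fit_integer_mlr <- function(X, y, trim = c("round", "truncate")) {
  trim <- match.arg(trim)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n <= p) stop("need more participants than predictors (n = ", n,
                   ", p = ", p, ")")
  Xd <- cbind(`(intercept)` = 1, X)
  qrd <- qr(Xd)
  rank_deficient <- qrd$rank < ncol(Xd)
  if (!rank_deficient) {
    beta <- qr.coef(qrd, y)
  } else {
    beta <- as.numeric(MASS::ginv(Xd) %*% y)
    names(beta) <- colnames(Xd)
  }
  fitted <- as.numeric(Xd %*% beta)
  trimmed <- trim_coefficients(beta, trim)
  trimmed_fitted <- as.numeric(Xd %*% trimmed)
  structure(list(
    intercept = unname(beta[1]),
    coefficients = beta[-1],
    trimmed_intercept = as.integer(trimmed[1]),
    trimmed_coefficients = stats::setNames(as.integer(trimmed[-1]), colnames(X)),
    fitted = fitted,
    rmse = sqrt(mean((y - fitted)^2)),
    trimmed_fitted = trimmed_fitted,
    trimmed_rmse = sqrt(mean((y - trimmed_fitted)^2)),
    rank_deficient = rank_deficient
  ), class = "integer_mlr")
}

#' Leave-one-out cross-validation of an integer-trimmed model
#'
#' For each participant i the model is fitted on the other n - 1 rows,
#' trimmed to integers, and used to predict row i. The pooled out-of-fold
#' predictions give the RMSE and the Pearson correlation (with Fisher-z 95%
#' confidence interval) against `y`. The reported model parameters are the
#' per-fold float coefficient means, trimmed to integers once at the end —
#' trimming each fold and then averaging would generally yield non-integer
#' coefficients.
#'
#' @inheritParams fit_integer_mlr
#' @return List of class `cv_result`: `predictions`, `rmse`, `pearson_r`,
#'   `r_ci95`, `p_value`, `mean_intercept`, `mean_coefficients`,
#'   `trimmed_intercept`, `trimmed_coefficients`, `rank_deficient`, `n`.
#' @export
loocv_evaluate <- function(X, y, trim = c("round", "truncate")) {
  trim <- match.arg(trim)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop("leave-one-out cross-validation needs at least 3 rows")
  if (n - 1 <= p) stop("each fold needs more rows than predictors (n = ",
                       n, ", p = ", p, ")")
  preds <- numeric(n)
  coefs <- matrix(NA_real_, n, p + 1)
  any_deficient <- FALSE
  for (i in seq_len(n)) {
    fit <- fit_integer_mlr(X[-i, , drop = FALSE], y[-i], trim = trim)
    any_deficient <- any_deficient || fit$rank_deficient
    coefs[i, ] <- c(fit$intercept, fit$coefficients)
    preds[i] <- fit$trimmed_intercept +
      sum(fit$trimmed_coefficients * X[i, ])
  }
  mean_beta <- colMeans(coefs)
  trimmed <- trim_coefficients(mean_beta, trim)
  rmse <- sqrt(mean((preds - y)^2))
  if (stats::sd(preds) > 0 && stats::sd(y) > 0 && n >= 4) {
    pc <- pearson_with_ci(preds, y)
    r <- pc$r; ci <- pc$ci95; pv <- pc$p_value
  } else {
    r <- NA_real_; ci <- c(NA_real_, NA_real_); pv <- NA_real_
  }
  structure(list(
    predictions = stats::setNames(preds, rownames(X)),
    rmse = rmse, pearson_r = r, r_ci95 = ci, p_value = pv,
    mean_intercept = mean_beta[1],
    mean_coefficients = stats::setNames(mean_beta[-1], colnames(X)),
    trimmed_intercept = as.integer(trimmed[1]),
    trimmed_coefficients = stats::setNames(as.integer(trimmed[-1]), colnames(X)),
    rank_deficient = any_deficient, n = n
  ), class = "cv_result")
}

# Closed-form leave-one-out RMSE of the float least-squares fit (the PRESS
# statistic): press_i = e_i / (1 - h_ii) with h the leverage. Used only to
# screen combinations; the exact integer-trimmed LOOCV decides.
press_rmse <- function(X, y) {
  X <- as.matrix(X)
  Xd <- cbind(1, X)
  qrd <- qr(Xd)
  if (qrd$rank < ncol(Xd)) {
    pinv <- MASS::ginv(Xd)
    beta <- as.numeric(pinv %*% y)
    h <- rowSums(Xd * t(pinv))
  } else {
    beta <- qr.coef(qrd, y)
    Q <- qr.Q(qrd)
    h <- rowSums(Q^2)
  }
  e <- y - as.numeric(Xd %*% beta)
  denom <- pmax(1 - h, 1e-8)
  sqrt(mean((e / denom)^2))
}

#' Enumerate set combinations with a given total item count
#'
#' Yields every subset of `sets` whose sizes sum exactly to
#' `target_item_count`, in deterministic lexicographic order of set ids.
#'
#' @param sets named list of item-id vectors ([group_items()] output).
#' @param target_item_count required total number of items.
#' @return List of character vectors of set ids (possibly empty).
#' @examples
#' sets <- list(s1 = "a", s2 = "b", s3 = c("c", "d"))
#' enumerate_combinations(sets, 2)  # {s1,s2} and {s3}
#' @export
enumerate_combinations <- function(sets, target_item_count) {
  if (target_item_count < 1) return(list())
  ids <- sort(names(sets), method = "radix")
  sizes <- lengths(sets)[ids]
  out <- list()
  # DFS in lexicographic id order; prune on the remaining attainable sum
  suffix_sum <- rev(cumsum(rev(sizes)))
  recurse <- function(idx, chosen, remaining) {
    if (remaining == 0) {
      out[[length(out) + 1]] <<- chosen
      return(invisible())
    }
    if (idx > length(ids) || remaining > suffix_sum[idx]) return(invisible())
    if (sizes[idx] <= remaining) {
      recurse(idx + 1, c(chosen, ids[idx]), remaining - sizes[idx])
    }
    recurse(idx + 1, chosen, remaining)
  }
  recurse(1, character(0), target_item_count)
  out
}

#' Exhaustive short-form search
#'
#' The core algorithm: for every model size (starting from 1 item and
#' scanning upward until the quality goal is met) all combinations of
#' sentence sets with exactly that many items are evaluated by
#' integer-trimmed least squares under leave-one-out cross-validation, and
#' the combination with the highest pooled Pearson correlation against the
#' full-length score is retained (ties broken by lower RMSE, then fewer
#' sets, then lexicographic set ids). The search stops at the smallest item
#' count whose best correlation reaches `goal$r_min`. If no reading-only
#' model meets the goal at any size, a second pass admits numeracy items
#' (as singleton sets) and is recorded in `pass_used`.
#'
#' @param sets reading sentence sets from [group_items()].
#' @param responses response matrix covering all set items (and numeracy
#'   items if a fallback pass may run).
#' @param full_scores numeric vector of full-length scores aligned to
#'   `responses` rows (from [score_full()] or supplied).
#' @param goal a [quality_goal()].
#' @param numeracy_items character vector of numeracy item ids available
#'   for the fallback pass (each becomes a singleton set); `NULL` disables
#'   the fallback.
#' @param config a [search_config()].
#' @return Object of class `search_result` with elements `curve` (one entry
#'   per scanned item count: `item_count`, `sets`, `cv`), `final_model` (a
#'   [shortform_model()], or `NULL` if the goal was not met), `goal_met`,
#'   `pass_used` (`"reading_only"` or `"with_numeracy"`), and `goal`.
#' @seealso [performance_curve()] to tabulate the curve.
#' @export
exhaustive_search <- function(sets, responses, full_scores,
                              goal = quality_goal(), numeracy_items = NULL,
                              config = search_config()) {
  stopifnot(inherits(goal, "quality_goal"), inherits(config, "search_config"))
  if (length(full_scores) != nrow(responses)) {
    stop("full_scores must align with the rows of responses")
  }
  pool_reading <- sets
  pool_numeracy <- if (length(numeracy_items) > 0) {
    stats::setNames(as.list(numeracy_items), numeracy_items)
  } else NULL

  if (goal$numeracy_allowed && !is.null(pool_numeracy)) {
    res <- search_one_pass(c(pool_reading, pool_numeracy), responses,
                           full_scores, goal, config)
    res$pass_used <- "with_numeracy"
  } else {
    res <- search_one_pass(pool_reading, responses, full_scores, goal, config)
    res$pass_used <- "reading_only"
    if (!res$goal_met && !is.null(pool_numeracy)) {
      res <- search_one_pass(c(pool_reading, pool_numeracy), responses,
                             full_scores, goal, config)
      res$pass_used <- "with_numeracy"
    }
  }
  res$goal <- goal
  class(res) <- "search_result"
  res
}

search_one_pass <- function(pool, responses, full_scores, goal, config) {
  missing_items <- setdiff(unlist(pool), colnames(responses))
  if (length(missing_items) > 0) {
    stop("responses are missing item(s): ", paste(missing_items, collapse = ", "))
  }
  n <- nrow(responses)
  total_items <- sum(lengths(pool))
  max_count <- min(total_items, config$max_item_count %||% total_items,
                   n - 2)  # LOOCV folds need n - 1 > p
  curve <- list()
  goal_met <- FALSE
  final_model <- NULL
  for (count in seq_len(max_count)) {
    combos <- enumerate_combinations(pool, count)
    if (length(combos) == 0) next
    best <- best_at_count(pool, combos, responses, full_scores, config)
    curve[[length(curve) + 1]] <- list(item_count = count,
                                       sets = best$combo, cv = best$cv)
    if (!is.na(best$cv$pearson_r) && best$cv$pearson_r >= goal$r_min) {
      goal_met <- TRUE
      final_model <- model_from_cv(pool, best$combo, best$cv)
      break
    }
  }
  list(curve = curve, final_model = final_model, goal_met = goal_met)
}

best_at_count <- function(pool, combos, responses, full_scores, config) {
  design_for <- function(combo) {
    responses[, unlist(pool[combo]), drop = FALSE]
  }
  candidates <- combos
  if (!config$exact && length(combos) > config$screen_top) {
    press <- vapply(combos, function(cb) press_rmse(design_for(cb), full_scores),
                    numeric(1))
    keep <- order(press)[seq_len(config$screen_top)]
    candidates <- combos[sort(keep)]  # keep enumeration (lexicographic) order
  }
  best <- NULL
  for (cb in candidates) {
    cv <- loocv_evaluate(design_for(cb), full_scores, trim = config$trim)
    cand <- list(combo = cb, cv = cv)
    if (is.null(best) || better_candidate(cand, best)) best <- cand
  }
  best
}

# Ranking of candidates at a fixed item count: higher pooled LOOCV r, then
# lower RMSE, then fewer sets, then lexicographically smaller set ids. An
# undefined r (constant predictions) ranks below any defined r.
better_candidate <- function(a, b) {
  ra <- if (is.na(a$cv$pearson_r)) -Inf else a$cv$pearson_r
  rb <- if (is.na(b$cv$pearson_r)) -Inf else b$cv$pearson_r
  if (ra != rb) return(ra > rb)
  if (a$cv$rmse != b$cv$rmse) return(a$cv$rmse < b$cv$rmse)
  if (length(a$combo) != length(b$combo)) return(length(a$combo) < length(b$combo))
  paste(sort(a$combo), collapse = "|") < paste(sort(b$combo), collapse = "|")
}

model_from_cv <- function(pool, combo, cv) {
  shortform_model(
    intercept = cv$trimmed_intercept,
    weights = cv$trimmed_coefficients,
    provenance = sprintf(
      "exhaustive LOOCV search: sets {%s}, %d items, pooled r = %.3f, rmse = %.2f",
      paste(combo, collapse = ", "), length(cv$trimmed_coefficients),
      cv$pearson_r, cv$rmse)
  )
}

#' Tabulate the search performance curve
#'
#' One row per scanned item count: the best combination's pooled LOOCV
#' Pearson correlation and RMSE, the number of sets, and the set ids. This
#' is the "best possible model performance as a function of the number of
#' items" curve.
#'
#' @param result a `search_result` from [exhaustive_search()].
#' @return Data frame with columns `item_count`, `best_r`, `best_rmse`,
#'   `n_sets`, `sets` (semicolon-joined ids), ordered by `item_count`.
#' @export
performance_curve <- function(result) {
  stopifnot(inherits(result, "search_result"))
  rows <- lapply(result$curve, function(e) {
    data.frame(item_count = e$item_count,
               best_r = e$cv$pearson_r,
               best_rmse = e$cv$rmse,
               n_sets = length(e$sets),
               sets = paste(e$sets, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(item_count = integer(0), best_r = numeric(0),
                      best_rmse = numeric(0), n_sets = integer(0),
                      sets = character(0))
  }
  out[order(out$item_count), , drop = FALSE]
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result: %s pass, %d item counts scanned, goal %s>\n",
              x$pass_used, length(x$curve),
              if (x$goal_met) "met" else "not met"))
  if (x$goal_met) {
    last <- x$curve[[length(x$curve)]]
    cat(sprintf("  final model: %d items, r = %.3f, rmse = %.2f\n",
                last$item_count, last$cv$pearson_r, last$cv$rmse))
  }
  invisible(x)
}
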