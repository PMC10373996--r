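#' Cronbach's alpha
#'
#' Internal-consistency reliability of a set of items:
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(item sum))`,
#' with sample variances (n - 1 denominator). An instrument is conventionally
#' considered reliable when alpha exceeds 0.7.
#'
#' @param responses numeric matrix (participants x items), typically a
#'   response matrix restricted to a model's items.
#' @return List of class `alpha_result`: `alpha`, `n_items`, `reliable`
#'   (`alpha > 0.7`).
#' @export
cronbach_alpha <- function(responses) {
  x <- as.matrix(responses)
  k <- ncol(x)
  if (k < 2) stop("Cronbach's alpha needs at least 2 items")
  if (nrow(x) < 2) stop("Cronbach's alpha needs at least 2 participants")
  total <- rowSums(x)
  v_total <- stats::var(total)
  if (v_total == 0) stop("total score has zero variance; alpha is undefined")
  alpha <- k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / v_total)
  structure(list(alpha = alpha, n_items = k, reliable = alpha > 0.7),
            class = "alpha_result")
}

#' @export
print.alpha_result <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f over %d items (%s)\n", x$alpha,
              x$n_items, if (x$reliable) "reliable, > 0.7" else "below 0.7"))
  invisible(x)
}

#' Point-biserial item-scale correlations
#'
#' Pearson correlation between each binary item and a continuous total
#' score, with a two-sided p-value from the t distribution. Strength labels
#' follow the conventional bands on `|r|`: weak below 0.2, medium 0.2 to
#' 0.5, high 0.5 and above (lower bounds inclusive). A constant item has an
#' undefined correlation and is flagged rather than dropped.
#'
#' @param responses binary response matrix (participants x items).
#' @param total_scores numeric score vector aligned to the rows.
#' @return Data frame with columns `item_id`, `r_pb`, `strength` (`"weak"`,
#'   `"medium"`, `"high"` or `"undefined"`), `p_value`, `undefined`.
#' @export
point_biserial_all <- function(responses, total_scores) {
  x <- as.matrix(responses)
  if (length(total_scores) != nrow(x)) {
    stop("total_scores must align with the rows of responses")
  }
  if (stats::sd(total_scores) == 0) stop("total score is constant")
  n <- nrow(x)
  rows <- lapply(colnames(x), function(id) {
    v <- x[, id]
    if (stats::sd(v) == 0) {
      return(data.frame(item_id = id, r_pb = NA_real_,
                        strength = "undefined", p_value = NA_real_,
                        undefined = TRUE, stringsAsFactors = FALSE))
    }
    r <- stats::cor(v, total_scores)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    data.frame(item_id = id, r_pb = r,
               strength = correlation_strength(r), p_value = p,
               undefined = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Label the strength of a correlation
#' @param r correlation coefficient(s).
#' @return `"weak"` for `|r| < 0.2`, `"medium"` for `0.2 <= |r| < 0.5`,
#'   `"high"` for `|r| >= 0.5`.
#' @export
correlation_strength <- function(r) {
  a <- abs(r)
  ifelse(a < 0.2, "weak", ifelse(a < 0.5, "medium", "high"))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y numeric vectors of equal length (n >= 4), both non-constant.
#' @return List: `r`, `ci95` (Fisher z-transform interval with normal
#'   quantile 1.96), `p_value` (two-sided, t distribution with n - 2 df),
#'   `n`.
#' @export
pearson_with_ci <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input; correlation undefined")
  r <- stats::cor(x, y)
  if (abs(r) < 1) {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    ci <- tanh(c(z - 1.96 * se, z + 1.96 * se))
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    ci <- c(r, r)
    p <- 0
  }
  list(r = r, ci95 = ci, p_value = p, n = n)
}

#' Three-level confusion matrix
#'
#' Cross-tabulates true against predicted functional health literacy
#' levels in the fixed order inadequate, marginal, adequate (rows = true).
#'
#' @param true_levels,predicted_levels vectors of level labels (character
#'   or factor); values outside the three levels are an error.
#' @return 3 x 3 integer matrix of class `confusion3`.
#' @export
confusion_levels <- function(true_levels, predicted_levels) {
  if (length(true_levels) != length(predicted_levels)) {
    stop("level vectors must have equal length")
  }
  check <- function(v, what) {
    bad <- setdiff(unique(as.character(v)), fhl_levels())
    if (length(bad) > 0) stop("unknown ", what, " level: '", bad[1], "'")
    factor(as.character(v), levels = fhl_levels())
  }
  tt <- check(true_levels, "true")
  pp <- check(predicted_levels, "predicted")
  m <- table(true = tt, predicted = pp)
  m <- matrix(as.integer(m), 3, 3,
              dimnames = list(true = fhl_levels(), predicted = fhl_levels()))
  structure(m, class = c("confusion3", "matrix"))
}

#' One-vs-rest classification accuracy
#'
#' Collapses the 3 x 3 confusion matrix to `level` vs the rest and returns
#' `(TP + TN) / N` as a whole percent (rounded half-up). For the adequate
#' level this equals the accuracy of detecting "low FHL" (inadequate or
#' marginal).
#'
#' @param m a `confusion3` matrix from [confusion_levels()].
#' @param level one of `"inadequate"`, `"marginal"`, `"adequate"`.
#' @return Integer percent.
#' @export
one_vs_rest_accuracy <- function(m, level) {
  stopifnot(inherits(m, "confusion3"))
  level <- match.arg(level, fhl_levels())
  i <- match(level, fhl_levels())
  n <- sum(m)
  if (n == 0) stop("empty confusion matrix")
  tp <- m[i, i]
  tn <- sum(m[-i, -i])
  as.integer(round_half_up((tp + tn) / n * 100))
}

#' Distribution of ordinal prediction errors
#'
#' Treats the three levels as ordinal (0, 1, 2) and counts predictions that
#' are exact, off by one level, and off by two levels. The counts sum to
#' the number of participants.
#'
#' @param m a `confusion3` matrix.
#' @return Named integer vector with names `"0"`, `"1"`, `"2"`.
#' @export
off_by_k <- function(m) {
  stopifnot(inherits(m, "confusion3"))
  d <- abs(outer(0:2, 0:2, "-"))
  out <- vapply(0:2, function(k) sum(m[d == k]), numeric(1))
  stats::setNames(as.integer(out), as.character(0:2))
}
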