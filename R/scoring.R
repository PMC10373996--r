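#' Full-length total score on the 0-100 scale
#'
#' The full-length instrument is scored on 0-100 with the two parts worth 50
#' points each: reading items score 1 point per correct answer (50 items =
#' 50 points) and the numeracy raw count is rescaled to 0-50 (x 50/17 for
#' the canonical 17-item part), rounded half-up to an integer. For a bank
#' whose parts differ in size from 50/17 the same equal-halves convention is
#' applied (each part rescaled to 50); a bank with a single part is rescaled
#' to the full 0-100 range.
#'
#' @param responses response matrix covering every bank item.
#' @param bank an [item_bank()].
#' @return Named numeric vector of integer scores in `[0, 100]`, one per
#'   participant.
#' @export
score_full <- function(responses, bank) {
  stopifnot(inherits(bank, "item_bank"))
  missing_items <- setdiff(bank$item_id, colnames(responses))
  if (length(missing_items) > 0) {
    stop("responses are missing bank item(s): ",
         paste(utils::head(missing_items, 5), collapse = ", "),
         if (length(missing_items) > 5) ", ...")
  }
  reading_ids <- bank$item_id[bank$part == "reading"]
  numeracy_ids <- bank$item_id[bank$part == "numeracy"]
  parts <- Filter(function(ids) length(ids) > 0,
                  list(reading = reading_ids, numeracy = numeracy_ids))
  points_per_part <- 100 / length(parts)
  score <- rep(0, nrow(responses))
  for (ids in parts) {
    raw <- rowSums(responses[, ids, drop = FALSE])
    score <- score + round_half_up(raw * points_per_part / length(ids))
  }
  stats::setNames(as.numeric(score), rownames(responses))
}

#' Score a short-form model
#'
#' Applies the integer-weighted linear rule `Y_i = b0 + sum_j w_j x_ij` and
#' clips the result to `[0, score_max]` (with non-negative weights and the
#' canonical models the clip never binds).
#'
#' @param responses response matrix covering every weighted item of the
#'   model.
#' @param model a [shortform_model()].
#' @return Named numeric vector of predicted full-length scores.
#' @examples
#' m <- ds_tofhla_model()
#' all_correct <- matrix(1, 1, length(m$weights),
#'                       dimnames = list("P1", names(m$weights)))
#' score_shortform(all_correct, m)  # 95 = 23 + sum of the weights
#' @export
score_shortform <- function(responses, model) {
  stopifnot(inherits(model, "shortform_model"))
  missing_items <- setdiff(names(model$weights), colnames(responses))
  if (length(missing_items) > 0) {
    stop("responses are missing weighted item(s): ",
         paste(missing_items, collapse = ", "))
  }
  x <- responses[, names(model$weights), drop = FALSE]
  y <- model$intercept + as.numeric(x %*% model$weights)
  y <- pmin(pmax(y, 0), model$scale$score_max)
  stats::setNames(y, rownames(responses))
}

#' Fixed-weight mirror models of the American short forms
#'
#' `mirror_s_model()` is the S-TOFHLA weighting applied to the Danish item
#' bank (the "D-36-4" model): the first 36 reading items at 2 points each
#' plus numeracy items 1, 4, 5 and 8 at 7 points each, maximum score
#' 72 + 28 = 100. `mirror_prose_model()` omits the numeracy items
#' ("D-36-0"), maximum score 72. Neither has an intercept.
#'
#' @return A [shortform_model()].
#' @export
mirror_s_model <- function() {
  w <- c(stats::setNames(rep(2L, 36), paste0("R", 1:36)),
         stats::setNames(rep(7L, 4), paste0("N", c(1, 4, 5, 8))))
  shortform_model(0L, w, provenance = "fixed-weight mirror of the S-TOFHLA (36 reading + 4 numeracy)")
}

#' @rdname mirror_s_model
#' @export
mirror_prose_model <- function() {
  w <- stats::setNames(rep(2L, 36), paste0("R", 1:36))
  shortform_model(0L, w, provenance = "fixed-weight mirror of the Prose S-TOFHLA (36 reading items)")
}

#' Score the fixed-weight mirror models
#'
#' Convenience wrappers around [score_shortform()] with [mirror_s_model()]
#' and [mirror_prose_model()]. `bank` is used only to check that the
#' required items exist.
#'
#' @inheritParams score_full
#' @return Named numeric score vector.
#' @export
score_mirror_s <- function(responses, bank) {
  m <- mirror_s_model()
  validate_model_against_bank(m, bank)
  score_shortform(responses, m)
}

#' @rdname score_mirror_s
#' @export
score_mirror_prose <- function(responses, bank) {
  m <- mirror_prose_model()
  validate_model_against_bank(m, bank)
  score_shortform(responses, m)
}

#' Classify scores into functional health literacy levels
#'
#' @param score numeric vector of scores in `[0, score_max]`.
#' @param scale a [level_scale()].
#' @return Factor with levels `inadequate` (score <= 59), `marginal`
#'   (60-74) and `adequate` (75+), under the default scale.
#' @examples
#' classify_level(c(59, 60, 74, 75))
#' @export
classify_level <- function(score, scale = level_scale()) {
  stopifnot(inherits(scale, "level_scale"))
  if (any(score < 0 | score > scale$score_max)) {
    stop("score outside [0, ", scale$score_max, "]")
  }
  lv <- ifelse(score <= scale$inadequate_max, "inadequate",
               ifelse(score <= scale$marginal_max, "marginal", "adequate"))
  factor(lv, levels = fhl_levels())
}

#' Ordered level labels
#' @return `c("inadequate", "marginal", "adequate")`.
#' @export
fhl_levels <- function() c("inadequate", "marginal", "adequate")

#' Administration-time model
#'
#' The full-length instrument takes at most 22 minutes: 12 minutes for the
#' 50 reading items and 10 minutes for the 17 numeracy items. A shorter
#' form's maximum time is prorated per part and rounded up to whole minutes,
#' which reproduces the published times for every instrument variant (22,
#' 12, 9 and 5 minutes).
#'
#' @param reading_minutes_full,numeracy_minutes_full minutes for the full
#'   parts.
#' @param n_reading_full,n_numeracy_full item counts of the full parts.
#' @return Object of class `admin_time_model`.
#' @export
admin_time_model <- function(reading_minutes_full = 12, numeracy_minutes_full = 10,
                             n_reading_full = 50, n_numeracy_full = 17) {
  vals <- c(reading_minutes_full, numeracy_minutes_full,
            n_reading_full, n_numeracy_full)
  if (any(vals <= 0)) stop("administration-time model parameters must be positive")
  structure(list(reading_minutes_full = reading_minutes_full,
                 numeracy_minutes_full = numeracy_minutes_full,
                 n_reading_full = n_reading_full,
                 n_numeracy_full = n_numeracy_full),
            class = "admin_time_model")
}

#' Maximum administration time of a (partial) instrument
#'
#' @param n_reading,n_numeracy number of reading / numeracy items
#'   administered (0 to the full part size).
#' @param model an [admin_time_model()].
#' @return Whole minutes: `ceil(12 * n_reading / 50) + ceil(10 * n_numeracy
#'   / 17)` under the default model.
#' @examples
#' admin_time(50, 17)  # 22 minutes, full length
#' admin_time(20, 0)   # 5 minutes, 20-item reading-only short form
#' @export
admin_time <- function(n_reading, n_numeracy, model = admin_time_model()) {
  stopifnot(inherits(model, "admin_time_model"))
  if (n_reading < 0 || n_numeracy < 0) stop("item counts must be non-negative")
  if (n_reading > model$n_reading_full || n_numeracy > model$n_numeracy_full) {
    stop("item counts exceed the full-length part sizes")
  }
  as.integer(ceiling(model$reading_minutes_full * n_reading / model$n_reading_full) +
             ceiling(model$numeracy_minutes_full * n_numeracy / model$n_numeracy_full))
}
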