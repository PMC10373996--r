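#' Compare instrument variants on one cohort
#'
#' Scores the full-length instrument, the two fixed-weight mirror models
#' (S-TOFHLA weighting with and without numeracy items) and a derived short
#' form on the same cohort, correlating each against the full-length score.
#' `reference_r` carries the correlations reported for the original Danish
#' development sample (TeleCare North, n = 158) as annotations only — they
#' are sample-specific and are not expected values for other cohorts.
#'
#' @param responses response matrix covering all bank items.
#' @param bank the canonical [item_bank()].
#' @param shortform a [shortform_model()] (e.g. [ds_tofhla_model()]).
#' @return Data frame with one row per model: `model`, `n_reading`,
#'   `n_numeracy`, `admin_minutes`, `r_vs_full`, `ci_lo`, `ci_hi`,
#'   `reference_r`, `r_undefined` (TRUE when the cohort makes the
#'   correlation undefined, e.g. all scores identical).
#' @export
compare_models <- function(responses, bank, shortform = ds_tofhla_model()) {
  stopifnot(inherits(bank, "item_bank"), inherits(shortform, "shortform_model"))
  validate_model_against_bank(shortform, bank)
  full <- score_full(responses, bank)

  part_of <- stats::setNames(bank$part, bank$item_id)
  count_parts <- function(ids) {
    c(reading = sum(part_of[ids] == "reading"),
      numeracy = sum(part_of[ids] == "numeracy"))
  }
  sf_counts <- count_parts(names(shortform$weights))

  specs <- list(
    list(model = "full_length", n_reading = n_items(bank, "reading"),
         n_numeracy = n_items(bank, "numeracy"), scores = NULL,
         reference_r = NA_real_),
    list(model = "mirror_s", n_reading = 36, n_numeracy = 4,
         scores = score_mirror_s(responses, bank), reference_r = 0.90),
    list(model = "mirror_prose", n_reading = 36, n_numeracy = 0,
         scores = score_mirror_prose(responses, bank), reference_r = 0.85),
    list(model = "short_form", n_reading = unname(sf_counts["reading"]),
         n_numeracy = unname(sf_counts["numeracy"]),
         scores = score_shortform(responses, shortform), reference_r = 0.90)
  )
  rows <- lapply(specs, function(s) {
    ci <- c(NA_real_, NA_real_)
    r <- NA_real_
    undefined <- FALSE
    if (!is.null(s$scores)) {
      res <- tryCatch(pearson_with_ci(s$scores, full), error = function(e) NULL)
      if (is.null(res)) undefined <- TRUE else {
        r <- res$r; ci <- res$ci95
      }
    }
    data.frame(model = s$model, n_reading = s$n_reading,
               n_numeracy = s$n_numeracy,
               admin_minutes = admin_time(s$n_reading, s$n_numeracy),
               r_vs_full = r, ci_lo = ci[1], ci_hi = ci[2],
               reference_r = s$reference_r, r_undefined = undefined,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
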