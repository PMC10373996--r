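#' Packaged Danish TOFHLA fixtures
#'
#' `ds_tofhla_bank()` returns the canonical 67-item Danish TOFHLA bank: 50
#' reading-comprehension items `R1`-`R50` (ordered by increasing difficulty)
#' partitioned into 19 sentence sets, and 17 numeracy items `N1`-`N17`. The
#' six sets that make up the published short form (`R2`-`R3`, `R13`-`R14`,
#' `R18`-`R21`, `R23`-`R25`, `R37`-`R41`, `R42`-`R45`) are as published; the
#' boundaries of the remaining 13 sets are not public and are reconstructed
#' here to satisfy the published set-size distribution (5 sets of 1 item, 7
#' of 2, 1 of 3, 3 of 4, 2 of 5, 1 of 6) and within-set contiguity. Treat
#' those 13 boundaries as a fixture convention, not ground truth.
#'
#' `ds_tofhla_model()` returns the published 20-item DS-TOFHLA scoring rule:
#' intercept 23 and integer weights over the six sets above (items `R39`
#' and `R42` carry weight 0 — administered for sentence integrity but not
#' scored). Its score range is 23 (all incorrect) to 95 (all correct).
#'
#' `dev_cohort_levels()` returns the 158 true/predicted functional health
#' literacy level pairs of the published classification assessment;
#' [confusion_levels()] on them reproduces the published confusion matrix.
#'
#' @return `ds_tofhla_bank()`: an [item_bank()]; `ds_tofhla_model()`: a
#'   [shortform_model()]; `dev_cohort_levels()`: a data frame with columns
#'   `true` and `predicted`.
#' @examples
#' bank <- ds_tofhla_bank()
#' n_items(bank, "reading")    # 50
#' length(group_items(bank))   # 19
#' @export
ds_tofhla_bank <- function() {
  read_item_bank(shortform_file("ds_tofhla_bank.json"))
}

#' @rdname ds_tofhla_bank
#' @export
ds_tofhla_model <- function() {
  read_shortform_model(shortform_file("ds_tofhla_short.json"))
}

#' @rdname ds_tofhla_bank
#' @export
dev_cohort_levels <- function() {
  utils::read.csv(shortform_file("dev_cohort_levels.csv"),
                  stringsAsFactors = FALSE)
}

shortform_file <- function(...) {
  path <- system.file("extdata", ..., package = "shortform", mustWork = FALSE)
  if (path == "") stop("packaged file not found: ", file.path(...))
  path
}
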