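#' Group reading items into sentence-level sets
#'
#' Reading-comprehension items of a cloze instrument belong to sentences:
#' dropping part of a sentence would destroy its meaning, so the sentence
#' sets — not individual items — are the atomic units of the short-form
#' search. Set membership is data carried in the bank (a human judgment),
#' not inferred from item text.
#'
#' Validates that the sets partition the reading items (disjoint and
#' covering) and that each set's items are consecutive in administration
#' order.
#'
#' @param bank an [item_bank()] whose reading items all carry a `set_id`.
#' @return An object of class `item_sets`: a named list, one character
#'   vector of item ids per set, ordered by the set's first item position.
#' @examples
#' sets <- group_items(ds_tofhla_bank())
#' length(sets)            # 19 sentence sets
#' set_size_distribution(sets)
#' @export
group_items <- function(bank) {
  stopifnot(inherits(bank, "item_bank"))
  reading <- bank[bank$part == "reading", , drop = FALSE]
  if (nrow(reading) == 0) stop("bank has no reading items to group")
  if (any(is.na(reading$set_id))) {
    stop("reading item '", reading$item_id[which(is.na(reading$set_id))[1]],
         "' has no set_id")
  }
  reading <- reading[order(reading$position), , drop = FALSE]
  split_sets <- split(reading, reading$set_id)
  for (sid in names(split_sets)) {
    pos <- sort(split_sets[[sid]]$position)
    if (!all(diff(pos) == 1)) {
      stop("set '", sid, "' is not contiguous in administration order ",
           "(positions ", paste(pos, collapse = ","), ")")
    }
  }
  first_pos <- vapply(split_sets, function(s) min(s$position), numeric(1))
  split_sets <- split_sets[order(first_pos)]
  sets <- lapply(split_sets, function(s) s$item_id[order(s$position)])
  structure(sets, class = "item_sets")
}

#' Distribution of set sizes
#'
#' @param sets an `item_sets` object from [group_items()], or any named list
#'   of item-id vectors.
#' @return Named integer vector mapping set size to the number of sets of
#'   that size. The identity `sum(size * count) == number of reading items`
#'   always holds.
#' @export
set_size_distribution <- function(sets) {
  if (length(sets) == 0) return(integer(0))
  tab <- table(lengths(sets))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' @export
print.item_sets <- function(x, ...) {
  cat(sprintf("<item_sets: %d sets over %d items>\n",
              length(x), sum(lengths(x))))
  invisible(x)
}
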