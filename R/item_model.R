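#' Construct an item bank
#'
#' An item bank describes a full-length instrument: one row per item with its
#' identifier, part (`"reading"` or `"numeracy"`), administration position
#' within its part, and — for reading items — the sentence set it belongs to.
#'
#' @param items data frame with columns `item_id` (character), `part`
#'   (`"reading"`/`"numeracy"`), `position` (positive integer, administration
#'   order within the part) and `set_id` (character; `NA` allowed only for
#'   numeracy items).
#' @param name short label for the instrument.
#' @return An object of class `item_bank`: the validated data frame with a
#'   `name` attribute, ordered by part (reading first) then position.
#' @examples
#' bank <- item_bank(data.frame(
#'   item_id = c("R1", "R2", "N1"),
#'   part = c("reading", "reading", "numeracy"),
#'   position = c(1L, 2L, 1L),
#'   set_id = c("S1", "S1", NA)
#' ), name = "toy")
#' n_items(bank)
#' @export
item_bank <- function(items, name = "item bank") {
  stopifnot(is.data.frame(items))
  required <- c("item_id", "part", "position")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0) {
    stop("item bank is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"set_id" %in% names(items)) items$set_id <- NA_character_
  items$item_id <- as.character(items$item_id)
  items$part <- as.character(items$part)
  items$set_id <- as.character(items$set_id)

  bad_part <- !items$part %in% c("reading", "numeracy")
  if (any(bad_part)) {
    stop("unknown part label for item '", items$item_id[which(bad_part)[1]],
         "': '", items$part[which(bad_part)[1]], "'")
  }
  dup <- items$item_id[duplicated(items$item_id)]
  if (length(dup) > 0) {
    stop("duplicate item_id in bank: '", dup[1], "'")
  }
  if (any(!is_whole(items$position)) || any(items$position < 1)) {
    stop("item positions must be positive integers")
  }
  for (p in unique(items$part)) {
    pos <- items$position[items$part == p]
    if (anyDuplicated(pos)) {
      stop("duplicate position within part '", p, "'")
    }
  }
  no_set <- items$part == "reading" & (is.na(items$set_id) | items$set_id == "")
  if (any(no_set)) {
    stop("reading item '", items$item_id[which(no_set)[1]], "' has no set_id")
  }
  items$position <- as.integer(items$position)
  items <- items[order(match(items$part, c("reading", "numeracy")), items$position),
                 c("item_id", "part", "position", "set_id")]
  rownames(items) <- NULL
  structure(items, name = name, class = c("item_bank", "data.frame"))
}

#' Read an item bank from JSON
#'
#' Expects `{"name": ..., "items": [{"item_id", "part", "position",
#' "set_id"}, ...]}`; `set_id` may be `null` for numeracy items.
#'
#' @param path path to a bank JSON file.
#' @return An [item_bank()].
#' @export
read_item_bank <- function(path) {
  if (!file.exists(path)) stop("item bank file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(raw$items)) stop("bank JSON has no 'items' field: ", path)
  items <- as.data.frame(raw$items, stringsAsFactors = FALSE)
  item_bank(items, name = raw$name %||% basename(path))
}

#' Write an item bank to JSON
#' @param bank an [item_bank()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(inherits(bank, "item_bank"))
  out <- list(name = attr(bank, "name"),
              items = as.data.frame(unclass(bank), stringsAsFactors = FALSE))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}

#' Number of items in a bank
#' @param bank an [item_bank()].
#' @param part optionally restrict to `"reading"` or `"numeracy"`.
#' @return integer count.
#' @export
n_items <- function(bank, part = NULL) {
  stopifnot(inherits(bank, "item_bank"))
  if (is.null(part)) nrow(bank) else sum(bank$part == part)
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank '%s': %d items (%d reading, %d numeracy)>\n",
              attr(x, "name"), nrow(x), sum(x$part == "reading"),
              sum(x$part == "numeracy")))
  invisible(x)
}

#' Read a binary response matrix from CSV
#'
#' The CSV must have a `participant_id` first column and one 0/1 column per
#' item; every item column must exist in `bank`. Columns are re-ordered to
#' the bank's administration order. Missing or non-binary cells are an error
#' (responses are complete-case by design; no imputation is performed).
#'
#' @param path path to a responses CSV.
#' @param bank the [item_bank()] the responses refer to.
#' @return Integer matrix (participants x items) with participant ids as row
#'   names and item ids as column names.
#' @export
read_response_matrix <- function(path, bank) {
  stopifnot(inherits(bank, "item_bank"))
  if (!file.exists(path)) stop("response file not found: ", path)
  if (length(readLines(path, n = 2, warn = FALSE)) < 2) {
    stop("response file is empty: ", path)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "participant_id") {
    stop("first column of ", path, " must be 'participant_id'")
  }
  ids <- as.character(df[[1]])
  values <- as.matrix(df[, -1, drop = FALSE])
  response_matrix(values, participant_ids = ids, bank = bank)
}

#' Construct and validate a response matrix
#'
#' @param values numeric matrix of 0/1 responses with item ids as column
#'   names.
#' @param participant_ids character vector of unique participant ids; taken
#'   from `rownames(values)` when omitted.
#' @param bank optional [item_bank()]; when given, item columns are checked
#'   against the bank and re-ordered to bank order.
#' @return Integer matrix with dimnames set.
#' @export
response_matrix <- function(values, participant_ids = NULL, bank = NULL) {
  values <- as.matrix(values)
  if (is.null(participant_ids)) participant_ids <- rownames(values)
  if (is.null(participant_ids)) {
    participant_ids <- sprintf("P%03d", seq_len(nrow(values)))
  }
  participant_ids <- as.character(participant_ids)
  if (anyDuplicated(participant_ids)) {
    stop("duplicate participant_id: '",
         participant_ids[duplicated(participant_ids)][1], "'")
  }
  if (is.null(colnames(values))) stop("response matrix has no item column names")
  bad <- which(is.na(values) | !(values == 0 | values == 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-binary response at row %d (participant '%s'), column '%s'",
                 bad[1, 1], participant_ids[bad[1, 1]], colnames(values)[bad[1, 2]]))
  }
  if (!is.null(bank)) {
    unknown <- setdiff(colnames(values), bank$item_id)
    if (length(unknown) > 0) {
      stop("response column '", unknown[1], "' is not in the item bank")
    }
    ord <- bank$item_id[bank$item_id %in% colnames(values)]
    values <- values[, ord, drop = FALSE]
  }
  storage.mode(values) <- "integer"
  rownames(values) <- participant_ids
  values
}

#' Write a response matrix to CSV
#' @param responses matrix from [response_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(responses, path) {
  df <- data.frame(participant_id = rownames(responses),
                   responses, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Level thresholds for the 0-100 health literacy scale
#'
#' Functional health literacy is classified as inadequate (0-59 points),
#' marginal (60-74) or adequate (75-100); inadequate and marginal together
#' are "low FHL".
#'
#' @param inadequate_max top of the inadequate band (default 59).
#' @param marginal_max top of the marginal band (default 74).
#' @param score_max maximum of the scale (default 100).
#' @return An object of class `level_scale`.
#' @export
level_scale <- function(inadequate_max = 59, marginal_max = 74, score_max = 100) {
  stopifnot(is_whole(inadequate_max), is_whole(marginal_max), is_whole(score_max))
  if (!(0 < inadequate_max && inadequate_max < marginal_max &&
        marginal_max < score_max)) {
    stop("level scale must satisfy 0 < inadequate_max < marginal_max < score_max")
  }
  structure(list(inadequate_max = as.integer(inadequate_max),
                 marginal_max = as.integer(marginal_max),
                 score_max = as.integer(score_max)),
            class = "level_scale")
}

#' Construct a short-form scoring model
#'
#' A short-form model is an integer-weighted linear scoring rule
#' `Y = b0 + sum_j b_j C_j` over binary item responses `C_j`, together with
#' the level thresholds used to classify the predicted score. Weights of 0
#' are meaningful: such items are still administered (they complete a
#' sentence set) but contribute no points.
#'
#' @param intercept integer intercept `b0`.
#' @param weights named integer vector of per-item weights (names are item
#'   ids; only included items are listed — an absent item is not
#'   administered).
#' @param scale a [level_scale()].
#' @param provenance free-text description of how the model was obtained.
#' @return An object of class `shortform_model`.
#' @export
shortform_model <- function(intercept, weights, scale = level_scale(),
                            provenance = "") {
  if (!is_whole(intercept)) stop("model intercept must be an integer")
  if (length(weights) == 0 || is.null(names(weights)) || any(names(weights) == "")) {
    stop("weights must be a non-empty named vector")
  }
  bad <- !is_whole(weights)
  if (any(bad)) {
    stop("non-integer weight for item '", names(weights)[which(bad)[1]],
         "': ", weights[which(bad)[1]])
  }
  if (anyDuplicated(names(weights))) stop("duplicate item in weights")
  stopifnot(inherits(scale, "level_scale"))
  w <- as.integer(round(weights))
  names(w) <- names(weights)
  structure(list(intercept = as.integer(round(intercept)), weights = w,
                 scale = scale, provenance = as.character(provenance)),
            class = "shortform_model")
}

#' @export
print.shortform_model <- function(x, ...) {
  cat(sprintf("<shortform_model: intercept %d, %d weighted items, score range [%d, %d]>\n",
              x$intercept, length(x$weights),
              max(0L, x$intercept + sum(pmin(x$weights, 0L))),
              min(x$scale$score_max, x$intercept + sum(pmax(x$weights, 0L)))))
  invisible(x)
}

#' Read / write a short-form model as JSON
#'
#' The JSON layout is `{"intercept", "weights": {"R2": 2, ...},
#' "scale": {"inadequate_max", "marginal_max", "score_max"}, "provenance"}`.
#' `load(save(m))` reproduces `m` field for field; non-integer weights in a
#' file are rejected.
#'
#' @param path path to a model JSON file.
#' @return [read_shortform_model()] returns a [shortform_model()];
#'   [write_shortform_model()] returns `path` invisibly.
#' @export
read_shortform_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(raw$intercept) || is.null(raw$weights)) {
    stop("model JSON must contain 'intercept' and 'weights': ", path)
  }
  weights <- unlist(raw$weights)
  sc <- raw$scale
  scale <- if (is.null(sc)) level_scale() else {
    level_scale(sc$inadequate_max, sc$marginal_max, sc$score_max)
  }
  shortform_model(raw$intercept, weights, scale = scale,
                  provenance = raw$provenance %||% "")
}

#' @rdname read_shortform_model
#' @param model a [shortform_model()].
#' @export
write_shortform_model <- function(model, path) {
  stopifnot(inherits(model, "shortform_model"))
  out <- list(intercept = model$intercept,
              weights = as.list(model$weights),
              scale = unclass(model$scale),
              provenance = model$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Check that a model's items exist in a bank
#' @param model a [shortform_model()].
#' @param bank an [item_bank()].
#' @return `TRUE`, invisibly; error if a weighted item is absent.
#' @export
validate_model_against_bank <- function(model, bank) {
  unknown <- setdiff(names(model$weights), bank$item_id)
  if (length(unknown) > 0) {
    stop("model weights refer to item(s) not in the bank: ",
         paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}
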