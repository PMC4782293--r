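#' Items: feature-value pairs
#'
#' An item is the atomic condition of an association rule: a feature together
#' with either a single categorical value or a half-open numeric interval
#' `[lo, hi)`. A condition such as "maximum BMI >= 35" is encoded as the
#' interval `[35, Inf)`; half-open intervals make any set of cutpoints a
#' partition of the real line, so exactly one bin item matches a non-missing
#' numeric value.
#'
#' @param feature Feature name (string).
#' @param value Categorical value (coerced to character).
#' @param lo,hi Interval bounds; `lo < hi`; `-Inf` / `Inf` allowed.
#' @return An object of class `rule_item`.
#' @examples
#' item_eq("smoker", "yes")
#' item_range("bmi_max", 35, Inf)
#' @export
item_eq <- function(feature, value) {
  stopifnot(is.character(feature), length(feature) == 1L, length(value) == 1L)
  structure(list(feature = feature, op = "eq", value = as.character(value),
                 lo = NULL, hi = NULL),
            class = "rule_item")
}

#' @rdname item_eq
#' @export
item_range <- function(feature, lo, hi) {
  stopifnot(is.character(feature), length(feature) == 1L,
            is.numeric(lo), is.numeric(hi), length(lo) == 1L, length(hi) == 1L)
  if (!(lo < hi)) stop("interval item requires lo < hi, got [", lo, ", ", hi, ")")
  structure(list(feature = feature, op = "in", value = NULL,
                 lo = as.numeric(lo), hi = as.numeric(hi)),
            class = "rule_item")
}

fmt_num <- function(x) {
  if (is.infinite(x)) return(if (x > 0) "Inf" else "-Inf")
  as.character(x)
}

#' Canonical display label of an interval
#'
#' @param lo,hi Interval bounds.
#' @return String such as `"[35,Inf)"` or `"(-Inf,25)"`.
#' @export
interval_label <- function(lo, hi) {
  left <- if (is.infinite(lo) && lo < 0) "(-Inf," else paste0("[", fmt_num(lo), ",")
  paste0(left, fmt_num(hi), ")")
}

#' Canonical label and key of an item
#'
#' The label is the categorical value or the interval label; the key prefixes
#' the feature name and is used wherever items are compared or looked up
#' (whitelists, intervention registries, diversified display).
#'
#' @param item A `rule_item`.
#' @return A string.
#' @export
item_label <- function(item) {
  if (item$op == "eq") item$value else interval_label(item$lo, item$hi)
}

#' @rdname item_label
#' @export
item_key <- function(item) paste0(item$feature, "=", item_label(item))

#' @export
print.rule_item <- function(x, ...) {
  cat("<item>", item_key(x), "\n")
  invisible(x)
}

#' Does an item match one patient row?
#'
#' A categorical item matches when the patient's value equals the item's
#' value; an interval item matches when the (numeric) value lies in
#' `[lo, hi)`. A missing value never matches: a rule cannot fire on an
#' unknown, so no explanation is fabricated from absent data.
#'
#' @param item A `rule_item` whose feature exists in the row.
#' @param patient A named list of feature values for one patient, e.g. an
#'   element of [patient_rows()].
#' @return `TRUE` or `FALSE`.
#' @export
item_matches <- function(item, patient) {
  if (!item$feature %in% names(patient)) {
    stop("feature '", item$feature, "' not present in patient row")
  }
  v <- patient[[item$feature]]
  if (length(v) != 1L || is.na(v)) return(FALSE)
  if (item$op == "eq") {
    as.character(v) == item$value
  } else {
    x <- as.numeric(v)
    x >= item$lo && x < item$hi
  }
}

#' Does a conjunction of items match a patient row?
#'
#' The antecedent of a rule is a conjunction: every item must match. An
#' antecedent has at least one item.
#'
#' @param items Non-empty list of `rule_item`s.
#' @inheritParams item_matches
#' @return `TRUE` or `FALSE`.
#' @export
antecedent_matches <- function(items, patient) {
  if (length(items) == 0L) {
    stop("an antecedent must contain at least one item")
  }
  for (it in items) if (!item_matches(it, patient)) return(FALSE)
  TRUE
}

## Logical match vector of an item over all rows of a feature table.
item_match_column <- function(item, table) {
  col <- table$data[[item$feature]]
  if (is.null(col)) stop("feature '", item$feature, "' not present in table")
  if (item$op == "eq") {
    !is.na(col) & as.character(col) == item$value
  } else {
    x <- suppressWarnings(as.numeric(col))
    !is.na(x) & x >= item$lo & x < item$hi
  }
}

## Canonical (feature, label) lexicographic order; radix sort keeps the
## ordering locale-independent and therefore reproducible.
sort_items <- function(items) {
  if (length(items) <= 1L) return(items)
  f <- vapply(items, function(i) i$feature, character(1))
  l <- vapply(items, item_label, character(1))
  items[order(f, l, method = "radix")]
}

antecedent_keys <- function(items) vapply(items, item_key, character(1))

antecedent_label <- function(items) paste(antecedent_keys(items), collapse = " & ")
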