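#' Value whitelist for clinically meaningful rule items
#'
#' Mirrors the curation step in which a clinician marks, per feature, which
#' values or value ranges may plausibly relate to the outcome of interest;
#' rules containing any other value are dropped. In `"closed"` mode a
#' feature absent from the list allows nothing; `"open"` mode disables the
#' filter entirely (useful for uncurated runs).
#'
#' @param allow Named list: feature name -> character vector of allowed
#'   value labels (for interval items, the interval label such as
#'   `"[35,Inf)"`, or use [item_label()]).
#' @param mode `"closed"` (default) or `"open"`.
#' @return An object of class `value_whitelist`.
#' @export
value_whitelist <- function(allow = list(), mode = c("closed", "open")) {
  mode <- match.arg(mode)
  stopifnot(is.list(allow))
  allow <- lapply(allow, as.character)
  structure(list(mode = mode, allow = allow), class = "value_whitelist")
}

#' @rdname value_whitelist
#' @export
open_whitelist <- function() value_whitelist(mode = "open")

whitelist_allows <- function(whitelist, item) {
  if (whitelist$mode == "open") return(TRUE)
  vals <- whitelist$allow[[item$feature]]
  !is.null(vals) && item_label(item) %in% vals
}

## Shared scaffolding for the two subset-based pruning stages. Rules are
## processed in increasing antecedent-size order and only retained rules can
## act as pruning witnesses: this guarantees that every patient covered by a
## removed rule is still covered by a surviving, more general rule with the
## same consequent (the reason the pruning is safe for giving explanations).
prune_by_witness <- function(ruleset, removes) {
  rules <- ruleset$rules
  nr <- length(rules)
  if (nr == 0L) return(ruleset)
  keys <- lapply(rules, function(r) antecedent_keys(r$antecedent))
  sizes <- lengths(keys)
  conf <- vapply(rules, function(r) r$confidence, numeric(1))
  cons <- vapply(rules, function(r) r$consequent, character(1))
  ord <- order(sizes, method = "radix")
  kept <- logical(nr)
  retained <- integer(0)
  for (i in ord) {
    removed <- FALSE
    for (w in retained) {
      if (cons[w] == cons[i] && sizes[w] < sizes[i] &&
          all(keys[[w]] %in% keys[[i]]) &&
          removes(conf[w], conf[i])) {
        removed <- TRUE
        break
      }
    }
    if (!removed) {
      kept[i] <- TRUE
      retained <- c(retained, i)
    }
  }
  ruleset$rules <- rules[kept]
  ruleset
}

#' Redundancy pruning: drop more specific, lower-confidence rules
#'
#' A rule is removed when a retained rule with the same consequent has a
#' proper subset of its antecedent and strictly higher confidence: the more
#' general rule explains every patient the specific one covers, and does so
#' with higher confidence. With `remove_equal_confidence = TRUE` a more
#' specific rule of *equal* confidence is also removed; the default keeps
#' the strict reading.
#'
#' @param ruleset A `ruleset` with computed confidences.
#' @param remove_equal_confidence Also remove equal-confidence
#'   specializations (default `FALSE`).
#' @return The pruned `ruleset`, with a `"redundancy"` provenance record.
#' @export
prune_redundant <- function(ruleset, remove_equal_confidence = FALSE) {
  removes <- if (remove_equal_confidence) {
    function(cw, cr) cw >= cr
  } else {
    function(cw, cr) cw > cr
  }
  add_stage(prune_by_witness(ruleset, removes), "redundancy")
}

#' Confidence-difference pruning: drop barely better specializations
#'
#' The complement of [prune_redundant()] for the explanation setting: a more
#' specific rule whose confidence exceeds a retained, more general
#' same-consequent rule's by no more than `delta` is removed, because the
#' general rule explains every patient the specific rule covers while losing
#' at most `delta` of confidence. Requires strictly
#' `conf(general) < conf(specific) <= conf(general) + delta`; the
#' strictly-lower case is already handled by redundancy pruning, so this
#' stage expects redundancy-pruned input (at `delta = 0` it is the
#' identity on such input).
#'
#' @param ruleset A redundancy-pruned `ruleset`.
#' @param delta Confidence-difference threshold, >= 0.
#' @return The pruned `ruleset`, with a `"confidence_diff"` provenance record.
#' @export
prune_confidence_diff <- function(ruleset, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0) {
    stop("delta must be a single number >= 0")
  }
  removes <- function(cw, cr) cw < cr && cr <= cw + delta
  add_stage(prune_by_witness(ruleset, removes), "confidence_diff")
}

#' Keep only rules whose every item is whitelisted
#'
#' @param ruleset A `ruleset`.
#' @param whitelist A [value_whitelist()].
#' @return The filtered `ruleset`, with a `"whitelist"` provenance record.
#' @export
filter_whitelist <- function(ruleset, whitelist) {
  stopifnot(inherits(whitelist, "value_whitelist"))
  keep <- vapply(ruleset$rules, function(r) {
    all(vapply(r$antecedent, function(it) whitelist_allows(whitelist, it),
               logical(1)))
  }, logical(1))
  ruleset$rules <- ruleset$rules[keep]
  add_stage(ruleset, "whitelist")
}

#' The full three-stage pruning cascade
#'
#' Applies, in order: redundancy pruning, confidence-difference pruning at
#' `config$delta`, and the value whitelist. Each stage appends its rule
#' count to the ruleset's provenance, giving the familiar
#' mined -> redundancy -> confidence-difference -> whitelist count trail.
#'
#' @param ruleset A mined `ruleset`.
#' @param whitelist A [value_whitelist()].
#' @param config A [mining_config()] (supplies `delta`).
#' @return The pruned `ruleset` with four provenance records.
#' @export
prune_pipeline <- function(ruleset, whitelist = open_whitelist(),
                           config = mining_config()) {
  if (!nrow(ruleset$provenance)) ruleset <- add_stage(ruleset, "mined")
  ruleset <- prune_redundant(ruleset)
  ruleset <- prune_confidence_diff(ruleset, config$delta)
  filter_whitelist(ruleset, whitelist)
}
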