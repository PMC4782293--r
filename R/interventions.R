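#' Intervention registry
#'
#' Maps single items (feature-value pairs) to intervention texts and,
#' optionally, to a weighted category. An item with at least one registered
#' intervention is an *actionable item*; a rule carrying at least one
#' intervention is an *actionable rule*. Categories and their positive
#' weights drive the weighted diversified-display algorithm, where a larger
#' weight reflects higher clinical importance.
#'
#' @param entries List of [registry_entry()] objects.
#' @param weights Named numeric vector of strictly positive category weights.
#' @return An object of class `intervention_registry`.
#' @export
intervention_registry <- function(entries = list(), weights = numeric(0)) {
  if (length(weights) && (is.null(names(weights)) || any(weights <= 0))) {
    stop("category weights must be named and strictly positive")
  }
  ents <- list()
  for (e in entries) {
    stopifnot(inherits(e, "registry_entry"))
    key <- item_key(e$item)
    if (!is.null(ents[[key]])) stop("duplicate registry entry for item ", key)
    ents[[key]] <- e
  }
  structure(list(entries = ents, weights = weights),
            class = "intervention_registry")
}

#' @rdname intervention_registry
#' @param item A `rule_item` the entry refers to.
#' @param interventions Character vector of intervention texts (may be empty).
#' @param category Optional category name.
#' @export
registry_entry <- function(item, interventions = character(0),
                           category = NA_character_) {
  stopifnot(inherits(item, "rule_item"))
  structure(list(item = item, interventions = as.character(interventions),
                 category = category),
            class = "registry_entry")
}

registry_lookup <- function(registry, item) registry$entries[[item_key(item)]]

item_is_actionable <- function(registry, item) {
  e <- registry_lookup(registry, item)
  !is.null(e) && length(e$interventions) > 0L
}

#' Suggest interventions for a rule
#'
#' The widget logic: for each antecedent item (in canonical order), list
#' every registered intervention for that item. A designer would then accept
#' or reject these; [annotate_ruleset()] accepts all by default.
#'
#' @param rule A `rule`.
#' @param registry An [intervention_registry()].
#' @return `data.frame` with columns `item` (item key) and `intervention`;
#'   zero rows when no antecedent item is registered.
#' @export
suggest_interventions <- function(rule, registry) {
  out_item <- character(0)
  out_text <- character(0)
  for (it in rule$antecedent) {
    e <- registry_lookup(registry, it)
    if (!is.null(e) && length(e$interventions)) {
      out_item <- c(out_item, rep(item_key(it), length(e$interventions)))
      out_text <- c(out_text, e$interventions)
    }
  }
  data.frame(item = out_item, intervention = out_text,
             stringsAsFactors = FALSE)
}

#' Annotate a ruleset with interventions and actionability
#'
#' Attaches to every rule its interventions (by default, all widget
#' suggestions; optionally overridden per rule), the set of actionable
#' antecedent items, and the actionable flag, which is true exactly when
#' the rule has at least one intervention. Support, confidence and the rule
#' list itself are never altered.
#'
#' @param ruleset A `ruleset`.
#' @param registry An [intervention_registry()].
#' @param accepted Optional named list: rule id (as printed by the rule,
#'   `"item & item => v"`) -> character vector of accepted interventions,
#'   overriding the default acceptance for those rules. Unknown rule ids are
#'   an error.
#' @return The annotated `ruleset`.
#' @export
annotate_ruleset <- function(ruleset, registry, accepted = NULL) {
  ids <- vapply(ruleset$rules, rule_id, character(1))
  if (!is.null(accepted)) {
    unknown <- setdiff(names(accepted), ids)
    if (length(unknown)) stop("accepted selection for unknown rule: ", unknown[1L])
  }
  ruleset$rules <- lapply(seq_along(ruleset$rules), function(i) {
    r <- ruleset$rules[[i]]
    texts <- if (!is.null(accepted) && ids[i] %in% names(accepted)) {
      as.character(accepted[[ids[i]]])
    } else {
      unique(suggest_interventions(r, registry)$intervention)
    }
    r$interventions <- texts
    r$actionable <- length(texts) > 0L
    act <- vapply(r$antecedent, function(it) item_is_actionable(registry, it),
                  logical(1))
    r$actionable_items <- antecedent_keys(r$antecedent)[act]
    r
  })
  ruleset
}

#' Weight of a rule for weighted diversified display
#'
#' Sum, over the rule's actionable antecedent items, of the weight of the
#' item's category — with items in `zeroed_items` contributing zero (they
#' have already been covered by previously selected rules). An actionable
#' item without a category (or without a weight for its category) is an
#' error, since weighted selection is then ill-defined.
#'
#' @param rule A `rule`.
#' @param registry An [intervention_registry()] with category weights.
#' @param zeroed_items Character vector of item keys whose weight is zeroed.
#' @return A non-negative number.
#' @export
rule_weight <- function(rule, registry, zeroed_items = character(0)) {
  total <- 0
  for (it in rule$antecedent) {
    if (!item_is_actionable(registry, it)) next
    key <- item_key(it)
    if (key %in% zeroed_items) next
    e <- registry_lookup(registry, it)
    if (is.na(e$category) || !e$category %in% names(registry$weights)) {
      stop("actionable item ", key, " has no weighted category")
    }
    total <- total + registry$weights[[e$category]]
  }
  total
}
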