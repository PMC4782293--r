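#' Display configuration
#'
#' @param n_r Maximum number of rules shown per patient (default 3).
#' @param show_nonactionable Fill remaining display slots with
#'   non-actionable rules (default `TRUE`); set `FALSE` to omit them.
#' @param method Diversified selection algorithm: `"greedy_disjoint"`
#'   (default) or `"weighted"` (requires a categorized, weighted registry).
#' @return An object of class `display_config`.
#' @export
display_config <- function(n_r = 3L, show_nonactionable = TRUE,
                           method = c("greedy_disjoint", "weighted")) {
  if (!(n_r >= 1)) stop("n_r must be >= 1")
  structure(list(n_r = as.integer(n_r),
                 show_nonactionable = isTRUE(show_nonactionable),
                 method = match.arg(method)),
            class = "display_config")
}

#' Rules applicable to one patient
#'
#' All rules whose antecedent the patient satisfies, in display order
#' (see [sort_rules()]).
#'
#' @param ruleset A `ruleset` over the same (discretized) feature space as
#'   the patient row.
#' @param patient A named list of feature values (see [patient_rows()]).
#' @return List of matching rules, sorted.
#' @export
applicable_rules <- function(ruleset, patient) {
  hits <- Filter(function(r) antecedent_matches(r$antecedent, patient),
                 ruleset$rules)
  sort_rules(hits)
}

#' Display order of rules
#'
#' Actionable rules above non-actionable ones; within each block descending
#' confidence, with ties broken by larger support and then by canonical
#' antecedent label, so the order is fully deterministic.
#'
#' @param rules List of annotated rules.
#' @return The same rules, re-ordered.
#' @export
sort_rules <- function(rules) {
  if (length(rules) <= 1L) return(rules)
  act <- vapply(rules, function(r) r$actionable, logical(1))
  conf <- vapply(rules, function(r) r$confidence, numeric(1))
  supp <- vapply(rules, function(r) r$support, numeric(1))
  lab <- vapply(rules, function(r) antecedent_label(r$antecedent), character(1))
  rules[order(!act, -conf, -supp, lab, method = "radix")]
}

## One greedy disjoint pass plus the wrap-around pass of the display
## algorithm. `item_sets` gives, per rule, the item keys that must not
## overlap previously used ones; `used` carries keys already covered by
## earlier selections. Returns indices into `rules` plus the updated keys.
greedy_disjoint_pick <- function(item_sets, k, used = character(0)) {
  chosen <- integer(0)
  for (i in seq_along(item_sets)) {
    if (length(chosen) >= k) break
    if (!any(item_sets[[i]] %in% used)) {
      chosen <- c(chosen, i)
      used <- c(used, item_sets[[i]])
    }
  }
  if (length(chosen) < k) {           # wrap-around: earliest unchosen first
    for (i in seq_along(item_sets)) {
      if (length(chosen) >= k) break
      if (!i %in% chosen) {
        chosen <- c(chosen, i)
        used <- c(used, item_sets[[i]])
      }
    }
  }
  list(chosen = chosen, used = used)
}

#' Greedy-disjoint diversified selection of displayed rules
#'
#' If no more than `n_r` actionable rules apply, all of them are shown.
#' Otherwise the top-ranked actionable rule is selected, the rest of the
#' list is scanned and a rule is selected when none of its actionable items
#' appears in a previously selected rule; if fewer than `n_r` rules are
#' selected at the end of the list, a second pass takes the earliest
#' unchosen rules until `n_r` are reached. Remaining display slots are then
#' filled with non-actionable rules by the same procedure (when
#' `show_nonactionable`), with disjointness there judged over all items
#' against everything already selected.
#'
#' @param sorted_rules Rules in [sort_rules()] order.
#' @param config A [display_config()].
#' @return List of at most `n_r` rules, a subset of `sorted_rules` in
#'   selection order.
#' @export
select_diverse <- function(sorted_rules, config = display_config()) {
  n_r <- config$n_r
  act <- Filter(function(r) r$actionable, sorted_rules)
  nonact <- Filter(function(r) !r$actionable, sorted_rules)
  if (length(act) <= n_r) {
    sel <- act
    used <- unlist(lapply(act, function(r) antecedent_keys(r$antecedent)))
  } else {
    sets <- lapply(act, function(r) r$actionable_items)
    pick <- greedy_disjoint_pick(sets, n_r)
    sel <- act[pick$chosen]
    used <- unlist(lapply(sel, function(r) antecedent_keys(r$antecedent)))
  }
  if (length(sel) < n_r && config$show_nonactionable && length(nonact)) {
    sets <- lapply(nonact, function(r) antecedent_keys(r$antecedent))
    pick <- greedy_disjoint_pick(sets, n_r - length(sel), used = used)
    sel <- c(sel, nonact[pick$chosen])
  }
  sel
}

#' Weighted diversified selection of displayed rules
#'
#' The alternative display algorithm: each actionable item carries the
#' weight of its category; a rule's weight is the sum of its actionable
#' items' weights. The actionable list is scanned `n_r` times; each pass
#' selects the first-encountered unchosen rule of maximal weight, then
#' zeroes the weights of its actionable items before the next pass, so
#' later passes favour rules covering not-yet-shown items. If fewer than
#' `n_r` actionable rules exist, all are selected and (when
#' `show_nonactionable`) remaining slots are filled as in
#' [select_diverse()].
#'
#' @param sorted_rules Rules in [sort_rules()] order.
#' @param registry An [intervention_registry()] with category weights for
#'   every actionable item (an uncategorized actionable item is an error).
#' @param config A [display_config()].
#' @return List of at most `n_r` rules in selection order.
#' @export
select_weighted <- function(sorted_rules, registry,
                            config = display_config()) {
  n_r <- config$n_r
  act <- Filter(function(r) r$actionable, sorted_rules)
  nonact <- Filter(function(r) !r$actionable, sorted_rules)
  if (length(act) <= n_r) {
    sel <- act
  } else {
    zeroed <- character(0)
    chosen <- integer(0)
    for (round in seq_len(n_r)) {
      w <- vapply(seq_along(act), function(i) {
        if (i %in% chosen) -Inf else rule_weight(act[[i]], registry, zeroed)
      }, numeric(1))
      pick <- which.max(w)              # first-encountered maximum
      chosen <- c(chosen, pick)
      zeroed <- union(zeroed, act[[pick]]$actionable_items)
    }
    sel <- act[chosen]
  }
  if (length(sel) < n_r && config$show_nonactionable && length(nonact)) {
    used <- unlist(lapply(sel, function(r) antecedent_keys(r$antecedent)))
    sets <- lapply(nonact, function(r) antecedent_keys(r$antecedent))
    pick <- greedy_disjoint_pick(sets, n_r - length(sel), used = used)
    sel <- c(sel, nonact[pick$chosen])
  }
  sel
}

new_explanation <- function(patient_id, predicted, applicable, displayed,
                            identified_items) {
  structure(list(patient_id = patient_id,
                 predicted_positive = predicted,
                 explained = predicted && length(applicable) > 0L,
                 applicable = applicable,
                 displayed = displayed,
                 n_applicable = length(applicable),
                 n_actionable_applicable =
                   sum(vapply(applicable, function(r) r$actionable, logical(1))),
                 identified_items = identified_items),
            class = "explanation")
}

#' @export
print.explanation <- function(x, ...) {
  cat(sprintf("<explanation> patient %s: %s, %d applicable (%d actionable), %d displayed\n",
              x$patient_id,
              if (!x$predicted_positive) "not predicted positive"
              else if (x$explained) "explained" else "no applicable rule",
              x$n_applicable, x$n_actionable_applicable, length(x$displayed)))
  for (r in x$displayed) print(r)
  invisible(x)
}

#' Explain one patient's prediction
#'
#' For a patient predicted to have an interesting outcome value, finds all
#' applicable rules, orders them, and selects at most `n_r` for display by
#' the configured algorithm; each displayed rule carries its confidence and
#' interventions. Patients not predicted positive need no explanation and
#' get an empty one. The identified actionable items — the distinct
#' actionable items across *all* applicable rules, not just the displayed
#' ones — are recorded for the evaluation metrics.
#'
#' @param patient A named list of feature values (see [patient_rows()]),
#'   in the same discretized feature space as the rules.
#' @param patient_id Identifier stored in the explanation.
#' @param predicted Logical: did the black-box model predict an interesting
#'   value for this patient?
#' @param ruleset An annotated, pruned `ruleset`.
#' @param config A [display_config()].
#' @param registry Registry, required for `method = "weighted"`.
#' @return An `explanation` object.
#' @export
explain_patient <- function(patient, patient_id, predicted, ruleset,
                            config = display_config(), registry = NULL) {
  if (!isTRUE(predicted)) {
    return(new_explanation(patient_id, FALSE, list(), list(), character(0)))
  }
  app <- applicable_rules(ruleset, patient)
  displayed <- if (config$method == "weighted") {
    if (is.null(registry)) stop("weighted selection requires a registry")
    select_weighted(app, registry, config)
  } else {
    select_diverse(app, config)
  }
  ident <- unique(unlist(lapply(app, function(r) r$actionable_items)))
  if (is.null(ident)) ident <- character(0)
  new_explanation(patient_id, TRUE, app, displayed, ident)
}

#' Explain every patient of a table
#'
#' @param table A (discretized) [feature_table()].
#' @param predicted Logical vector aligned with the table's patients.
#' @inheritParams explain_patient
#' @return List of `explanation` objects, named by patient id.
#' @export
explain_cohort <- function(table, predicted, ruleset,
                           config = display_config(), registry = NULL) {
  stopifnot(length(predicted) == n_patients(table))
  rows <- patient_rows(table)
  out <- lapply(seq_along(rows), function(i) {
    explain_patient(rows[[i]], table$ids[i], predicted[i], ruleset,
                    config, registry)
  })
  names(out) <- table$ids
  out
}
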