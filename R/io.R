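#' File I/O for pipeline artifacts
#'
#' Plain-text serialization of every intermediate: feature tables as CSV
#' with a YAML/JSON schema sidecar, predictions as CSV, rulesets, binning
#' maps, whitelists, registries and explanations as JSON. All round-trip
#' losslessly: `read(write(x))` reproduces `x`.
#'
#' @name ruleexplain-io
NULL

num_out <- function(x) if (is.finite(x)) x else as.character(x)   # Inf-safe
num_in <- function(x) as.numeric(x)

item_to_list <- function(item) {
  if (item$op == "eq") {
    list(feature = item$feature, op = "eq", value = item$value)
  } else {
    list(feature = item$feature, op = "in",
         interval = list(lo = num_out(item$lo), hi = num_out(item$hi)))
  }
}

item_from_list <- function(x) {
  if (x$op == "eq") item_eq(x$feature, x$value)
  else item_range(x$feature, num_in(x$interval$lo), num_in(x$interval$hi))
}

#' @rdname ruleexplain-io
#' @param ruleset A `ruleset`.
#' @param path Output file path.
#' @export
write_rules <- function(ruleset, path) {
  obj <- list(
    rules = lapply(ruleset$rules, function(r) {
      list(antecedent = lapply(r$antecedent, item_to_list),
           consequent = r$consequent,
           support = r$support, confidence = r$confidence,
           actionable = r$actionable,
           interventions = as.list(r$interventions),
           actionable_items = as.list(r$actionable_items))
    }),
    provenance = lapply(seq_len(nrow(ruleset$provenance)), function(i) {
      list(stage = ruleset$provenance$stage[i],
           count = ruleset$provenance$count[i])
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname ruleexplain-io
#' @export
read_rules <- function(path) {
  obj <- jsonlite::read_json(path)
  rules <- lapply(obj$rules, function(x) {
    r <- new_rule(lapply(x$antecedent, item_from_list), x$consequent,
                  as.numeric(x$support), as.numeric(x$confidence))
    r$actionable <- isTRUE(x$actionable)
    r$interventions <- as.character(unlist(x$interventions))
    r$actionable_items <- as.character(unlist(x$actionable_items))
    r
  })
  prov <- data.frame(
    stage = vapply(obj$provenance, function(p) p$stage, character(1)),
    count = vapply(obj$provenance, function(p) as.integer(p$count), integer(1)),
    stringsAsFactors = FALSE)
  new_ruleset(rules, prov)
}

#' @rdname ruleexplain-io
#' @param bins A `binning_map`.
#' @export
write_binning <- function(bins, path) {
  obj <- lapply(unclass(bins), as.list)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname ruleexplain-io
#' @export
read_binning <- function(path) {
  obj <- jsonlite::read_json(path)
  structure(lapply(obj, function(x) as.numeric(unlist(x))),
            class = "binning_map")
}

#' @rdname ruleexplain-io
#' @param whitelist A [value_whitelist()].
#' @export
write_whitelist <- function(whitelist, path) {
  jsonlite::write_json(list(mode = whitelist$mode,
                            allow = lapply(whitelist$allow, as.list)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname ruleexplain-io
#' @export
read_whitelist <- function(path) {
  obj <- jsonlite::read_json(path)
  value_whitelist(lapply(obj$allow, function(x) as.character(unlist(x))),
                  mode = obj$mode)
}

#' @rdname ruleexplain-io
#' @param registry An [intervention_registry()].
#' @export
write_registry <- function(registry, path) {
  obj <- list(
    entries = lapply(unname(registry$entries), function(e) {
      list(item = item_to_list(e$item),
           interventions = as.list(e$interventions),
           category = if (is.na(e$category)) NULL else e$category)
    }),
    weights = as.list(registry$weights))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname ruleexplain-io
#' @export
read_registry <- function(path) {
  obj <- jsonlite::read_json(path)
  entries <- lapply(obj$entries, function(e) {
    registry_entry(item_from_list(e$item),
                   as.character(unlist(e$interventions)),
                   if (is.null(e$category)) NA_character_ else e$category)
  })
  w <- unlist(obj$weights)
  intervention_registry(entries, if (is.null(w)) numeric(0) else w)
}

#' @rdname ruleexplain-io
#' @param predictions `data.frame` with columns `patient_id`, `probability`.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(all(c("patient_id", "probability") %in% names(predictions)))
  utils::write.csv(predictions[c("patient_id", "probability")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname ruleexplain-io
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "numeric"))
  stopifnot(all(c("patient_id", "probability") %in% names(df)))
  if (any(df$probability < 0 | df$probability > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]")
  }
  df
}

#' @rdname ruleexplain-io
#' @param table A [feature_table()].
#' @export
write_feature_table <- function(table, path) {
  df <- cbind(data.frame(patient_id = table$ids, stringsAsFactors = FALSE),
              table$data)
  df[[table$outcome_spec$name]] <- table$outcome
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname ruleexplain-io
#' @export
write_table_schema <- function(table, path) {
  schema <- list(
    features = lapply(unname(table$features), function(f) {
      s <- list(name = f$name, kind = f$kind)
      if (!is.null(f$levels)) s$levels <- as.list(f$levels)
      s
    }),
    outcome = list(name = table$outcome_spec$name,
                   levels = as.list(table$outcome_spec$levels),
                   interesting = as.list(table$outcome_spec$interesting)))
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(schema, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(schema, path)
  }
  invisible(path)
}

#' @rdname ruleexplain-io
#' @param explanations List of `explanation`s.
#' @export
write_explanations <- function(explanations, path) {
  lines <- vapply(explanations, function(e) {
    jsonlite::toJSON(list(
      patient_id = e$patient_id,
      predicted_positive = e$predicted_positive,
      explained = e$explained,
      n_applicable = e$n_applicable,
      n_actionable_applicable = e$n_actionable_applicable,
      identified_items = as.list(e$identified_items),
      displayed = lapply(e$displayed, function(r) {
        list(antecedent = lapply(r$antecedent, item_to_list),
             consequent = r$consequent,
             confidence = r$confidence,
             interventions = as.list(r$interventions))
      })), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
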