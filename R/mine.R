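#' Mining configuration
#'
#' Thresholds for class association rule mining and the downstream pruning
#' and display steps. Defaults follow common associative-classifier
#' practice: minimum support 1 %, minimum confidence 50 %, at most four
#' items per antecedent (long rules are hard to comprehend and act on),
#' confidence-difference threshold 0.1, and up to three displayed rules.
#'
#' @param min_support Minimum support, in (0, 1].
#' @param min_confidence Minimum confidence, in (0, 1].
#' @param max_len Maximum antecedent size, >= 1.
#' @param model_features Names of the features the black-box model uses;
#'   only these may appear in rule antecedents. `NULL` means all features.
#' @param delta Confidence-difference pruning threshold, >= 0.
#' @param n_r Maximum number of rules displayed per patient, >= 1.
#' @return An object of class `mining_config`.
#' @export
mining_config <- function(min_support = 0.01, min_confidence = 0.5,
                          max_len = 4L, model_features = NULL,
                          delta = 0.1, n_r = 3L) {
  if (!(min_support > 0 && min_support <= 1)) stop("min_support must be in (0, 1]")
  if (!(min_confidence > 0 && min_confidence <= 1)) stop("min_confidence must be in (0, 1]")
  if (!(max_len >= 1)) stop("max_len must be >= 1")
  if (!(delta >= 0)) stop("delta must be >= 0")
  if (!(n_r >= 1)) stop("n_r must be >= 1")
  structure(list(min_support = min_support, min_confidence = min_confidence,
                 max_len = as.integer(max_len), model_features = model_features,
                 delta = delta, n_r = as.integer(n_r)),
            class = "mining_config")
}

new_rule <- function(antecedent, consequent, support, confidence) {
  structure(list(antecedent = sort_items(antecedent),
                 consequent = consequent,
                 support = support, confidence = confidence,
                 actionable = FALSE,
                 interventions = character(0),
                 actionable_items = character(0)),
            class = "rule")
}

#' @export
print.rule <- function(x, ...) {
  cat(sprintf("%s => %s  (supp %.4f, conf %.4f%s)\n",
              antecedent_label(x$antecedent), x$consequent,
              x$support, x$confidence,
              if (x$actionable) ", actionable" else ""))
  invisible(x)
}

rule_id <- function(rule) {
  paste0(antecedent_label(rule$antecedent), " => ", rule$consequent)
}

new_ruleset <- function(rules, provenance = NULL) {
  if (is.null(provenance)) {
    provenance <- data.frame(stage = character(0), count = integer(0),
                             stringsAsFactors = FALSE)
  }
  structure(list(rules = rules, provenance = provenance), class = "ruleset")
}

add_stage <- function(ruleset, stage) {
  ruleset$provenance <- rbind(
    ruleset$provenance,
    data.frame(stage = stage, count = length(ruleset$rules),
               stringsAsFactors = FALSE))
  ruleset
}

#' @export
print.ruleset <- function(x, ...) {
  cat(sprintf("<ruleset> %d rules\n", length(x$rules)))
  if (nrow(x$provenance)) {
    cat(paste(sprintf("  %s: %d", x$provenance$stage, x$provenance$count),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
length.ruleset <- function(x) length(x$rules)

#' Support and confidence of one candidate rule
#'
#' Support is the fraction of all patients that satisfy the antecedent and
#' have outcome `v` (joint proportion over the whole cohort); confidence is
#' the same numerator divided by the number of patients satisfying the
#' antecedent (conditional proportion). When no patient matches the
#' antecedent the confidence is undefined and returned as `NA` (never 0).
#'
#' @param antecedent Non-empty list of `rule_item`s.
#' @param v Outcome value.
#' @param table A [feature_table()].
#' @return List with `support`, `confidence`, `n_match`, `n_joint`.
#' @export
count_support_confidence <- function(antecedent, v, table) {
  stopifnot(length(antecedent) >= 1L, n_patients(table) >= 1L)
  match <- Reduce(`&`, lapply(antecedent, item_match_column, table = table))
  n <- n_patients(table)
  n_match <- sum(match)
  n_joint <- sum(match & table$outcome == v)
  list(support = n_joint / n,
       confidence = if (n_match == 0L) NA_real_ else n_joint / n_match,
       n_match = n_match, n_joint = n_joint)
}

#' Mine all class association rules for the interesting outcome values
#'
#' Exhaustive level-wise (Apriori-style) search over antecedents built from
#' the black-box model's features, one item per feature, up to
#' `config$max_len` items. A candidate antecedent is extended only while its
#' joint support with the consequent stays at or above `min_support`
#' (anti-monotone pruning, which cannot lose any rule that meets the support
#' threshold); the confidence threshold is applied after counting, since
#' confidence is not anti-monotone. Rules are emitted only for the
#' interesting outcome values: the classifier explains, it never predicts,
#' so rules for the uninteresting values would serve no purpose.
#'
#' Output order is deterministic: items are ordered lexicographically by
#' (feature, value label) and antecedents are generated in that order,
#' level by level.
#'
#' @param table A fully categorical [feature_table()] (run [apply_binning()]
#'   first if continuous features remain among the model features).
#' @param config A [mining_config()].
#' @param outcome An [outcome_spec()]; defaults to the table's.
#' @return A `ruleset` with a `"mined"` provenance record.
#' @export
mine_rules <- function(table, config = mining_config(), outcome = NULL) {
  if (is.null(outcome)) outcome <- table$outcome_spec
  feats <- config$model_features
  if (is.null(feats)) feats <- names(table$features)
  missing <- setdiff(feats, names(table$features))
  if (length(missing)) stop("model feature not in table: ", missing[1L])
  cont <- feats[vapply(table$features[feats], function(f)
    f$kind == "continuous", logical(1))]
  if (length(cont)) {
    stop("continuous feature '", cont[1L],
         "' must be discretized with apply_binning() before mining")
  }
  feats <- sort(feats, method = "radix")
  n <- n_patients(table)

  ## item universe in canonical order
  items <- list()
  for (fi in seq_along(feats)) {
    f <- feats[fi]
    for (lv in sort(table$features[[f]]$levels, method = "radix")) {
      items[[length(items) + 1L]] <- list(
        fidx = fi, feature = f, label = lv,
        match = !is.na(table$data[[f]]) & table$data[[f]] == lv)
    }
  }

  min_count <- config$min_support * n - 1e-9
  rules <- list()
  for (v in outcome$interesting) {
    yv <- table$outcome == v
    emit <- function(ids, idx_match, joint) {
      conf <- joint / length(idx_match)
      if (conf >= config$min_confidence - 1e-12) {
        ante <- lapply(items[ids], function(it) item_eq(it$feature, it$label))
        rules[[length(rules) + 1L]] <<-
          new_rule(ante, v, joint / n, conf)
      }
    }
    frontier <- list()
    for (i in seq_along(items)) {
      idx <- which(items[[i]]$match)
      joint <- sum(yv[idx])
      if (joint >= min_count) {
        emit(i, idx, joint)
        frontier[[length(frontier) + 1L]] <- list(ids = i, idx = idx)
      }
    }
    len <- 1L
    while (len < config$max_len && length(frontier) > 0L) {
      nxt <- list()
      for (cand in frontier) {
        last_f <- items[[cand$ids[length(cand$ids)]]]$fidx
        for (i in seq_along(items)) {
          if (items[[i]]$fidx <= last_f) next
          idx <- cand$idx[items[[i]]$match[cand$idx]]
          joint <- sum(yv[idx])
          if (joint >= min_count) {
            ids <- c(cand$ids, i)
            emit(ids, idx, joint)
            nxt[[length(nxt) + 1L]] <- list(ids = ids, idx = idx)
          }
        }
      }
      frontier <- nxt
      len <- len + 1L
    }
  }
  add_stage(new_ruleset(rules), "mined")
}
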