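#' Run the full explanation pipeline
#'
#' End-to-end composition of the method: split the cohort, discretize the
#' continuous model features on the training set, mine class association
#' rules on the (binned) training set, prune them in three stages, annotate
#' them with interventions, pick the probability cutoff by Youden's index on
#' the training predictions, and explain and evaluate the test set.
#'
#' @param table A [feature_table()].
#' @param predictions `data.frame` with `patient_id` and `probability`,
#'   covering every patient of `table` (the external black-box model's
#'   output).
#' @param config A [mining_config()].
#' @param display A [display_config()].
#' @param whitelist A [value_whitelist()].
#' @param registry An [intervention_registry()].
#' @param train_fraction Training proportion (default 0.8).
#' @param seed Seed for the split.
#' @return List of class `pipeline_result` with the binning map, pruned
#'   annotated ruleset, cutoff, test-set explanations,
#'   `classification_metrics`, `explanation_metrics`, and the split ids.
#' @export
run_pipeline <- function(table, predictions,
                         config = mining_config(),
                         display = display_config(),
                         whitelist = open_whitelist(),
                         registry = intervention_registry(),
                         train_fraction = 0.8, seed = 1L) {
  prob <- predictions$probability[match(table$ids, predictions$patient_id)]
  if (anyNA(prob)) {
    stop("predictions missing for patient ",
         table$ids[which(is.na(prob))[1L]])
  }

  split <- split_train_test(table, train_fraction, seed)
  train <- split$train
  test <- split$test
  p_train <- prob[match(train$ids, table$ids)]
  p_test <- prob[match(test$ids, table$ids)]

  feats <- config$model_features
  if (is.null(feats)) feats <- names(table$features)
  cont <- feats[vapply(table$features[feats], function(f)
    f$kind == "continuous", logical(1))]
  bins <- build_binning(train, cont)
  train_b <- apply_binning(train, bins)
  test_b <- apply_binning(test, bins)

  rules <- mine_rules(train_b, config)
  rules <- prune_pipeline(rules, whitelist, config)
  rules <- annotate_ruleset(rules, registry)

  y_train <- train$outcome %in% train$outcome_spec$interesting
  y_test <- test$outcome %in% test$outcome_spec$interesting
  cutoff <- youden_cutoff(p_train, y_train)
  pred_test <- p_test >= cutoff

  explanations <- explain_cohort(test_b, pred_test, rules, display, registry)
  cls <- classification_metrics(p_test, y_test, cutoff)
  cov <- explanation_coverage(explanations, y_test, pred_test,
                              ruleset = rules, table = test_b)

  structure(list(bins = bins, rules = rules, cutoff = cutoff,
                 explanations = explanations,
                 classification = cls, coverage = cov,
                 train_ids = train$ids, test_ids = test$ids),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$rules)
  print(x$classification)
  print(x$coverage)
  invisible(x)
}
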