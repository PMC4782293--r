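#' Youden-index probability cutoff
#'
#' Selects the cutoff maximizing Youden's J = sensitivity + specificity - 1
#' (equivalently, the sum of sensitivity and specificity). Candidate
#' thresholds are the midpoints between adjacent distinct sorted
#' probabilities plus -Inf/+Inf sentinels; a patient is classified positive
#' when probability >= cutoff. Ties in the maximum resolve to the smallest
#' such cutoff, which favours sensitivity.
#'
#' @param probabilities Numeric vector of predicted probabilities.
#' @param labels Binary vector (0/1 or logical); both classes must be present.
#' @return The selected cutoff.
#' @export
youden_cutoff <- function(probabilities, labels) {
  y <- as.integer(as.logical(labels))
  stopifnot(length(probabilities) == length(y))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  sp <- sort(unique(probabilities))
  cands <- c(-Inf, if (length(sp) > 1L)
    (sp[-length(sp)] + sp[-1L]) / 2, Inf)
  npos <- sum(y == 1L)
  nneg <- sum(y == 0L)
  best_j <- -Inf
  best_c <- cands[1L]
  for (ct in cands) {        # ascending: numeric ties keep the smallest cutoff
    pred <- probabilities >= ct
    j <- sum(pred & y == 1L) / npos + sum(!pred & y == 0L) / nneg - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_c <- ct
    }
  }
  best_c
}

#' Classification metrics at a probability cutoff
#'
#' Confusion-matrix metrics with the rule "positive iff probability >=
#' cutoff", plus the AUROC computed exactly as the Mann-Whitney U statistic
#' scaled by n_pos * n_neg, with half credit for tied probabilities. When
#' nothing is predicted positive, PPV is undefined and reported as `NA`.
#'
#' @inheritParams youden_cutoff
#' @param cutoff Probability cutoff.
#' @return Object of class `classification_metrics`: a list with `cutoff`,
#'   `auroc`, `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv` and the
#'   confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
classification_metrics <- function(probabilities, labels, cutoff) {
  y <- as.integer(as.logical(labels))
  stopifnot(length(probabilities) == length(y))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  pred <- probabilities >= cutoff
  tp <- sum(pred & y == 1L); fp <- sum(pred & y == 0L)
  fn <- sum(!pred & y == 1L); tn <- sum(!pred & y == 0L)
  r <- rank(probabilities)                  # average ranks: tie half-credit
  auroc <- (sum(r[y == 1L]) - tp_fn_pairs(tp + fn)) / ((tp + fn) * (fp + tn))
  structure(list(
    cutoff = cutoff,
    auroc = auroc,
    accuracy = (tp + tn) / length(y),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
    npv = if (tn + fn == 0L) NA_real_ else tn / (tn + fn),
    tp = tp, fp = fp, fn = fn, tn = tn),
    class = "classification_metrics")
}

tp_fn_pairs <- function(npos) npos * (npos + 1) / 2

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(paste0("<classification_metrics> cutoff %.4g | AUROC %.3f | ",
                     "acc %.3f | sens %.3f | spec %.3f | ppv %s | npv %s\n"),
              x$cutoff, x$auroc, x$accuracy, x$sensitivity, x$specificity,
              formatC(x$ppv, digits = 3, format = "f"),
              formatC(x$npv, digits = 3, format = "f")))
  invisible(x)
}

#' Explanation-coverage metrics
#'
#' The explanation-quality metrics: among *true positives* (patients
#' correctly predicted to have the interesting outcome), the fraction with
#' at least one applicable rule (`explained_rate_tp`) and with at least one
#' actionable applicable rule (`explained_rate_tp_actionable`); among *all*
#' actual positives, regardless of prediction, the fraction with at least
#' one applicable rule (`explained_rate_all_pos`); the mean number of
#' applicable rules, actionable applicable rules, and identified actionable
#' items per explained true positive; and the per-patient histograms of
#' those three counts over explained true positives. Identified actionable
#' items count distinct actionable items over all applicable rules, not
#' just the displayed ones.
#'
#' @param explanations List of `explanation`s aligned with `labels`
#'   (e.g. from [explain_cohort()]).
#' @param labels Binary vector of actual outcomes (interesting value = 1).
#' @param predictions Binary vector of predicted outcomes.
#' @param ruleset,table Optional: the pruned annotated ruleset and the
#'   discretized table, used to count applicable rules for patients that
#'   were *not* predicted positive (whose explanations are empty by
#'   construction), so that `explained_rate_all_pos` is unconditional on
#'   the prediction. Without them that rate is `NA`.
#' @return Object of class `explanation_metrics`. Rates with an empty
#'   denominator (e.g. no true positives) are `NA`.
#' @export
explanation_coverage <- function(explanations, labels, predictions,
                                 ruleset = NULL, table = NULL) {
  y <- as.logical(labels)
  pred <- as.logical(predictions)
  stopifnot(length(explanations) == length(y), length(pred) == length(y))
  n_app <- vapply(explanations, function(e) e$n_applicable, numeric(1))
  n_act <- vapply(explanations, function(e) e$n_actionable_applicable, numeric(1))
  n_items <- vapply(explanations, function(e) length(e$identified_items), numeric(1))

  tp <- y & pred
  rate <- function(num, den) if (sum(den) == 0L) NA_real_ else sum(num & den) / sum(den)
  explained <- n_app > 0 & pred

  all_pos_rate <- NA_real_
  if (!is.null(ruleset) && !is.null(table)) {
    rows <- patient_rows(table)
    app_any <- vapply(seq_along(rows), function(i) {
      if (pred[i]) return(n_app[i] > 0)     # already computed
      any(vapply(ruleset$rules, function(r)
        antecedent_matches(r$antecedent, rows[[i]]), logical(1)))
    }, logical(1))
    all_pos_rate <- rate(app_any, y)
  }

  etp <- explained & tp
  structure(list(
    explained_rate_tp = rate(explained, tp),
    explained_rate_tp_actionable = rate(n_act > 0 & pred, tp),
    explained_rate_all_pos = all_pos_rate,
    mean_rules_per_explained_tp =
      if (sum(etp) == 0L) NA_real_ else mean(n_app[etp]),
    mean_actionable_rules_per_explained_tp =
      if (sum(etp) == 0L) NA_real_ else mean(n_act[etp]),
    mean_identified_actionable_items =
      if (sum(etp) == 0L) NA_real_ else mean(n_items[etp]),
    hist_rules = count_histogram(n_app[etp]),
    hist_actionable_rules = count_histogram(n_act[etp]),
    hist_identified_items = count_histogram(n_items[etp]),
    n_tp = sum(tp), n_pos = sum(y), n_predicted_pos = sum(pred)),
    class = "explanation_metrics")
}

count_histogram <- function(counts) {
  if (length(counts) == 0L) {
    return(data.frame(count = integer(0), patients = integer(0)))
  }
  tab <- table(counts)
  data.frame(count = as.integer(names(tab)), patients = as.integer(tab))
}

#' @export
print.explanation_metrics <- function(x, ...) {
  cat(sprintf(paste0("<explanation_metrics> explained (TP): %.1f%% | ",
                     "actionable-only: %.1f%% | all positives: %s%%\n"),
              100 * x$explained_rate_tp, 100 * x$explained_rate_tp_actionable,
              formatC(100 * x$explained_rate_all_pos, digits = 1, format = "f")))
  cat(sprintf("mean per explained TP: %.1f rules, %.1f actionable, %.1f identified items\n",
              x$mean_rules_per_explained_tp,
              x$mean_actionable_rules_per_explained_tp,
              x$mean_identified_actionable_items))
  invisible(x)
}
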