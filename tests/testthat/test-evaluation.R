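test_that("youden cutoff lands between classes on separable input", {
  # perfect separation: any cutoff in (.4, .7) attains J = 1; midpoint 0.55
  expect_equal(youden_cutoff(c(.9, .7, .4, .2), c(1, 1, 0, 0)), 0.55)
})

test_that("ties in the maximal J resolve to the smallest cutoff", {
  # J = 0.5 at cutoffs 0.4 and 0.75; the smaller wins (favours sensitivity)
  expect_equal(youden_cutoff(c(.9, .6, .5, .3), c(1, 0, 1, 0)), 0.4)
})

test_that("youden cutoff is invariant to patient order and needs both classes", {
  set.seed(801)
  p <- runif(30); y <- rbinom(30, 1, 0.4)
  y[1:2] <- c(0, 1)
  perm <- sample(30)
  expect_equal(youden_cutoff(p, y), youden_cutoff(p[perm], y[perm]))
  expect_error(youden_cutoff(p, rep(1, 30)), "both classes")
})

test_that("youden cutoff equals an exhaustive threshold scan", {
  set.seed(802)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    p <- round(runif(n), sample(1:3, 1))   # ties likely
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(youden_cutoff(p, y), oracle_youden(p, y))
  }
})

test_that("confusion metrics match hand arithmetic", {
  # TP=3, FP=1, FN=1, TN=5 at cutoff 0.65
  p <- c(.9, .8, .7, .2, .66, .3, .25, .2, .15, .1)
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  m <- classification_metrics(p, y, 0.65)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(3, 1, 1, 5))
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 5 / 6)
  expect_equal(m$accuracy, 0.8)

  # nothing predicted positive: PPV undefined
  m2 <- classification_metrics(p, y, 2)
  expect_identical(m2$ppv, NA_real_)
})

test_that("AUROC is the tie-adjusted rank statistic", {
  expect_equal(classification_metrics(c(.9, .8, .2, .1), c(1, 1, 0, 0), .5)$auroc, 1)
  # all probabilities identical: pure ties give half credit
  expect_equal(classification_metrics(rep(.3, 10),
                                      rep(c(0, 1), 5), .5)$auroc, 0.5)
  # invariant under strictly monotone transforms
  set.seed(803)
  p <- runif(50); y <- rbinom(50, 1, 0.5); y[1:2] <- c(0, 1)
  a1 <- classification_metrics(p, y, .5)$auroc
  a2 <- classification_metrics(plogis(5 * p - 2), y, .5)$auroc
  expect_equal(a1, a2)
})

test_that("AUROC agrees with an established ROC implementation", {
  library(pROC)
  set.seed(804)
  for (rep in 1:10) {
    p <- round(runif(40), 2)
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    ours <- classification_metrics(p, y, .5)$auroc
    ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

mk_explanation <- function(id, predicted, n_app, n_act, items = character(0)) {
  structure(list(patient_id = id, predicted_positive = predicted,
                 explained = predicted && n_app > 0,
                 applicable = vector("list", n_app), displayed = list(),
                 n_applicable = n_app, n_actionable_applicable = n_act,
                 identified_items = items),
            class = "explanation")
}

test_that("explanation coverage counts rates over the right denominators", {
  # 5 true positives, 4 of them with at least one applicable rule
  y <- c(rep(1, 6), rep(0, 4))
  pred <- c(rep(1, 5), 0, 1, rep(0, 3))     # 5 TPs (patients 1-5), 1 FP
  ex <- list(
    mk_explanation("a", TRUE, 3, 2, c("i1", "i2")),
    mk_explanation("b", TRUE, 2, 0, character(0)),
    mk_explanation("c", TRUE, 1, 1, "i1"),
    mk_explanation("d", TRUE, 4, 4, c("i1", "i2", "i3")),
    mk_explanation("e", TRUE, 0, 0, character(0)),   # unexplained TP
    mk_explanation("f", FALSE, 0, 0, character(0)),
    mk_explanation("g", TRUE, 2, 1, "i2"),           # FP, explained
    mk_explanation("h", FALSE, 0, 0, character(0)),
    mk_explanation("i", FALSE, 0, 0, character(0)),
    mk_explanation("j", FALSE, 0, 0, character(0)))
  cov <- explanation_coverage(ex, y, pred)
  expect_equal(cov$explained_rate_tp, 0.8)
  expect_equal(cov$explained_rate_tp_actionable, 3 / 5)
  expect_true(cov$explained_rate_tp_actionable <= cov$explained_rate_tp)
  expect_equal(cov$mean_rules_per_explained_tp, mean(c(3, 2, 1, 4)))
  expect_equal(cov$mean_actionable_rules_per_explained_tp, mean(c(2, 0, 1, 4)))
  expect_equal(cov$mean_identified_actionable_items, mean(c(2, 0, 1, 3)))
  expect_equal(sum(cov$hist_rules$patients), 4)

  # no true positives: TP-denominated rates are undefined, not zero
  cov0 <- explanation_coverage(ex[7:10], labels = c(0, 0, 0, 0),
                               predictions = c(1, 0, 0, 0))
  expect_identical(cov0$explained_rate_tp, NA_real_)
})

test_that("identified actionable items count distinct items over applicable rules", {
  reg <- intervention_registry(
    list(registry_entry(item_eq("m1", "1"), "act m1", "med"),
         registry_entry(item_eq("m2", "1"), "act m2", "med")))
  rules <- list(
    ruleexplain:::new_rule(list(item_eq("m1", "1"), item_eq("d1", "1")),
                           "yes", .05, .8),
    ruleexplain:::new_rule(list(item_eq("m1", "1"), item_eq("m2", "1")),
                           "yes", .05, .7))
  rs <- annotate_ruleset(mk_ruleset(rules), reg)
  ex <- explain_patient(list(m1 = "1", m2 = "1", d1 = "1"), "p", TRUE, rs)
  # m1 and m2 are actionable, d1 is not -> 2 identified items
  expect_setequal(ex$identified_items, c("m1=1", "m2=1"))
})

test_that("explained rate among TPs can exceed the rules' own sensitivity", {
  # Positives covered by several conflicting low-sensitivity rules: a rule
  # set that would mispredict many patients can still explain all of them.
  df <- data.frame(
    a = c("1", "1", "0", "0", "1", "0", "0", "0"),
    b = c("0", "0", "1", "1", "1", "0", "0", "0"),
    stringsAsFactors = FALSE)
  y <- c("yes", "yes", "yes", "yes", "no", "no", "no", "no")
  tab <- toy_table(df, y)
  cfg <- mining_config(min_support = 0.2, min_confidence = 0.6,
                       max_len = 1)
  rs <- annotate_ruleset(mine_rules(tab, cfg), intervention_registry())
  # both {a=1} and {b=1} are mined with confidence 2/3
  expect_setequal(rule_ids(rs), c("a=1 => yes", "b=1 => yes"))
  pred <- rep(TRUE, 8)
  ex <- explain_cohort(tab, pred, rs)
  cov <- explanation_coverage(ex, y == "yes", pred)
  expect_equal(cov$explained_rate_tp, 1)
})
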