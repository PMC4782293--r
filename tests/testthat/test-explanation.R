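test_that("rules sort actionable-first, then by confidence, support, label", {
  r_act_low <- mk_rule("a", 0.6)
  r_act_high <- mk_rule("b", 0.9)
  r_non <- mk_rule("c", 0.95, actionable = FALSE)
  out <- sort_rules(list(r_non, r_act_low, r_act_high))
  expect_equal(vapply(out, ruleexplain:::rule_id, character(1)),
               vapply(list(r_act_high, r_act_low, r_non),
                      ruleexplain:::rule_id, character(1)))

  # confidence tie broken by larger support
  t1 <- mk_rule("a", 0.8, supp = 0.05)
  t2 <- mk_rule("b", 0.8, supp = 0.02)
  out2 <- sort_rules(list(t2, t1))
  expect_equal(ruleexplain:::rule_id(out2[[1]]), ruleexplain:::rule_id(t1))
})

test_that("greedy-disjoint selection skips overlapping rules then wraps around", {
  cfg <- display_config(n_r = 2)
  r1 <- mk_rule(c("a", "b"), 0.90)
  r2 <- mk_rule(c("a", "c"), 0.85)
  r3 <- mk_rule("d", 0.80)
  r4 <- mk_rule("e", 0.75)
  sel <- select_diverse(list(r1, r2, r3, r4), cfg)
  expect_equal(vapply(sel, ruleexplain:::rule_id, character(1)),
               c(ruleexplain:::rule_id(r1), ruleexplain:::rule_id(r3)))

  # all rules share an item: wrap-around second pass takes earliest unchosen
  s1 <- mk_rule(c("a", "b"), 0.9); s2 <- mk_rule(c("a", "c"), 0.8)
  s3 <- mk_rule(c("a", "d"), 0.7); s4 <- mk_rule(c("a", "e"), 0.6)
  sel2 <- select_diverse(list(s1, s2, s3, s4), cfg)
  expect_equal(vapply(sel2, ruleexplain:::rule_id, character(1)),
               c(ruleexplain:::rule_id(s1), ruleexplain:::rule_id(s2)))
})

test_that("few actionable rules are all shown, with diversified non-actionable fill", {
  cfg <- display_config(n_r = 3)
  act <- mk_rule("a", 0.7)
  n1 <- mk_rule(c("x", "y"), 0.9, actionable = FALSE)
  n2 <- mk_rule(c("x", "z"), 0.85, actionable = FALSE)
  n3 <- mk_rule("w", 0.8, actionable = FALSE)
  sel <- select_diverse(sort_rules(list(n1, n2, n3, act)), cfg)
  ids <- vapply(sel, ruleexplain:::rule_id, character(1))
  # the actionable rule first, then diversified non-actionable: n1, then n3
  # (n2 shares item x with n1)
  expect_equal(ids, vapply(list(act, n1, n3), ruleexplain:::rule_id,
                           character(1)))

  # show_nonactionable = FALSE omits the fill
  cfg2 <- display_config(n_r = 3, show_nonactionable = FALSE)
  sel2 <- select_diverse(sort_rules(list(n1, n2, n3, act)), cfg2)
  expect_equal(vapply(sel2, ruleexplain:::rule_id, character(1)),
               ruleexplain:::rule_id(act))
})

weighted_registry <- function() {
  intervention_registry(
    list(registry_entry(item_eq("m1", "1"), "m1 act", "med"),
         registry_entry(item_eq("m2", "1"), "m2 act", "med"),
         registry_entry(item_eq("d1", "1"), "d1 act", "dx"),
         registry_entry(item_eq("d2", "1"), "d2 act", "dx")),
    weights = c(med = 2, dx = 1))
}

test_that("weighted selection follows the zero-and-recompute trace", {
  reg <- weighted_registry()
  r1 <- mk_rule(c("m1", "d1"), 0.9)   # weight 2 + 1 = 3
  r2 <- mk_rule(c("m1", "m2"), 0.8)   # weight 2 + 2 = 4
  r3 <- mk_rule("d2", 0.7)            # weight 1
  cfg <- display_config(n_r = 2, method = "weighted")
  sel <- select_weighted(list(r1, r2, r3), reg, cfg)
  # pass 1 picks r2 (weight 4); zeroing m1, m2 leaves r1 = 1, r3 = 1;
  # pass 2 takes the first-encountered maximum: r1
  expect_equal(vapply(sel, ruleexplain:::rule_id, character(1)),
               c(ruleexplain:::rule_id(r2), ruleexplain:::rule_id(r1)))
})

test_that("weighted selection degenerates gracefully", {
  reg <- weighted_registry()
  cfg <- display_config(n_r = 2, method = "weighted")
  # all weights zero (no actionable items): first n_r in list order
  z <- lapply(c("x", "y", "z"), function(f)
    mk_rule(f, 0.8, actionable_features = character(0)))
  sel <- select_weighted(z, reg, cfg)
  expect_equal(vapply(sel, ruleexplain:::rule_id, character(1)),
               vapply(z[1:2], ruleexplain:::rule_id, character(1)))

  # a single rule is returned once even for larger n_r
  one <- list(mk_rule("m1", 0.9))
  sel1 <- select_weighted(one, reg, display_config(n_r = 3, method = "weighted"))
  expect_length(sel1, 1)
})

test_that("applicable rules equal a brute-force match scan", {
  set.seed(701)
  for (rep in 1:10) {
    tab <- random_table(30, 4)
    cfg <- mining_config(min_support = 0.05, min_confidence = 0.2)
    rs <- mine_rules(tab, cfg)
    rs <- annotate_ruleset(rs, intervention_registry())
    rows <- patient_rows(tab)
    i <- sample(length(rows), 1)
    app <- applicable_rules(rs, rows[[i]])
    brute <- Filter(function(r) {
      all(vapply(r$antecedent, item_matches, logical(1),
                 patient = rows[[i]]))
    }, rs$rules)
    expect_setequal(vapply(app, ruleexplain:::rule_id, character(1)),
                    vapply(brute, ruleexplain:::rule_id, character(1)))
  }
})

test_that("explanations are gated on a positive prediction", {
  rs <- annotate_ruleset(mk_ruleset(list(mk_rule("a", 0.8))),
                         intervention_registry())
  patient <- list(a = "1")
  off <- explain_patient(patient, "p1", predicted = FALSE, rs)
  expect_false(off$explained)
  expect_length(off$displayed, 0)
  expect_equal(off$n_applicable, 0)

  on <- explain_patient(patient, "p1", predicted = TRUE, rs)
  expect_true(on$explained)
  expect_equal(on$n_applicable, 1)

  miss <- explain_patient(list(a = "0"), "p2", predicted = TRUE, rs)
  expect_false(miss$explained)
  expect_true(miss$predicted_positive)
})

test_that("displayed rules carry their interventions and respect n_r", {
  reg <- weighted_registry()
  rules <- lapply(list(c("m1"), c("m2"), c("d1"), c("d2"),
                       c("m1", "d1"), c("m2", "d2"), c("m1", "m2")),
                  function(f) {
                    r <- ruleexplain:::new_rule(
                      lapply(f, function(x) item_eq(x, "1")), "yes",
                      0.05, runif(1, 0.6, 0.9))
                    r
                  })
  rs <- annotate_ruleset(mk_ruleset(rules), reg)
  patient <- list(m1 = "1", m2 = "1", d1 = "1", d2 = "1")
  ex <- explain_patient(patient, "p9", TRUE, rs, display_config(n_r = 3))
  expect_equal(ex$n_applicable, 7)
  expect_equal(ex$n_actionable_applicable, 7)
  expect_length(ex$displayed, 3)
  for (r in ex$displayed) expect_gt(length(r$interventions), 0)
  # identified actionable items span all applicable rules
  expect_setequal(ex$identified_items, c("m1=1", "m2=1", "d1=1", "d2=1"))

  # identical inputs give identical explanations
  ex2 <- explain_patient(patient, "p9", TRUE, rs, display_config(n_r = 3))
  expect_identical(ex, ex2)
})
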