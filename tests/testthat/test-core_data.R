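test_that("CSV loading types columns, keeps missing cells, validates levels", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("id,bmi,smoker,y",
               "a,31.5,yes,no",
               "b,,no,yes",
               "c,28,yes,yes"), csv)
  schema <- list(
    features = list(list(name = "bmi", kind = "continuous"),
                    list(name = "smoker", kind = "categorical",
                         levels = c("yes", "no"))),
    outcome = list(name = "y", levels = c("no", "yes"), interesting = "yes"))
  tab <- load_feature_table(csv, schema)
  expect_equal(n_patients(tab), 3)
  expect_equal(tab$data$bmi, c(31.5, NA, 28))
  expect_equal(tab$features$bmi$kind, "continuous")

  writeLines(c("id,bmi,smoker,y", "a,31.5,sometimes,no"), csv)
  expect_error(load_feature_table(csv, schema), "smoker.*sometimes")

  writeLines(c("id,bmi,smoker,y", "a,31.5,yes,maybe"), csv)
  expect_error(load_feature_table(csv, schema), "maybe")

  writeLines(c("id,bmi,smoker,y", "a,31.5,yes,no", "a,28,no,yes"), csv)
  expect_error(load_feature_table(csv, schema), "duplicate patient id")
})

test_that("schema sidecars round-trip through YAML and JSON", {
  tab <- toy_table(data.frame(a = c("1", "0"), stringsAsFactors = FALSE),
                   c("yes", "no"))
  for (ext in c(".yaml", ".json")) {
    sp <- tempfile(fileext = ext)
    cp <- tempfile(fileext = ".csv")
    write_table_schema(tab, sp)
    write_feature_table(tab, cp)
    back <- load_feature_table(cp, sp)
    expect_equal(back$data, tab$data)
    expect_equal(back$outcome, tab$outcome)
    expect_equal(back$outcome_spec$interesting, "yes")
  }
})

test_that("items match by equality or half-open interval; missing never matches", {
  row <- list(smoker = "yes", bmi = 35.0)
  expect_true(item_matches(item_eq("smoker", "yes"), row))
  expect_false(item_matches(item_eq("smoker", "no"), row))
  # the >= 35 condition of a BMI rule: boundary belongs to the interval
  expect_true(item_matches(item_range("bmi", 35, Inf), row))
  expect_false(item_matches(item_range("bmi", 35, Inf), list(bmi = 34.9)))
  expect_false(item_matches(item_range("bmi", 35, Inf), list(bmi = NA_real_)))
  expect_error(item_matches(item_eq("age", "1"), row), "not present")
})

test_that("interval bins partition the line: exactly one bin item matches", {
  cuts <- c(-2, 0.5, 3)
  bounds <- c(-Inf, cuts, Inf)
  items <- lapply(seq_len(length(bounds) - 1), function(i)
    item_range("x", bounds[i], bounds[i + 1]))
  for (x in c(-10, -2, -1.99, 0.49999, 0.5, 2.2, 3, 1e6)) {
    hits <- vapply(items, item_matches, logical(1),
                   patient = list(x = x))
    expect_equal(sum(hits), 1)
  }
})

test_that("antecedents are conjunctions; empty antecedents are rejected", {
  row <- list(a = "1", b = "2")
  expect_true(antecedent_matches(list(item_eq("a", "1"), item_eq("b", "2")), row))
  expect_false(antecedent_matches(list(item_eq("a", "1"), item_eq("b", "9")), row))
  expect_error(antecedent_matches(list(), row), "at least one item")

  # same feature with disjoint intervals is unsatisfiable for every row
  contradiction <- list(item_range("x", -Inf, 0), item_range("x", 5, Inf))
  for (x in c(-3, 0, 2, 5, 100)) {
    expect_false(antecedent_matches(contradiction, list(x = x)))
  }
})

test_that("antecedent matching agrees with per-item brute force on random rows", {
  set.seed(401)
  for (rep in 1:50) {
    row <- list(a = sample(c("0", "1", NA), 1),
                x = sample(c(runif(1, -5, 5), NA), 1),
                z = sample(c("lo", "hi"), 1))
    items <- list(item_eq("a", sample(c("0", "1"), 1)),
                  item_range("x", runif(1, -5, 0), runif(1, 0, 5)),
                  item_eq("z", "hi"))
    picked <- sample(items, sample(1:3, 1))
    expect_identical(
      antecedent_matches(picked, row),
      all(vapply(picked, item_matches, logical(1), patient = row)))
  }
})

test_that("train/test split is a reproducible disjoint partition", {
  set.seed(77)
  tab <- random_table(40, 3)
  for (seed in 1:100) {
    sp <- split_train_test(tab, 0.8, seed)
    expect_equal(n_patients(sp$train), 32)
    expect_length(intersect(sp$train$ids, sp$test$ids), 0)
    expect_setequal(c(sp$train$ids, sp$test$ids), tab$ids)
  }
  a <- split_train_test(tab, 0.8, 5)
  b <- split_train_test(tab, 0.8, 5)
  expect_identical(a$train$ids, b$train$ids)
  expect_error(split_train_test(tab, 1.2, 1), "between 0 and 1")
})

test_that("split size follows round-half-even on an n = 9948 cohort", {
  # 9948 * 0.8 = 7958.4 -> 7958 training patients
  ids <- as.character(seq_len(9948))
  df <- data.frame(a = rep("1", 9948), stringsAsFactors = FALSE)
  tab <- feature_table(ids, df,
                       list(feature_spec("a", "categorical", c("0", "1"))),
                       rep(c("no", "yes"), length.out = 9948),
                       outcome_spec("y", c("no", "yes"), "yes"))
  sp <- split_train_test(tab, 0.8, 1)
  expect_equal(n_patients(sp$train), 7958)
  expect_equal(n_patients(sp$test), 1990)
})
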