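#' Planted rule for cohort simulation
#'
#' Describes a ground-truth association planted into a synthetic cohort:
#' patients satisfying the antecedent acquire the interesting outcome with
#' probability `target_confidence`; a fraction `prevalence` of the cohort is
#' forced to satisfy the antecedent.
#'
#' @param antecedent List of `rule_item`s.
#' @param target_confidence In (0, 1].
#' @param prevalence In (0, 1].
#' @return Object of class `planted_rule`.
#' @export
planted_rule <- function(antecedent, target_confidence, prevalence) {
  stopifnot(length(antecedent) >= 1L,
            target_confidence > 0, target_confidence <= 1,
            prevalence > 0, prevalence <= 1)
  structure(list(antecedent = sort_items(antecedent),
                 target_confidence = target_confidence,
                 prevalence = prevalence),
            class = "planted_rule")
}

#' Cohort simulation configuration
#'
#' Feature entries are lists with `name`, `kind`, and either `levels` +
#' `probs` (categorical marginals) or `mean` + `sd` + optional
#' `class_shift` (continuous). A non-zero `class_shift` is added to the
#' values of positive-outcome patients for continuous features that are not
#' part of any planted antecedent, giving the discretizer a recoverable
#' class-conditional signal. `baseline_rate` is the outcome probability for
#' patients firing no planted rule and must stay below every planted
#' confidence, so planted rules remain discoverable above the confidence
#' threshold.
#'
#' @param n_patients Cohort size.
#' @param features List of feature entries (see above).
#' @param planted_rules List of [planted_rule()]s.
#' @param baseline_rate Outcome probability when no planted rule fires.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, features, planted_rules = list(),
                          baseline_rate = 0.19, seed = 1L) {
  stopifnot(n_patients >= 1, baseline_rate >= 0, baseline_rate < 1)
  if (length(planted_rules)) {
    min_conf <- min(vapply(planted_rules, function(r) r$target_confidence,
                           numeric(1)))
    if (!(baseline_rate < min_conf)) {
      stop("baseline_rate must be below every planted target_confidence")
    }
    if (sum(vapply(planted_rules, function(r) r$prevalence, numeric(1))) > 1) {
      stop("infeasible prevalence combination: planted prevalences sum above 1")
    }
  }
  structure(list(n_patients = as.integer(n_patients), features = features,
                 planted_rules = planted_rules, baseline_rate = baseline_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

## Draw a value inside [lo, hi) for a forced interval item, using the
## feature's scale to bound infinite ends.
sample_in_interval <- function(n, lo, hi, mean, sd) {
  l <- if (is.finite(lo)) lo else min(hi - 2 * sd, mean - 2 * sd)
  h <- if (is.finite(hi)) hi else max(lo + 2 * sd, mean + 2 * sd)
  stats::runif(n, l, h)
}

#' Generate a synthetic EMR-like cohort with planted rule structure
#'
#' Features are sampled independently from their marginals; then, for each
#' planted rule, a disjoint random slice of the cohort of size
#' `round(prevalence * n)` is overwritten to satisfy the rule's antecedent
#' (slices disjoint across rules, which is why prevalences must sum to at
#' most 1; patients outside the slices can still satisfy an antecedent by
#' chance). The outcome is then drawn per patient with probability equal to
#' the maximum `target_confidence` over the rules the patient actually
#' fires, or `baseline_rate` when none fires. Finally, class-conditional
#' shifts are applied to eligible continuous features. Ground-truth
#' bookkeeping (firing matrix and generating probabilities) is returned for
#' the stand-in model and for recovery tests.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort` with elements `table` (a
#'   [feature_table()], outcome levels `"no"`/`"yes"` with `"yes"`
#'   interesting) and `truth` (list: `fired` n-by-rules logical matrix,
#'   `prob` generating probabilities, `config`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_patients
  feats <- config$features
  fnames <- vapply(feats, function(f) f$name, character(1))
  names(feats) <- fnames
  data <- list()
  specs <- list()
  for (f in feats) {
    if (f$kind == "categorical") {
      probs <- if (is.null(f$probs)) rep(1 / length(f$levels), length(f$levels)) else f$probs
      data[[f$name]] <- sample(as.character(f$levels), n, replace = TRUE,
                               prob = probs)
      specs[[f$name]] <- feature_spec(f$name, "categorical", f$levels)
    } else {
      data[[f$name]] <- stats::rnorm(n, f$mean, f$sd)
      specs[[f$name]] <- feature_spec(f$name, "continuous")
    }
  }

  rules <- config$planted_rules
  planted_feats <- unique(unlist(lapply(rules, function(r)
    vapply(r$antecedent, function(it) it$feature, character(1)))))
  if (length(setdiff(planted_feats, fnames))) {
    stop("planted rule references unknown feature: ",
         setdiff(planted_feats, fnames)[1L])
  }

  ## disjoint forced slices
  perm <- sample.int(n)
  offset <- 0L
  for (r in rules) {
    size <- as.integer(round(r$prevalence * n))
    idx <- perm[offset + seq_len(size)]
    offset <- offset + size
    for (it in r$antecedent) {
      if (it$op == "eq") {
        data[[it$feature]][idx] <- it$value
      } else {
        fs <- feats[[it$feature]]
        data[[it$feature]][idx] <-
          sample_in_interval(length(idx), it$lo, it$hi, fs$mean, fs$sd)
      }
    }
  }

  ## who actually fires which rule (forced or by chance)
  tmp <- as.data.frame(data, check.names = FALSE, stringsAsFactors = FALSE)
  fired <- matrix(FALSE, nrow = n, ncol = length(rules))
  shell <- list(data = tmp)
  for (ri in seq_along(rules)) {
    m <- Reduce(`&`, lapply(rules[[ri]]$antecedent, item_match_column,
                            table = shell))
    fired[, ri] <- m
  }

  prob <- rep(config$baseline_rate, n)
  if (length(rules)) {
    confs <- vapply(rules, function(r) r$target_confidence, numeric(1))
    for (i in seq_len(n)) {
      if (any(fired[i, ])) prob[i] <- max(confs[fired[i, ]])
    }
  }
  y <- ifelse(stats::runif(n) < prob, "yes", "no")

  ## class-conditional shift for continuous features outside planted antecedents
  for (f in feats) {
    if (f$kind == "continuous" && !is.null(f$class_shift) &&
        f$class_shift != 0 && !(f$name %in% planted_feats)) {
      data[[f$name]] <- data[[f$name]] + f$class_shift * (y == "yes")
    }
  }

  ids <- sprintf("P%05d", seq_len(n))
  table <- feature_table(
    ids,
    as.data.frame(data, check.names = FALSE, stringsAsFactors = FALSE),
    specs, y, outcome_spec("outcome", c("no", "yes"), "yes"))
  structure(list(table = table,
                 truth = list(fired = fired, prob = prob, config = config)),
            class = "synthetic_cohort")
}

#' Stand-in black-box model
#'
#' Plays the role of an arbitrary external classifier: its predicted
#' probability for each patient is the cohort's true generating probability,
#' blended with uniform noise as
#' `(1 - noise) * p + noise * U(0,1)`. At `noise = 0` it is a perfect
#' oracle of the generating probabilities; increasing noise degrades its
#' discrimination while keeping probabilities in \[0, 1\].
#'
#' @param cohort A `synthetic_cohort`.
#' @param noise In \[0, 0.5).
#' @param seed Optional seed for the noise draw.
#' @return `data.frame` with columns `patient_id` and `probability`
#'   (a predictions table, see [write_predictions()]).
#' @export
standin_model <- function(cohort, noise = 0, seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            noise >= 0, noise < 0.5)
  p <- cohort$truth$prob
  if (noise > 0) {
    u <- if (is.null(seed)) stats::runif(length(p)) else
      withr::with_seed(seed, stats::runif(length(p)))
    p <- (1 - noise) * p + noise * u
  }
  data.frame(patient_id = cohort$table$ids, probability = p,
             stringsAsFactors = FALSE)
}

#' Default demonstration cohort configuration
#'
#' An EMR-like cohort of 9948 patients with an overall interesting-outcome
#' prevalence near 19 %: three medication/lab-style categorical features, a
#' smoking-status feature, and three continuous features (maximum BMI,
#' diagnosis count, age), with three planted rules modeled on typical
#' diabetes-risk patterns (e.g. ACE-inhibitor use with BMI >= 35). The
#' planted confidences (0.65-0.75) sit above the 50 % mining confidence
#' threshold; the baseline rate of 8 % brings the overall prevalence to
#' about 19 %.
#'
#' @param n_patients Cohort size (default 9948).
#' @param seed Integer seed.
#' @return A [cohort_config()].
#' @export
default_cohort_config <- function(n_patients = 9948, seed = 1L) {
  features <- list(
    list(name = "ace_inhibitor", kind = "categorical",
         levels = c("no", "yes"), probs = c(0.85, 0.15)),
    list(name = "loop_diuretic", kind = "categorical",
         levels = c("no", "yes"), probs = c(0.90, 0.10)),
    list(name = "statin", kind = "categorical",
         levels = c("no", "yes"), probs = c(0.80, 0.20)),
    list(name = "smoker", kind = "categorical",
         levels = c("never", "former", "current"),
         probs = c(0.60, 0.20, 0.20)),
    list(name = "bmi_max", kind = "continuous", mean = 29, sd = 5),
    list(name = "n_diagnoses", kind = "continuous", mean = 10, sd = 6),
    list(name = "age", kind = "continuous", mean = 55, sd = 12)
  )
  planted <- list(
    planted_rule(list(item_eq("ace_inhibitor", "yes"),
                      item_range("bmi_max", 35, Inf)),
                 target_confidence = 0.75, prevalence = 0.06),
    planted_rule(list(item_eq("loop_diuretic", "yes"),
                      item_range("n_diagnoses", 23, Inf)),
                 target_confidence = 0.70, prevalence = 0.05),
    planted_rule(list(item_eq("statin", "yes"),
                      item_range("age", 65, Inf)),
                 target_confidence = 0.65, prevalence = 0.07)
  )
  cohort_config(n_patients, features, planted,
                baseline_rate = 0.08, seed = seed)
}
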