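#' Feature specifications
#'
#' A feature is either categorical (with a declared set of levels) or
#' continuous. Continuous features must be discretized (see
#' [build_binning()]) before rule mining.
#'
#' @param name Feature name, unique within a table.
#' @param kind `"categorical"` or `"continuous"`.
#' @param levels Character vector of category labels (categorical only).
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(name, kind = c("categorical", "continuous"),
                         levels = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "continuous" && !is.null(levels)) {
    stop("continuous feature '", name, "' must not declare levels")
  }
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) == 0L) {
      stop("categorical feature '", name, "' needs at least one level")
    }
    levels <- as.character(levels)
    if (anyDuplicated(levels)) stop("duplicate levels for feature '", name, "'")
  }
  structure(list(name = name, kind = kind, levels = levels),
            class = "feature_spec")
}

#' Outcome specification
#'
#' Declares the categorical outcome, its levels, and which levels are
#' "interesting", i.e. require explanation (e.g. "will be diagnosed").
#' The interesting values must be a non-empty proper subset of the levels:
#' at least one level represents the normal case needing no explanation.
#'
#' @param name Outcome column name.
#' @param levels All outcome levels.
#' @param interesting Levels requiring explanation.
#' @return An object of class `outcome_spec`.
#' @export
outcome_spec <- function(name, levels, interesting) {
  levels <- as.character(levels)
  interesting <- as.character(interesting)
  stopifnot(is.character(name), length(name) == 1L)
  if (length(interesting) == 0L || !all(interesting %in% levels) ||
      length(setdiff(levels, interesting)) == 0L) {
    stop("interesting values must be a non-empty proper subset of outcome levels")
  }
  structure(list(name = name, levels = levels, interesting = interesting),
            class = "outcome_spec")
}

#' Patient feature table
#'
#' One row per patient, typed feature columns, and a never-missing
#' categorical outcome. Missing feature values are allowed and are treated
#' as "no item matches".
#'
#' @param ids Character vector of unique patient identifiers.
#' @param data `data.frame` of feature columns (character for categorical,
#'   numeric for continuous); `NA` marks a missing value.
#' @param features List of [feature_spec()]s covering every column of `data`.
#' @param outcome Character vector of outcome values, no `NA`.
#' @param outcome_spec An [outcome_spec()].
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(ids, data, features, outcome, outcome_spec) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate patient id: ", ids[duplicated(ids)][1L],
         " (every patient has a single row)")
  }
  stopifnot(is.data.frame(data), nrow(data) == length(ids),
            length(outcome) == length(ids))
  names(features) <- vapply(features, function(f) f$name, character(1))
  if (anyDuplicated(names(features))) stop("duplicate feature names")
  if (!setequal(names(features), names(data))) {
    stop("feature specs and data columns disagree")
  }
  data <- data[names(features)]
  for (f in features) {
    col <- data[[f$name]]
    if (f$kind == "continuous") {
      if (!is.numeric(col)) stop("continuous feature '", f$name, "' is not numeric")
    } else {
      col <- as.character(col)
      bad <- !is.na(col) & !col %in% f$levels
      if (any(bad)) {
        stop("feature '", f$name, "': value '", col[bad][1L],
             "' is not a declared level")
      }
      data[[f$name]] <- col
    }
  }
  outcome <- as.character(outcome)
  if (anyNA(outcome)) stop("outcome must never be missing")
  if (!all(outcome %in% outcome_spec$levels)) {
    stop("outcome '", outcome_spec$name, "': value '",
         setdiff(outcome, outcome_spec$levels)[1L], "' is not a declared level")
  }
  structure(list(ids = ids, data = data, features = features,
                 outcome = outcome, outcome_spec = outcome_spec),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  kinds <- vapply(x$features, function(f) f$kind, character(1))
  cat(sprintf("<feature_table> %d patients, %d features (%d categorical, %d continuous)\n",
              length(x$ids), length(x$features),
              sum(kinds == "categorical"), sum(kinds == "continuous")))
  tab <- table(x$outcome)
  cat("outcome '", x$outcome_spec$name, "': ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      " (interesting: ", paste(x$outcome_spec$interesting, collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Number of patients in a feature table
#' @param table A `feature_table`.
#' @export
n_patients <- function(table) length(table$ids)

#' Subset a feature table by patient index
#'
#' @param table A `feature_table`.
#' @param idx Integer or logical row index.
#' @return A `feature_table` with the selected patients.
#' @export
subset_patients <- function(table, idx) {
  feature_table(table$ids[idx], table$data[idx, , drop = FALSE],
                table$features, table$outcome[idx], table$outcome_spec)
}

#' Patient rows as named lists
#'
#' Converts a feature table into a list of per-patient named value lists,
#' the form consumed by [item_matches()] and the explanation functions.
#'
#' @param table A `feature_table`.
#' @return A list (named by patient id) of named lists of feature values.
#' @export
patient_rows <- function(table) {
  rows <- lapply(seq_along(table$ids), function(i) {
    lapply(table$data, function(col) col[[i]])
  })
  names(rows) <- table$ids
  rows
}

#' Load a feature table from CSV plus a schema
#'
#' The CSV must have a header row; its first column holds the patient id and
#' the remaining columns are matched to the schema by name. Empty cells
#' become missing values. Unknown categorical values and duplicate patient
#' ids are errors.
#'
#' @param path CSV file path.
#' @param schema Either a list with elements `features` (list of
#'   `name`/`kind`/`levels` entries) and `outcome` (`name`/`levels`/
#'   `interesting`), or the path of a YAML/JSON sidecar with that structure.
#' @return A [feature_table()].
#' @export
load_feature_table <- function(path, schema) {
  schema <- read_schema(schema)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = character(0))
  if (ncol(raw) < 2L) stop("CSV needs a patient-id column plus data columns")
  ids <- raw[[1L]]
  specs <- lapply(schema$features, function(f) {
    feature_spec(f$name, f$kind, f$levels)
  })
  names(specs) <- vapply(specs, function(f) f$name, character(1))
  cols <- list()
  for (f in specs) {
    if (!f$name %in% names(raw)) stop("schema feature '", f$name, "' missing from CSV")
    col <- raw[[f$name]]
    col[!nzchar(col)] <- NA_character_
    if (f$kind == "continuous") {
      num <- suppressWarnings(as.numeric(col))
      bad <- is.na(num) & !is.na(col)
      if (any(bad)) {
        stop("feature '", f$name, "': non-numeric value '", col[bad][1L], "'")
      }
      cols[[f$name]] <- num
    } else {
      cols[[f$name]] <- col
    }
  }
  oc <- schema$outcome
  if (!oc$name %in% names(raw)) stop("outcome column '", oc$name, "' missing from CSV")
  yv <- raw[[oc$name]]
  yv[!nzchar(yv)] <- NA_character_
  ospec <- outcome_spec(oc$name, oc$levels, oc$interesting)
  feature_table(ids, as.data.frame(cols, check.names = FALSE,
                                   stringsAsFactors = FALSE),
                specs, yv, ospec)
}

read_schema <- function(schema) {
  if (is.character(schema) && length(schema) == 1L) {
    ext <- tolower(tools::file_ext(schema))
    schema <- if (ext == "json") {
      jsonlite::read_json(schema, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(schema)
    }
  }
  stopifnot(is.list(schema), !is.null(schema$features), !is.null(schema$outcome))
  schema
}

#' Split a feature table into training and test sets
#'
#' Random disjoint partition; the training set has `round(n * fraction)`
#' patients (banker's rounding, ties to even), mirroring the usual
#' 80 %/20 % design. The split is reproducible for a fixed seed.
#'
#' @param table A `feature_table`.
#' @param train_fraction Proportion in (0, 1).
#' @param seed Integer seed.
#' @return List with elements `train` and `test` (both `feature_table`s).
#' @export
split_train_test <- function(table, train_fraction, seed) {
  if (!is.numeric(train_fraction) || length(train_fraction) != 1L ||
      train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  n <- n_patients(table)
  n_train <- as.integer(round(n * train_fraction))
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  list(train = subset_patients(table, sort(idx)),
       test = subset_patients(table, sort(setdiff(seq_len(n), idx))))
}
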