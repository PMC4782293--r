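# Independent oracles and fixture builders used across the suite.
# Each oracle is a deliberately naive re-derivation of the contract it
# checks, kept free of the package's internal code paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- fixture builders -------------------------------------------------------

# A quick categorical feature_table from a data.frame of character columns
# plus an outcome vector.
toy_table <- function(df, outcome, interesting = "yes",
                      levels = c("no", "yes")) {
  specs <- lapply(names(df), function(nm) {
    feature_spec(nm, "categorical", levels = sort(unique(df[[nm]])))
  })
  feature_table(sprintf("p%03d", seq_len(nrow(df))), df, specs,
                outcome, outcome_spec("y", levels, interesting))
}

# Random all-categorical table for mining/property tests. Call under a seed.
random_table <- function(n, n_feat, max_levels = 4) {
  df <- as.data.frame(lapply(seq_len(n_feat), function(i) {
    k <- sample(2:max_levels, 1)
    sample(paste0("v", seq_len(k)), n, replace = TRUE)
  }), col.names = paste0("f", seq_len(n_feat)))
  outcome <- sample(c("no", "yes"), n, replace = TRUE,
                    prob = c(0.7, 0.3))
  toy_table(df, outcome)
}

# A bare annotated rule for pruning/display tests; items given as feature
# names (value fixed to "1"), all items actionable unless stated.
mk_rule <- function(features, conf, supp = 0.05, consequent = "yes",
                    actionable = TRUE, actionable_features = features) {
  r <- ruleexplain:::new_rule(
    lapply(features, function(f) item_eq(f, "1")), consequent, supp, conf)
  if (actionable) {
    r$actionable <- TRUE
    r$interventions <- paste0("intervention for ", features[1])
  }
  r$actionable_items <- vapply(actionable_features,
                               function(f) item_key(item_eq(f, "1")),
                               character(1))
  r
}

mk_ruleset <- function(rules) ruleexplain:::new_ruleset(rules)

# Random ruleset with subset structure (base rules plus specializations),
# the natural shape pruning operates on. Call under a seed.
random_ruleset <- function(n_base = 20, universe = paste0("f", 1:10),
                           extensions = 2) {
  ants <- lapply(seq_len(n_base), function(i)
    sample(universe, sample(1:2, 1)))
  for (b in seq_len(n_base)) {
    for (e in seq_len(extensions)) {
      extra <- setdiff(universe, ants[[b]])
      if (length(extra)) {
        ants[[length(ants) + 1]] <-
          c(ants[[b]], sample(extra, min(sample(1:2, 1), length(extra))))
      }
    }
  }
  ants <- ants[!duplicated(lapply(ants, function(a)
    paste(sort(a), collapse = "|")))]
  mk_ruleset(lapply(ants, function(a)
    mk_rule(a, conf = runif(1, 0.5, 1), supp = runif(1, 0.01, 0.3))))
}

rule_ids <- function(ruleset) {
  vapply(ruleset$rules, ruleexplain:::rule_id, character(1))
}

# ---- mining oracle ----------------------------------------------------------

# Exhaustive enumeration of every antecedent (one item per feature, size up
# to max_len) with direct counting; no level-wise pruning.
oracle_mine <- function(table, config) {
  feats <- sort(config$model_features %||% names(table$features))
  n <- n_patients(table)
  out <- list()
  for (v in table$outcome_spec$interesting) {
    yv <- table$outcome == v
    for (k in seq_len(min(config$max_len, length(feats)))) {
      for (fc in utils::combn(feats, k, simplify = FALSE)) {
        grid <- expand.grid(lapply(fc, function(f) table$features[[f]]$levels),
                            stringsAsFactors = FALSE)
        for (gi in seq_len(nrow(grid))) {
          match <- rep(TRUE, n)
          for (j in seq_along(fc)) {
            col <- table$data[[fc[j]]]
            match <- match & !is.na(col) & col == grid[gi, j]
          }
          nm <- sum(match)
          nj <- sum(match & yv)
          if (nj >= config$min_support * n - 1e-9 && nm > 0 &&
              nj / nm >= config$min_confidence - 1e-12) {
            key <- paste(sort(paste0(fc, "=", unlist(grid[gi, ]))),
                         collapse = " & ")
            out[[length(out) + 1]] <- list(key = paste0(key, " => ", v),
                                           support = nj / n,
                                           confidence = nj / nm)
          }
        }
      }
    }
  }
  out
}

# ---- MDLP oracle ------------------------------------------------------------

oracle_mdlp <- function(values, labels) {
  ent <- function(labs) {
    if (!length(labs)) return(0)
    p <- as.numeric(table(labs)) / length(labs)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  rec <- function(v, y) {
    n <- length(v)
    if (n < 2 || length(unique(y)) < 2 || length(unique(v)) < 2)
      return(numeric(0))
    dv <- sort(unique(v))
    cand <- (dv[-1] + dv[-length(dv)]) / 2
    gains <- vapply(cand, function(ct) {
      l <- v < ct
      ent(y) - (sum(l) * ent(y[l]) + sum(!l) * ent(y[!l])) / n
    }, numeric(1))
    best <- which(gains > max(gains) - 1e-12)[1]   # smallest cut on ties
    ct <- cand[best]
    l <- v < ct
    e <- ent(y); e1 <- ent(y[l]); e2 <- ent(y[!l])
    k <- length(unique(y))
    k1 <- length(unique(y[l])); k2 <- length(unique(y[!l]))
    gain <- e - (sum(l) * e1 + sum(!l) * e2) / n
    delta <- log2(3^k - 2) - (k * e - k1 * e1 - k2 * e2)
    if (!(gain > log2(n - 1) / n + delta / n)) return(numeric(0))
    c(ct, rec(v[l], y[l]), rec(v[!l], y[!l]))
  }
  keep <- !is.na(values) & !is.na(labels)
  v <- values[keep]; y <- as.character(labels[keep])
  ord <- order(v)
  sort(rec(v[ord], y[ord]))
}

# ---- Youden oracle ----------------------------------------------------------

oracle_youden <- function(prob, labels) {
  y <- as.integer(as.logical(labels))
  sp <- sort(unique(prob))
  cands <- c(-Inf, if (length(sp) > 1) (sp[-length(sp)] + sp[-1]) / 2, Inf)
  best_j <- -Inf; best_c <- NA_real_
  for (ct in cands) {
    pred <- prob >= ct
    j <- mean(pred[y == 1]) + mean(!pred[y == 0]) - 1
    if (j > best_j + 1e-12) { best_j <- j; best_c <- ct }
  }
  best_c
}
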