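#' Supervised MDL discretization of a numeric feature
#'
#' Recursive entropy-based binary splitting with the minimum-description-
#' length stopping rule. At each recursion level every boundary between
#' adjacent distinct values is evaluated; the split minimizing the weighted
#' class entropy (maximal information gain) is taken, with ties resolved
#' towards the smallest threshold, and the cut is placed at the midpoint of
#' the two adjacent distinct values. A split of S into S1, S2 is accepted iff
#'
#'   Gain > log2(N - 1)/N + Delta/N,
#'   Delta = log2(3^k - 2) - (k*Ent(S) - k1*Ent(S1) - k2*Ent(S2)),
#'
#' where N = |S| and k, k1, k2 count the classes present in each set.
#' Recursion stops when the criterion fails, a side is pure, or a side has
#' fewer than two observations (or fewer than two distinct values).
#'
#' @param values Numeric vector.
#' @param labels Class labels, same length; usually the binary indicator of
#'   an interesting outcome value. Pairs with a missing value or label are
#'   dropped.
#' @return Sorted numeric vector of cutpoints (possibly empty). All-equal
#'   values or a single class yield no cuts.
#' @export
mdlp_cuts <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  keep <- !is.na(values) & !is.na(labels)
  v <- as.numeric(values[keep])
  y <- as.character(labels[keep])
  if (length(v) < 2L) return(numeric(0))
  ord <- order(v, method = "radix")
  sort(mdlp_recurse(v[ord], y[ord]))
}

class_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

## v sorted ascending, y aligned class labels.
mdlp_recurse <- function(v, y) {
  n <- length(v)
  classes <- unique(y)
  if (n < 2L || length(classes) < 2L) return(numeric(0))
  dv <- unique(v)
  if (length(dv) < 2L) return(numeric(0))

  ## cumulative class counts at the end of each distinct-value group
  grp <- match(v, dv)                       # v sorted => grp non-decreasing
  cls <- match(y, classes)
  cum <- matrix(0, nrow = length(dv), ncol = length(classes))
  for (i in seq_len(n)) cum[grp[i], cls[i]] <- cum[grp[i], cls[i]] + 1L
  cum <- apply(cum, 2L, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1L)
  total <- cum[length(dv), ]
  ent_s <- class_entropy(total)

  best <- NULL
  for (b in seq_len(length(dv) - 1L)) {      # split: groups 1..b | rest
    left <- cum[b, ]
    right <- total - left
    n1 <- sum(left); n2 <- sum(right)
    e1 <- class_entropy(left); e2 <- class_entropy(right)
    gain <- ent_s - (n1 * e1 + n2 * e2) / n
    if (is.null(best) || gain > best$gain + 1e-12) {
      best <- list(b = b, gain = gain, e1 = e1, e2 = e2,
                   k1 = sum(left > 0), k2 = sum(right > 0))
    }
  }
  k <- length(classes)
  delta <- log2(3^k - 2) - (k * ent_s - best$k1 * best$e1 - best$k2 * best$e2)
  if (!(best$gain > log2(n - 1) / n + delta / n)) return(numeric(0))
  cut <- (dv[best$b] + dv[best$b + 1L]) / 2
  left_idx <- grp <= best$b
  c(cut,
    mdlp_recurse(v[left_idx], y[left_idx]),
    mdlp_recurse(v[!left_idx], y[!left_idx]))
}

#' Build a binning map for the continuous features of a table
#'
#' Runs [mdlp_cuts()] per continuous feature, supervised against the binary
#' indicator "outcome is an interesting value", which matches the
#' explanation goal: bins are chosen where they separate patients who go on
#' to have the outcome of interest from those who do not.
#'
#' @param table A [feature_table()].
#' @param features Continuous feature names to bin (default: all).
#' @return A named list of cutpoint vectors, class `binning_map`.
#' @export
build_binning <- function(table, features = NULL) {
  cont <- names(table$features)[vapply(table$features, function(f)
    f$kind == "continuous", logical(1))]
  if (is.null(features)) features <- cont
  if (length(setdiff(features, cont))) {
    stop("not a continuous feature: ", setdiff(features, cont)[1L])
  }
  y <- table$outcome %in% table$outcome_spec$interesting
  bins <- lapply(features, function(f) mdlp_cuts(table$data[[f]], y))
  names(bins) <- features
  structure(bins, class = "binning_map")
}

bin_labels <- function(cuts) {
  if (length(cuts) == 0L) return(interval_label(-Inf, Inf))
  bounds <- c(-Inf, cuts, Inf)
  vapply(seq_len(length(bounds) - 1L), function(i)
    interval_label(bounds[i], bounds[i + 1L]), character(1))
}

#' Replace continuous columns by categorical interval bins
#'
#' Each listed continuous feature is mapped onto the half-open bins induced
#' by its cutpoints; the bin labels become the categorical levels. Missing
#' values stay missing; categorical columns are untouched. A value exactly
#' on a cut falls into the right-hand bin (`35` with cut `35` is
#' `"[35,Inf)"`).
#'
#' @param table A [feature_table()].
#' @param bins A `binning_map` (named list of cutpoint vectors).
#' @return A `feature_table` in which the binned features are categorical.
#' @export
apply_binning <- function(table, bins) {
  data <- table$data
  specs <- table$features
  for (f in names(bins)) {
    spec <- specs[[f]]
    if (is.null(spec)) stop("binning requested for unknown feature '", f, "'")
    if (spec$kind != "continuous") stop("feature '", f, "' is not continuous")
    cuts <- as.numeric(bins[[f]])
    labels <- bin_labels(cuts)
    x <- data[[f]]
    idx <- findInterval(x, cuts) + 1L       # [c_i, c_{i+1}) half-open bins
    lab <- labels[idx]
    lab[is.na(x)] <- NA_character_
    data[[f]] <- lab
    specs[[f]] <- feature_spec(f, "categorical", levels = labels)
  }
  feature_table(table$ids, data, specs, table$outcome, table$outcome_spec)
}
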