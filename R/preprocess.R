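#' Z-score normalisation
#'
#' Replaces each named numeric column by `(x - mean) / sd`, with mean and
#' sample standard deviation (denominator `n - 1`) computed over the
#' non-missing entries. Zero-variance columns map to all zeros; missing
#' cells stay missing.
#'
#' @param d a [cpemm_dataset].
#' @param columns feature names to normalise; default all numeric features.
#' @return The normalised dataset.
#' @export
zscore_normalize <- function(d, columns = NULL) {
  columns <- check_numeric_columns(d, columns)
  for (cn in columns) {
    x <- d$X[[cn]]
    obs <- !is.na(x)
    m <- mean(x[obs])
    s <- if (sum(obs) > 1) stats::sd(x[obs]) else 0
    d$X[[cn]] <- if (is.na(s) || s == 0) ifelse(obs, 0, NA_real_) else (x - m) / s
  }
  d
}

#' Min-max normalisation to the unit interval
#'
#' Replaces each named numeric column by `(x - min) / (max - min)` over the
#' non-missing entries. Constant columns map to all zeros; missing cells
#' stay missing.
#'
#' @inheritParams zscore_normalize
#' @return The normalised dataset.
#' @export
minmax_normalize <- function(d, columns = NULL) {
  columns <- check_numeric_columns(d, columns)
  for (cn in columns) {
    x <- d$X[[cn]]
    obs <- !is.na(x)
    lo <- min(x[obs]); hi <- max(x[obs])
    d$X[[cn]] <- if (hi == lo) ifelse(obs, 0, NA_real_) else (x - lo) / (hi - lo)
  }
  d
}

check_numeric_columns <- function(d, columns) {
  kinds <- feature_kinds(d)
  if (is.null(columns)) return(names(kinds)[kinds == "numeric"])
  absent <- setdiff(columns, names(kinds))
  if (length(absent)) stop("unknown feature(s): ", paste(absent, collapse = ", "))
  nom <- columns[kinds[columns] == "nominal"]
  if (length(nom)) stop("cannot normalise nominal feature(s): ",
                        paste(nom, collapse = ", "))
  columns
}

#' Drop features with a high missing fraction
#'
#' Removes every feature whose missing fraction is strictly greater than
#' `threshold` (default 0.40, i.e. "more than 40% missing"). The order of
#' the surviving features is preserved and the operation is idempotent.
#'
#' @param d a [cpemm_dataset].
#' @param threshold missing-fraction cut-off in (0, 1).
#' @return The reduced dataset.
#' @export
drop_high_missing <- function(d, threshold = 0.40) {
  stopifnot(threshold > 0, threshold < 1)
  keep <- missing_fraction(d) <= threshold
  if (!any(keep)) stop("all features exceed the missing-data threshold")
  dataset_columns(d, names(d$X)[keep])
}

#' Class-wise imputation of missing values
#'
#' Numeric missing cells are replaced by the mean of the feature among
#' non-missing rows of the same class; nominal missing cells by the
#' within-class mode (ties broken by category declaration order). A class
#' with no observed value in a column falls back to the global mean/mode.
#' Non-missing cells are never altered.
#'
#' @param d a [cpemm_dataset].
#' @return The dataset with no missing cells.
#' @export
impute_classwise <- function(d) {
  for (cn in names(d$X)) {
    x <- d$X[[cn]]
    if (!anyNA(x)) next
    if (all(is.na(x))) stop("feature '", cn, "' is entirely missing; cannot impute")
    if (is.numeric(x)) {
      global <- mean(x, na.rm = TRUE)
      for (cl in levels(d$y)) {
        rows <- d$y == cl
        fill <- mean(x[rows], na.rm = TRUE)
        if (is.nan(fill)) fill <- global
        x[rows & is.na(x)] <- fill
      }
    } else {
      mode_of <- function(v) {
        v <- v[!is.na(v)]
        if (!length(v)) return(NA_character_)
        tab <- table(factor(v, levels = levels(x)))
        names(tab)[which.max(tab)] # which.max keeps declaration order on ties
      }
      global <- mode_of(x)
      for (cl in levels(d$y)) {
        rows <- d$y == cl
        fill <- mode_of(x[rows])
        if (is.na(fill)) fill <- global
        x[rows & is.na(x)] <- fill
      }
    }
    d$X[[cn]] <- x
  }
  d
}

#' Standard preprocessing pipeline
#'
#' Applies, in fixed order: removal of features with more than
#' `drop_threshold` missing data, class-wise imputation, z-score
#' normalisation of all numeric features, and (optionally) min-max
#' normalisation of selected columns. A log of the rules fired is attached
#' as attribute `"log"`.
#'
#' @param d a [cpemm_dataset].
#' @param drop_threshold missing-fraction cut-off (default 0.40).
#' @param minmax_columns numeric features to rescale to `[0, 1]` after the
#'   z-score step (default none).
#' @param zscore apply z-score normalisation to all numeric features
#'   (default `TRUE`).
#' @return The preprocessed dataset.
#' @export
preprocess <- function(d, drop_threshold = 0.40, minmax_columns = character(),
                       zscore = TRUE) {
  log <- character()
  before <- feature_names(d)
  d <- drop_high_missing(d, drop_threshold)
  dropped <- setdiff(before, feature_names(d))
  if (length(dropped)) {
    log <- c(log, sprintf("drop_high_missing(%.2f): removed %s", drop_threshold,
                          paste(dropped, collapse = ", ")))
  } else {
    log <- c(log, sprintf("drop_high_missing(%.2f): nothing removed", drop_threshold))
  }
  n_missing <- sum(missing_mask(d))
  d <- impute_classwise(d)
  log <- c(log, sprintf("impute_classwise: filled %d cells", n_missing))
  if (zscore) {
    d <- zscore_normalize(d)
    log <- c(log, "zscore_normalize: all numeric features")
  }
  if (length(minmax_columns)) {
    d <- minmax_normalize(d, minmax_columns)
    log <- c(log, sprintf("minmax_normalize: %s",
                          paste(minmax_columns, collapse = ", ")))
  }
  attr(d, "log") <- log
  d
}
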