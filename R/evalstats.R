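#' Confusion matrix
#'
#' k x k count matrix with rows = true class, columns = predicted class, in
#' the dataset's class order. Per-class TP/FP/FN/TN are obtained by
#' one-vs-rest collapsing.
#'
#' @param truth true labels (factor or coercible).
#' @param pred predicted labels.
#' @param classes class set fixing row/column order; default the levels of
#'   `truth`.
#' @return A matrix of class `cpemm_confusion`.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  classes <- classes %||% levels(as.factor(truth))
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  if (anyNA(truth) || anyNA(pred)) stop("labels outside the class set")
  m <- table(truth, pred)
  m <- matrix(as.numeric(m), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  structure(m, class = c("cpemm_confusion", "matrix"))
}

ovr_counts <- function(c, class) {
  if (!class %in% rownames(c)) stop("unknown class: ", class)
  tp <- c[class, class]
  fp <- sum(c[, class]) - tp
  fn <- sum(c[class, ]) - tp
  tn <- sum(c) - tp - fp - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Classification metrics from a confusion matrix
#'
#' `accuracy()` is the fraction of correct classifications (the trace over
#' the total). `precision()` is `TP / (TP + FP)` and `recall()` is
#' `TP / (TP + FN)` for the named class, one-vs-rest; both are defined as 0
#' when their denominator is 0. `ovr_accuracy()` is the one-vs-rest
#' accuracy `(TP + TN) / total` used for per-class accuracy tables.
#'
#' @param c a [confusion_matrix()] (for `accuracy()`, alternatively an
#'   evaluation report).
#' @param class class label.
#' @return A number in `[0, 1]`.
#' @export
accuracy <- function(c) {
  if (inherits(c, "cpemm_report")) return(c$accuracy)
  total <- sum(c)
  if (total <= 0) stop("empty confusion matrix")
  sum(diag(unclass(c))) / total
}

#' @rdname accuracy
#' @export
precision <- function(c, class) {
  k <- ovr_counts(c, class)
  if (k$tp + k$fp == 0) 0 else k$tp / (k$tp + k$fp)
}

#' @rdname accuracy
#' @export
recall <- function(c, class) {
  k <- ovr_counts(c, class)
  if (k$tp + k$fn == 0) 0 else k$tp / (k$tp + k$fn)
}

#' @rdname accuracy
#' @export
ovr_accuracy <- function(c, class) {
  k <- ovr_counts(c, class)
  (k$tp + k$tn) / sum(c)
}

#' One-vs-rest ROC AUC
#'
#' The area under the one-vs-rest ROC curve for `class`, computed as the
#' Mann-Whitney probability that a positive instance outscores a negative
#' one, ties counted one half. The value is invariant under any strictly
#' increasing transform of the scores.
#'
#' @param scores numeric vector of scores for `class`, or an n x k score
#'   matrix with a column named `class`.
#' @param y true labels.
#' @param class the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc_ovr <- function(scores, y, class) {
  if (is.matrix(scores)) {
    if (!class %in% colnames(scores)) stop("no score column for class ", class)
    scores <- scores[, class]
  }
  pos <- y == class
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("need both positive and negative instances")
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Press' Q significance test
#'
#' Tests whether `n` correct classifications out of `m` samples over `p`
#' groups exceed chance: `Q = (m - n p)^2 / (m (p - 1))`, referred to a
#' chi-square distribution with one degree of freedom.
#'
#' @param m number of samples (> 0).
#' @param n number of correct classifications (`0 <= n <= m`).
#' @param p number of groups (classes, >= 2).
#' @return An object of class `press_q` with elements `m`, `n`, `p`, `Q`
#'   and `p_value` (upper tail).
#' @examples
#' press_q(100, 90, 3) # Q = 144.5
#' @export
press_q <- function(m, n, p) {
  stopifnot(m > 0, p >= 2, n >= 0, n <= m)
  Q <- (m - n * p)^2 / (m * (p - 1))
  structure(list(m = m, n = n, p = p, Q = Q,
                 p_value = stats::pchisq(Q, df = 1, lower.tail = FALSE)),
            class = "press_q")
}

#' @export
print.press_q <- function(x, ...) {
  cat(sprintf("Press' Q: Q = %.4g (m = %d, n = %d, p = %d), p = %.4g\n",
              x$Q, x$m, x$n, x$p, x$p_value))
  invisible(x)
}

# assemble an evaluation report from pooled predictions
build_report <- function(truth, pred, scores, classes, protocol, seed) {
  cm <- confusion_matrix(truth, pred, classes)
  per_class <- data.frame(
    class = classes,
    accuracy = vapply(classes, function(cl) ovr_accuracy(cm, cl), numeric(1)),
    precision = vapply(classes, function(cl) precision(cm, cl), numeric(1)),
    recall = vapply(classes, function(cl) recall(cm, cl), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  auc <- NULL
  if (!is.null(scores)) {
    per_class$auc <- vapply(classes, function(cl) {
      roc_auc_ovr(scores, truth, cl)
    }, numeric(1))
    auc <- mean(per_class$auc)
  }
  structure(list(confusion = cm, accuracy = accuracy(cm),
                 per_class = per_class, macro_auc = auc,
                 protocol = protocol, seed = seed,
                 n = length(truth)),
            class = "cpemm_report")
}

#' @export
print.cpemm_report <- function(x, ...) {
  cat(sprintf("evaluation (%s, n = %d): accuracy %.4f", x$protocol, x$n,
              x$accuracy))
  if (!is.null(x$macro_auc)) cat(sprintf(", macro AUC %.4f", x$macro_auc))
  cat("\n")
  df <- x$per_class
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Splits the dataset into k stratified folds (per-class fold sizes differ
#' by at most one), predicts each instance exactly once from a model fitted
#' on the other folds, and aggregates the pooled predictions into an
#' evaluation report with per-class precision/recall/one-vs-rest accuracy
#' and one-vs-rest AUCs when the callback supplies scores.
#'
#' @param d a [cpemm_dataset].
#' @param k number of folds (default 5).
#' @param fit_predict callback `function(train_dataset, test_X)` returning
#'   either a label vector or `list(class = labels, scores = matrix)`.
#' @param seed fold-assignment seed.
#' @return An object of class `cpemm_report`.
#' @export
kfold_cv <- function(d, k = 5, fit_predict, seed = 1L) {
  fold_id <- stratified_folds(d$y, k, seed)
  n <- n_instances(d)
  pred <- factor(rep(NA_character_, n), levels = levels(d$y))
  scores <- NULL
  for (f in seq_len(k)) {
    te <- which(fold_id == f)
    out <- fit_predict(dataset_rows(d, which(fold_id != f)),
                       d$X[te, , drop = FALSE])
    if (is.list(out) && !is.factor(out)) {
      pred[te] <- out$class
      if (!is.null(out$scores)) {
        if (is.null(scores)) {
          scores <- matrix(NA_real_, n, ncol(out$scores),
                           dimnames = list(NULL, colnames(out$scores)))
        }
        scores[te, ] <- out$scores
      }
    } else {
      pred[te] <- out
    }
  }
  build_report(d$y, pred, scores, levels(d$y), sprintf("cv%d", k), seed)
}

#' Stratified train/test evaluation
#'
#' Single stratified split; the report is computed on the held-out part
#' only.
#'
#' @param d a [cpemm_dataset].
#' @param test_fraction held-out fraction in (0, 1) (default 0.3).
#' @param fit_predict as in [kfold_cv()].
#' @param seed split seed.
#' @return An object of class `cpemm_report`.
#' @export
train_test_eval <- function(d, test_fraction = 0.3, fit_predict, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  test_idx <- integer(0)
  with_seed(seed, {
    for (cl in levels(d$y)) {
      idx <- which(d$y == cl)
      n_te <- round(length(idx) * test_fraction)
      n_te <- min(max(n_te, 1L), length(idx) - 1L)
      test_idx <- c(test_idx, idx[sample.int(length(idx), n_te)])
    }
  })
  test_idx <- sort(test_idx)
  out <- fit_predict(dataset_rows(d, setdiff(seq_len(n_instances(d)), test_idx)),
                     d$X[test_idx, , drop = FALSE])
  if (is.list(out) && !is.factor(out)) {
    pred <- out$class; scores <- out$scores
  } else {
    pred <- out; scores <- NULL
  }
  build_report(d$y[test_idx], pred, scores, levels(d$y), "train_test", seed)
}

#' Phase I base-classifier comparison with key-attribute ablation
#'
#' Cross-validates every requested base-learner kind on the full dataset
#' and on the dataset with the named key attributes removed (probing each
#' classifier's sensitivity when dominant attributes, such as the clinical
#' dementia rating, are absent). The winner is the kind with the highest
#' mean overall accuracy across both conditions, ties going to the
#' fewer-parameter kind (`nb < c45 < rf < svm_rbf`).
#'
#' @param d a fully imputed [cpemm_dataset].
#' @param kinds character vector of learner kinds to compare.
#' @param ablate feature names to remove in the ablated condition (default
#'   none, making the two conditions identical).
#' @param seed fold seed (shared across kinds and conditions).
#' @param k folds (default 5).
#' @param n_trees random-forest size for the `"rf"` rows (default 600).
#' @return A data.frame with one row per kind x condition: overall
#'   accuracy, per-class recall columns, and attribute `"winner"`.
#' @export
compare_base_classifiers <- function(d, kinds, ablate = character(),
                                     seed = 1L, k = 5, n_trees = 600) {
  if (!length(kinds)) stop("no learner kinds given")
  absent <- setdiff(ablate, feature_names(d))
  if (length(absent)) stop("ablated column(s) absent: ",
                           paste(absent, collapse = ", "))
  conditions <- list(full = d)
  conditions$ablated <- if (length(ablate)) {
    dataset_columns(d, setdiff(feature_names(d), ablate))
  } else d
  rows <- list()
  for (kind in kinds) {
    cfg <- learner_config(kind, n_trees = n_trees, seed = seed)
    for (cond in names(conditions)) {
      dc <- conditions[[cond]]
      rep <- kfold_cv(dc, k = k, seed = seed, fit_predict = function(tr, te) {
        predict(fit_base(cfg, tr), te)
      })
      row <- data.frame(kind = kind, condition = cond,
                        accuracy = rep$accuracy, stringsAsFactors = FALSE)
      for (i in seq_len(nrow(rep$per_class))) {
        row[[paste0("recall_", rep$per_class$class[i])]] <-
          rep$per_class$recall[i]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  means <- tapply(out$accuracy, out$kind, mean)
  complexity <- c(nb = 1, c45 = 2, rf = 3, svm_rbf = 4)
  cand <- names(means)[means == max(means)]
  attr(out, "winner") <- cand[order(complexity[cand])][1]
  out
}
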