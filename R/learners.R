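#' Base learner configuration
#'
#' The four base classifiers share one fit/predict/score contract:
#' a C4.5-style decision tree (`"c45"`: binary entropy splits,
#' pessimistic-error pruning, native missing-value handling), Gaussian /
#' Laplace-smoothed naive Bayes (`"nb"`), random forest (`"rf"`, default
#' 600 trees, where the out-of-bag error was observed to level off), and an
#' RBF-kernel support vector machine (`"svm_rbf"`).
#'
#' @param kind one of `"c45"`, `"nb"`, `"rf"`, `"svm_rbf"`.
#' @param n_trees random-forest ensemble size (default 600).
#' @param C,gamma RBF-SVM cost and kernel width; `gamma = NULL` defaults to
#'   1/d at fit time. Tune with [grid_search_svm()].
#' @param minbucket,cf,prune C4.5 controls: minimum leaf size, pruning
#'   confidence, and whether to prune (defaults 2, 0.25, TRUE).
#' @param seed integer used to derive all fitting randomness.
#' @return An object of class `cpemm_learner_config`.
#' @export
learner_config <- function(kind = c("c45", "nb", "rf", "svm_rbf"),
                           n_trees = 600, C = 1, gamma = NULL,
                           minbucket = 2, cf = 0.25, prune = TRUE,
                           seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(C > 0, is.null(gamma) || gamma >= 0, n_trees >= 1, minbucket >= 1,
            cf > 0, cf < 1)
  structure(list(kind = kind, n_trees = as.integer(n_trees), C = C,
                 gamma = gamma, minbucket = as.integer(minbucket), cf = cf,
                 prune = isTRUE(prune), seed = as.integer(seed)),
            class = "cpemm_learner_config")
}

#' @export
print.cpemm_learner_config <- function(x, ...) {
  extra <- switch(x$kind,
    rf = sprintf(" (n_trees = %d)", x$n_trees),
    svm_rbf = sprintf(" (C = %g, gamma = %s)", x$C,
                      if (is.null(x$gamma)) "1/d" else format(x$gamma)),
    c45 = sprintf(" (minbucket = %d, cf = %.2f, prune = %s)", x$minbucket,
                  x$cf, x$prune),
    "")
  cat("learner_config: ", x$kind, extra, "\n", sep = "")
  invisible(x)
}

#' Radial basis function kernel
#'
#' `k(xi, xj) = exp(-gamma * ||xi - xj||^2)`, the kernel the RBF-SVM uses to
#' define its separating hyperplane.
#'
#' @param xi,xj equal-length numeric vectors.
#' @param gamma non-negative kernel width.
#' @return A value in `(0, 1]`.
#' @examples
#' rbf_kernel(c(0, 0), c(1, 0), gamma = 1) # exp(-1)
#' @export
rbf_kernel <- function(xi, xj, gamma) {
  if (length(xi) != length(xj)) stop("xi and xj must have equal length")
  stopifnot(gamma >= 0)
  exp(-gamma * sum((xi - xj)^2))
}

# encode a dataset's feature block for the compiled tree: numeric columns
# pass through, nominal columns become 1-based category codes (NA preserved)
c45_encode <- function(X) {
  ncat <- integer(ncol(X))
  M <- matrix(NA_real_, nrow(X), ncol(X))
  for (j in seq_along(X)) {
    col <- X[[j]]
    if (is.factor(col)) {
      ncat[j] <- nlevels(col)
      M[, j] <- as.numeric(as.integer(col))
    } else {
      M[, j] <- as.numeric(col)
    }
  }
  colnames(M) <- names(X)
  list(M = M, ncat = ncat)
}

# one-hot design matrix for the kernel/SVM pathway
onehot_encode <- function(X) {
  cols <- lapply(names(X), function(nm) {
    col <- X[[nm]]
    if (is.factor(col)) {
      out <- sapply(levels(col), function(lv) as.numeric(col == lv))
      colnames(out) <- paste0(nm, "=", levels(col))
      out
    } else {
      out <- matrix(as.numeric(col), ncol = 1)
      colnames(out) <- nm
      out
    }
  })
  do.call(cbind, cols)
}

#' Fit a base classifier on a feature subset
#'
#' Trains a model of `cfg$kind` on the columns of `d` selected by `subset`.
#' All kinds are deterministic given `cfg$seed`. Learners other than the
#' C4.5 tree require a fully imputed dataset; the tree handles missing
#' values natively.
#'
#' @param cfg a [learner_config()].
#' @param d a [cpemm_dataset].
#' @param subset features to train on: a [feature_subset()], a logical mask,
#'   a character vector of names, or `NULL` for all features.
#' @return An object of class `cpemm_model` with [predict()] and
#'   [predict_scores()] methods.
#' @export
fit_base <- function(cfg, d, subset = NULL) {
  stopifnot(inherits(cfg, "cpemm_learner_config"), inherits(d, "cpemm_dataset"))
  cols <- resolve_subset(d, subset)
  if (!length(cols)) stop("empty feature subset")
  if (nlevels(droplevels(d$y)) < 2L) stop("training data contains a single class")
  X <- d$X[, cols, drop = FALSE]
  if (cfg$kind != "c45" && anyNA(X)) {
    stop("learner '", cfg$kind, "' requires imputed data (no missing cells)")
  }
  classes <- levels(d$y)
  fit <- switch(cfg$kind,
    c45 = {
      enc <- c45_encode(X)
      tree <- .c45_fit_cpp(enc$M, as.integer(d$y) - 1L, enc$ncat,
                           length(classes), cfg$minbucket, 30L, cfg$prune,
                           cfg$cf)
      list(tree = tree, ncat = enc$ncat)
    },
    nb = with_seed(cfg$seed, e1071::naiveBayes(x = X, y = d$y, laplace = 1)),
    rf = with_seed(cfg$seed,
      randomForest::randomForest(x = X, y = d$y, ntree = cfg$n_trees)),
    svm_rbf = {
      M <- onehot_encode(X)
      gamma <- cfg$gamma %||% (1 / ncol(M))
      with_seed(cfg$seed,
        e1071::svm(x = M, y = d$y, kernel = "radial", cost = cfg$C,
                   gamma = gamma, probability = TRUE))
    })
  structure(list(kind = cfg$kind, fit = fit, classes = classes,
                 features = cols,
                 feature_levels = lapply(X, levels),
                 priors = as.vector(prop.table(table(d$y))),
                 cfg = cfg),
            class = "cpemm_model")
}

# normalise the many subset notations to a character vector of names
resolve_subset <- function(d, subset) {
  if (is.null(subset)) return(feature_names(d))
  if (inherits(subset, "feature_subset")) subset <- subset$mask
  if (is.logical(subset)) {
    if (length(subset) != length(feature_names(d))) {
      stop("mask length does not match the number of features")
    }
    return(feature_names(d)[subset])
  }
  as.character(subset)
}

# check and arrange newdata columns for a fitted model
model_newdata <- function(object, newdata) {
  if (inherits(newdata, "cpemm_dataset")) newdata <- newdata$X
  stopifnot(is.data.frame(newdata))
  absent <- setdiff(object$features, names(newdata))
  if (length(absent)) {
    stop("newdata lacks feature(s): ", paste(absent, collapse = ", "))
  }
  X <- newdata[, object$features, drop = FALSE]
  for (nm in names(X)) {
    lv <- object$feature_levels[[nm]]
    if (!is.null(lv)) X[[nm]] <- factor(as.character(X[[nm]]), levels = lv)
  }
  X
}

#' Class-membership scores from a fitted base model
#'
#' Returns an n x k matrix of non-negative scores whose rows sum to one,
#' ordered by the model's class set. [predict.cpemm_model()] is the row-wise
#' argmax of these scores, ties broken by class-set order, so the two code
#' paths always agree.
#'
#' @param object a fitted `cpemm_model` or `cpemm_bagged` ensemble.
#' @param newdata data.frame (or [cpemm_dataset]) with the model's features.
#' @param ... unused.
#' @return An n x k numeric matrix with `colnames` the class set.
#' @export
predict_scores <- function(object, newdata, ...) UseMethod("predict_scores")

#' @export
predict_scores.cpemm_model <- function(object, newdata, ...) {
  X <- model_newdata(object, newdata)
  k <- length(object$classes)
  if (nrow(X) == 0L) {
    return(matrix(numeric(0), 0, k, dimnames = list(NULL, object$classes)))
  }
  scores <- switch(object$kind,
    c45 = {
      enc <- c45_encode(X)
      .c45_predict_cpp(object$fit$tree, enc$M)$prob
    },
    nb = {
      p <- predict(object$fit, X, type = "raw")
      p[!is.finite(p)] <- 0
      p
    },
    rf = {
      p <- predict(object$fit, X, type = "prob")
      p[, object$classes, drop = FALSE]
    },
    svm_rbf = {
      M <- onehot_encode(X)
      pr <- predict(object$fit, M, probability = TRUE)
      p <- attr(pr, "probabilities")
      p[, object$classes, drop = FALSE]
    })
  scores <- as.matrix(scores)
  dimnames(scores) <- list(NULL, object$classes)
  rs <- rowSums(scores)
  zero <- rs <= 0
  if (any(zero)) { scores[zero, ] <- 1 / k; rs[zero] <- 1 }
  scores / rs
}

#' Predict class labels
#'
#' @param object a fitted `cpemm_model`.
#' @param newdata data.frame (or [cpemm_dataset]) with the model's features.
#' @param ... unused.
#' @return A factor over the model's class set, one label per row.
#' @export
predict.cpemm_model <- function(object, newdata, ...) {
  s <- predict_scores(object, newdata)
  scores_to_labels(s, object$classes)
}

scores_to_labels <- function(scores, classes) {
  if (nrow(scores) == 0L) return(factor(character(0), levels = classes))
  idx <- max.col(scores, ties.method = "first")
  factor(classes[idx], levels = classes)
}

#' Grid search for RBF-SVM hyper-parameters
#'
#' Evaluates every `(C, gamma)` pair on a stratified k-fold cross-validation
#' and returns the pair with the highest mean accuracy; ties are broken by
#' the smaller `C`, then the smaller `gamma`.
#'
#' @param d a fully imputed [cpemm_dataset].
#' @param C_grid,gamma_grid candidate values (defaults: the standard
#'   log2-spaced RBF grid `C = 2^(-5, -3, ..., 15)`,
#'   `gamma = 2^(-15, -13, ..., 3)`).
#' @param folds number of cross-validation folds (default 5).
#' @param seed fold-assignment seed.
#' @return A list with `C`, `gamma` and the full accuracy `table`.
#' @export
grid_search_svm <- function(d, C_grid = 2^seq(-5, 15, 2),
                            gamma_grid = 2^seq(-15, 3, 2), folds = 5,
                            seed = 1L) {
  if (!length(C_grid) || !length(gamma_grid)) stop("empty hyper-parameter grid")
  fold_id <- stratified_folds(d$y, folds, seed)
  grid <- expand.grid(C = sort(C_grid), gamma = sort(gamma_grid))
  grid$accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    cfg <- learner_config("svm_rbf", C = grid$C[g], gamma = grid$gamma[g],
                          seed = seed)
    acc <- vapply(seq_len(folds), function(f) {
      tr <- dataset_rows(d, which(fold_id != f))
      te <- which(fold_id == f)
      m <- fit_base(cfg, tr)
      mean(predict(m, d$X[te, , drop = FALSE]) == d$y[te])
    }, numeric(1))
    grid$accuracy[g] <- mean(acc)
  }
  best <- grid[order(-grid$accuracy, grid$C, grid$gamma), ][1, ]
  list(C = best$C, gamma = best$gamma, table = grid)
}
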