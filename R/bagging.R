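#' Bootstrap sample of a dataset
#'
#' Draws `n_instances` rows i.i.d. with replacement; deterministic given
#' `seed`.
#'
#' @param d a [cpemm_dataset].
#' @param seed integer sampling seed.
#' @return A [cpemm_dataset] with the same number of rows.
#' @export
bootstrap_sample <- function(d, seed) {
  n <- n_instances(d)
  if (n < 1L) stop("empty dataset")
  idx <- with_seed(seed, sample.int(n, n, replace = TRUE))
  dataset_rows(d, idx)
}

#' Fit a bagged ensemble of one base-learner kind
#'
#' Trains `B` models of the same kind, each on an independent bootstrap
#' replicate of `d` restricted to `subset`; member seeds are derived
#' deterministically from `seed`. Labels are combined by majority vote
#' (ties broken by the higher empirical class frequency in the training
#' data, then class-set order); scores for ROC analysis are the mean of the
#' member score rows.
#'
#' @param cfg a [learner_config()].
#' @param d a [cpemm_dataset].
#' @param subset features to train on (see [fit_base()]).
#' @param B ensemble size (default 10 bagging rounds).
#' @param seed integer master seed.
#' @return An object of class `cpemm_bagged`.
#' @export
fit_bagged <- function(cfg, d, subset = NULL, B = 10, seed = 1L) {
  stopifnot(B >= 1)
  cols <- resolve_subset(d, subset)
  if (!length(cols)) stop("empty feature subset")
  # single-class bootstrap replicates are possible on tiny data; resample
  # until at least two classes are present (bounded retries, deterministic)
  members <- vector("list", B)
  for (i in seq_len(B)) {
    for (try in 0:20) {
      bd <- bootstrap_sample(d, derive_seed(seed, i * 131L + try))
      if (nlevels(droplevels(bd$y)) >= 2L) break
    }
    mcfg <- cfg
    mcfg$seed <- derive_seed(seed, 100000L + i)
    bd$y <- factor(bd$y, levels = levels(d$y))
    members[[i]] <- fit_base(mcfg, bd, cols)
  }
  structure(list(members = members, B = as.integer(B), base_cfg = cfg,
                 classes = levels(d$y),
                 priors = as.vector(prop.table(table(d$y))),
                 features = cols, seed = as.integer(seed)),
            class = "cpemm_bagged")
}

#' @export
print.cpemm_bagged <- function(x, ...) {
  cat(sprintf("cpemm_bagged: %d x %s on %d features\n", x$B, x$base_cfg$kind,
              length(x$features)))
  invisible(x)
}

#' Majority vote over label vectors
#'
#' @param votes list of equal-length factors (one per voter).
#' @param classes class set defining label order; default the union of vote
#'   levels.
#' @param priors optional per-class tie-break weights (e.g. training class
#'   frequencies); ties that survive the priors fall back to class order.
#' @return A factor of plurality labels.
#' @export
majority_vote <- function(votes, classes = NULL, priors = NULL) {
  if (!length(votes)) stop("no voters")
  lens <- lengths(votes)
  if (length(unique(lens)) != 1L) stop("vote vectors must have equal length")
  classes <- classes %||% sort(unique(unlist(lapply(votes, as.character))))
  k <- length(classes)
  if (is.null(priors)) priors <- rep(0, k)
  counts <- matrix(0, lens[1], k, dimnames = list(NULL, classes))
  for (v in votes) {
    vi <- match(as.character(v), classes)
    if (anyNA(vi)) stop("vote outside the class set")
    counts[cbind(seq_along(vi), vi)] <- counts[cbind(seq_along(vi), vi)] + 1
  }
  # add a sub-vote prior bonus so ties resolve by class frequency first,
  # then (max.col "first") by class-set order
  if (nrow(counts) > 0) {
    counts <- counts + matrix(priors, nrow(counts), k, byrow = TRUE) * 0.5
  }
  idx <- max.col(counts, ties.method = "first")
  factor(classes[idx], levels = classes)
}

#' @export
predict.cpemm_bagged <- function(object, newdata, ...) {
  votes <- lapply(object$members, predict, newdata = newdata)
  majority_vote(votes, classes = object$classes, priors = object$priors)
}

#' @export
predict_scores.cpemm_bagged <- function(object, newdata, ...) {
  acc <- NULL
  for (m in object$members) {
    s <- predict_scores(m, newdata)
    acc <- if (is.null(acc)) s else acc + s
  }
  acc / object$B
}
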