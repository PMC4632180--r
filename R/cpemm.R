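#' CPEMM: ensemble Merit Merge feature selection
#'
#' The one-call pipeline: a binary Particle Swarm Optimisation search over
#' feature subsets, each candidate scored by the cross-validated accuracy of
#' a bagged base-classifier ensemble (Phase II), followed by the three-case
#' Merit Merge consolidation of the merit-ranked subsets (Phase III). The
#' result carries the selected feature set, the refit bagged ensemble, the
#' evaluation report and the full decision log.
#'
#' `cpemm()` is generic: give it a [cpemm_dataset], or a formula plus a
#' data.frame (`class ~ .` style).
#'
#' @param x a [cpemm_dataset], or a model formula.
#' @param ... passed between methods.
#' @param learner base-learner configuration ([learner_config()]); the C4.5
#'   tree is the default and the recommended judge.
#' @param pso Phase II search configuration ([pso_config()]).
#' @param merge Phase III configuration ([merge_config()]).
#' @param B bagging rounds for the final refit ensemble (default 10).
#' @param seed one master seed that determinises the whole pipeline
#'   (search, merit folds, evaluation folds, refit).
#' @return An object of class `cpemm`; see [print.cpemm()],
#'   [summary.cpemm()], [predict.cpemm()], [plot.cpemm()],
#'   [selected_features()].
#' @examples
#' spec <- synthetic_spec(class_counts = c(NL = 30, MCI = 40, AD = 30),
#'                        n_informative = 2, n_redundant = 1, n_noise = 3)
#' gen <- generate_synthetic(spec)
#' fit <- cpemm(gen$dataset, pso = pso_config(iterations = 3, swarm_size = 5,
#'                                            folds = 2, B = 2), seed = 1)
#' selected_features(fit)
#' @export
cpemm <- function(x, ...) UseMethod("cpemm")

#' @rdname cpemm
#' @export
cpemm.cpemm_dataset <- function(x, learner = learner_config("c45"),
                                pso = pso_config(), merge = merge_config(),
                                B = 10, seed = 1L, ...) {
  cl <- match.call()
  pso$seed <- derive_seed(seed, 1L)
  merge$seed <- derive_seed(seed, 2L)
  base_pso <- pso
  rerun <- function(iterations) {
    cfg <- base_pso
    cfg$iterations <- as.integer(iterations)
    run_pso(x, cfg, learner)
  }
  ranking <- run_pso(x, pso, learner)
  mm <- merit_merge(ranking, x, learner = learner, cfg = merge,
                    rerun = rerun, B = B)
  structure(list(call = cl, dataset = x, learner = learner, pso = pso,
                 merge_cfg = merge, seed = as.integer(seed),
                 ranking = mm$ranking, selected = mm$selected,
                 evaluations = mm$evaluations, decisions = mm$decisions,
                 final_model = mm$final_model, report = mm$report,
                 schedule_exhausted = mm$schedule_exhausted),
            class = "cpemm")
}

#' @rdname cpemm
#' @param data data.frame holding the variables of the formula.
#' @param label name to record for the class column (taken from the formula
#'   response).
#' @export
cpemm.formula <- function(x, data, ..., label = NULL) {
  mf <- stats::model.frame(x, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  label <- label %||% deparse(x[[2]])
  X <- mf[setdiff(names(mf), label)]
  d <- cpemm_dataset(X, y, label = label)
  out <- cpemm(d, ...)
  out$call <- match.call()
  out
}

#' Selected feature names of a CPEMM fit
#'
#' @param object a `cpemm` fit (or `cpemm_merge` result).
#' @return Character vector of selected feature names.
#' @export
selected_features <- function(object) {
  mask <- object$selected$mask
  names(mask)[mask] %||% which(mask)
}

#' @export
print.cpemm <- function(x, ...) {
  cat("CPEMM feature selection\n")
  cat("call: "); print(x$call)
  cat(sprintf("learner: %s | PSO: %d iterations x %d particles | seed %d\n",
              x$learner$kind, x$pso$iterations, x$pso$swarm_size, x$seed))
  cat(sprintf("selected %d/%d features (accuracy %.4f, %s protocol):\n",
              sum(x$selected$mask), length(x$selected$mask),
              accuracy(x$report), x$merge_cfg$protocol))
  cat(" ", paste(selected_features(x), collapse = ", "), "\n")
  invisible(x)
}

#' Summarise a CPEMM fit
#'
#' Prints the fit header plus the search statistics, the full evaluation
#' report and the Merit Merge decision log.
#'
#' @param object a `cpemm` fit.
#' @param ... unused.
#' @return An object of class `summary.cpemm`.
#' @export
summary.cpemm <- function(object, ...) {
  structure(list(fit = object), class = "summary.cpemm")
}

#' @export
print.summary.cpemm <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nSearch: ", f$ranking$n_evaluated, " distinct subsets evaluated; ",
      "gbest merit ", sprintf("%.4f", f$ranking$gbest$merit), "\n", sep = "")
  cat("\nEvaluation report:\n")
  print(f$report)
  cat("\nMerit Merge decisions:\n")
  print(f$decisions[, c("step", "case", "action", "n_features", "accuracy",
                        "note")], row.names = FALSE)
  invisible(x)
}

#' Predict with the final CPEMM ensemble
#'
#' @param object a `cpemm` fit.
#' @param newdata data.frame (or [cpemm_dataset]) containing at least the
#'   selected features.
#' @param type `"class"` for labels, `"scores"` for the class-score matrix.
#' @param ... unused.
#' @export
predict.cpemm <- function(object, newdata, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  if (type == "class") predict(object$final_model, newdata)
  else predict_scores(object$final_model, newdata)
}

#' Plot a CPEMM fit
#'
#' Left panel: global-best merit over the PSO iterations. Right panel:
#' merit profile of the final ranking with the accuracy of every subset
#' evaluated during the Merit Merge walk overlaid.
#'
#' @param x a `cpemm` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cpemm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$ranking$trace), x$ranking$trace, type = "s",
                 xlab = "PSO iteration", ylab = "gbest merit",
                 main = "Swarm search", ...)
  df <- as.data.frame(x$ranking)
  graphics::plot(seq_len(nrow(df)), df$merit, type = "b", pch = 16,
                 xlab = "rank", ylab = "merit / accuracy",
                 ylim = range(c(df$merit, x$evaluations$accuracy)),
                 main = "Ranking and walk")
  idx <- match(x$evaluations$mask, df$mask)
  ok <- !is.na(idx)
  graphics::points(idx[ok], x$evaluations$accuracy[ok], col = 2, pch = 4)
  graphics::legend("bottomleft", legend = c("merit", "walk accuracy"),
                   col = c(1, 2), pch = c(16, 4), bty = "n")
  invisible(x)
}
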