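#' Merit Merge configuration
#'
#' Controls the three-case consolidation of a merit-ranked subset list:
#' Case 1 (equal-merit subsets are evaluated individually and as a merged
#' union, the union kept only if it strictly improves accuracy), Case 2
#' (if more than `top_tie_fraction` of the ranking ties at the top merit,
#' the PSO search is re-run at the next iteration count in the schedule),
#' and Case 3 (the walk stops at the first successive subset whose merit
#' drops by more than `drop_threshold`).
#'
#' @param equal_merit_tol absolute tolerance defining "equal merit"
#'   (default 1e-6).
#' @param drop_threshold absolute merit drop defining "much lower merit"
#'   (default 0.05).
#' @param top_tie_fraction fraction of the ranking that must tie at the top
#'   to trigger Case 2 (default 0.5).
#' @param iteration_schedule strictly increasing PSO iteration counts for
#'   Case 2 escalation (default `c(60, 80, 100)`).
#' @param protocol accuracy-evaluation protocol inside the walk and for the
#'   final report: `"cv5"` (stratified 5-fold CV) or `"train_test"`.
#' @param test_fraction held-out fraction for `"train_test"` (default 0.3).
#' @param seed evaluation seed (kept distinct from the merit seed so
#'   selection does not reuse the search's resampling splits).
#' @return An object of class `cpemm_merge_config`.
#' @export
merge_config <- function(equal_merit_tol = 1e-6, drop_threshold = 0.05,
                         top_tie_fraction = 0.5,
                         iteration_schedule = c(60, 80, 100),
                         protocol = c("cv5", "train_test"),
                         test_fraction = 0.3, seed = 1L) {
  protocol <- match.arg(protocol)
  stopifnot(drop_threshold > 0, drop_threshold <= 1, # 1 disables Case 3
            equal_merit_tol >= 0,
            all(diff(iteration_schedule) > 0),
            test_fraction > 0, test_fraction < 1)
  structure(list(equal_merit_tol = equal_merit_tol,
                 drop_threshold = drop_threshold,
                 top_tie_fraction = top_tie_fraction,
                 iteration_schedule = as.integer(iteration_schedule),
                 protocol = protocol, test_fraction = test_fraction,
                 seed = as.integer(seed)),
            class = "cpemm_merge_config")
}

#' Merge two feature subsets
#'
#' Bitwise OR of the inclusion masks; the result has unset merit and origin
#' `"merged"`.
#'
#' @param a,b [feature_subset()] objects with equal mask length.
#' @return A merged `feature_subset`.
#' @export
merge_subsets <- function(a, b) {
  stopifnot(inherits(a, "feature_subset"), inherits(b, "feature_subset"))
  if (length(a$mask) != length(b$mask)) stop("mask length mismatch")
  feature_subset(a$mask | b$mask, origin = "merged")
}

# default Phase III evaluator: protocol accuracy (with full report) of the
# bagged base classifier on one subset -- the same form of model the
# pipeline finally deploys, and a lower-variance judge than a single tree
protocol_evaluator <- function(d, learner, cfg, B = 10) {
  fp <- function(train_d, test_X) {
    m <- fit_bagged(learner, train_d, B = B, seed = derive_seed(cfg$seed, 53L))
    list(class = predict(m, test_X), scores = predict_scores(m, test_X))
  }
  function(subset) {
    ds <- dataset_columns(d, resolve_subset(d, subset))
    if (cfg$protocol == "cv5") {
      kfold_cv(ds, k = 5, fit_predict = fp, seed = derive_seed(cfg$seed, 97L))
    } else {
      train_test_eval(ds, test_fraction = cfg$test_fraction, fit_predict = fp,
                      seed = derive_seed(cfg$seed, 97L))
    }
  }
}

#' Merit Merge consolidation of a subset ranking
#'
#' Walks the merit-ranked subset list top-down, evaluating subsets with the
#' base classifier under the configured protocol, applying the three cases
#' described in [merge_config()], and returning the accuracy-best feature
#' set together with the refit final ensemble, the evaluation report and an
#' audit log of every decision.
#'
#' @param ranking a [run_pso()] result (class `subset_ranking`).
#' @param d the preprocessed [cpemm_dataset] the ranking was computed on.
#' @param learner base classifier for Phase III evaluation. The C4.5 tree is
#'   the default; `"nb"` and `"rf"` are supported alternatives, and
#'   `"svm_rbf"` is accepted with a warning (its recall on this kind of
#'   multiclass clinical data is typically too low to act as the judge).
#' @param cfg a [merge_config()].
#' @param rerun optional callback `function(iterations)` returning a fresh
#'   `subset_ranking`; used by Case 2 escalation.
#' @param evaluator optional replacement for the accuracy evaluator,
#'   `function(subset)` returning either a number in `[0, 1]` or an
#'   evaluation report; intended for tests.
#' @param B bagging rounds for the refit final model (default 10).
#' @return An object of class `cpemm_merge` with elements `selected`,
#'   `group_selected`, `evaluations`, `decisions`, `final_model`, `report`
#'   and `schedule_exhausted`.
#' @export
merit_merge <- function(ranking, d, learner = learner_config("c45"),
                        cfg = merge_config(), rerun = NULL, evaluator = NULL,
                        B = 10) {
  stopifnot(inherits(ranking, "subset_ranking"))
  if (!length(ranking$subsets)) stop("empty ranking")
  if (inherits(learner, "cpemm_learner_config") && learner$kind == "svm_rbf") {
    warning("svm_rbf as the Phase III judge is allowed but not recommended")
  }
  reports <- new.env(parent = emptyenv())
  eval_fun <- evaluator %||% protocol_evaluator(d, learner, cfg, B = B)
  acc_of <- function(subset) {
    key <- mask_key(subset$mask)
    hit <- reports[[key]]
    if (!is.null(hit)) return(hit)
    r <- eval_fun(subset)
    r <- list(accuracy = if (is.numeric(r)) as.numeric(r) else accuracy(r),
              report = if (is.numeric(r)) NULL else r)
    reports[[key]] <- r
    r
  }

  decisions <- list()
  evals <- list()
  log_decision <- function(step, case, action, mask, merit, acc, note = "") {
    decisions[[length(decisions) + 1L]] <<- data.frame(
      step = step, case = case, action = action, mask = mask_key(mask),
      n_features = sum(mask), merit = merit, accuracy = acc, note = note,
      stringsAsFactors = FALSE)
  }
  log_eval <- function(subset, acc) {
    evals[[length(evals) + 1L]] <<- list(subset = subset, accuracy = acc)
  }

  schedule_exhausted <- FALSE
  sched_pos <- 1L

  # Case 2: re-search at higher iteration counts while the top merit floods
  # more than top_tie_fraction of the ranking
  repeat {
    merits <- vapply(ranking$subsets, function(s) s$merit, numeric(1))
    n_top <- sum(abs(merits - merits[1]) <= cfg$equal_merit_tol)
    if (n_top <= cfg$top_tie_fraction * length(merits)) break
    if (is.null(rerun) || sched_pos >= length(cfg$iteration_schedule)) {
      if (length(merits) > 1) {
        schedule_exhausted <- TRUE
        log_decision(0L, "case2", "schedule_exhausted",
                     ranking$subsets[[1]]$mask, merits[1], NA_real_,
                     "top tie unresolved; continuing with best-so-far")
      }
      break
    }
    sched_pos <- sched_pos + 1L
    iters <- cfg$iteration_schedule[sched_pos]
    log_decision(0L, "case2", "rerun_pso", ranking$subsets[[1]]$mask,
                 merits[1], NA_real_,
                 sprintf("top tie %d/%d; iterations -> %d", n_top,
                         length(merits), iters))
    ranking <- rerun(iters)
    if (!length(ranking$subsets)) stop("rerun returned an empty ranking")
  }

  subs <- ranking$subsets
  merits <- vapply(subs, function(s) s$merit, numeric(1))
  step <- 0L
  group_id <- 0L
  group_of <- list()     # mask key -> group id (rejected-merge groups only)
  group_members <- list() # group id -> list of subsets
  i <- 1L
  while (i <= length(subs)) {
    step <- step + 1L
    # maximal run of equal merit starting at i
    j <- i
    while (j < length(subs) &&
           abs(merits[j + 1L] - merits[i]) <= cfg$equal_merit_tol) {
      j <- j + 1L
    }
    group <- subs[i:j]
    group_id <- group_id + 1L
    accs <- numeric(length(group))
    for (g in seq_along(group)) {
      r <- acc_of(group[[g]])
      accs[g] <- r$accuracy
      log_eval(group[[g]], r$accuracy)
      log_decision(step, if (length(group) > 1) "case1" else "walk",
                   "evaluate_individual", group[[g]]$mask, merits[i], r$accuracy)
    }
    if (length(group) > 1) {
      merged <- Reduce(merge_subsets, group)
      rm_ <- acc_of(merged)
      log_eval(merged, rm_$accuracy)
      if (rm_$accuracy > max(accs)) {
        log_decision(step, "case1", "merge_accepted", merged$mask, NA_real_,
                     rm_$accuracy,
                     sprintf("merged accuracy %.4f > best individual %.4f",
                             rm_$accuracy, max(accs)))
      } else {
        log_decision(step, "case1", "merge_rejected", merged$mask, NA_real_,
                     rm_$accuracy,
                     sprintf("merged accuracy %.4f <= best individual %.4f; individual subsets kept",
                             rm_$accuracy, max(accs)))
        for (g in group) group_of[[mask_key(g$mask)]] <- group_id
        group_members[[group_id]] <- group
      }
    }
    # Case 3: stop if the next subset's merit is much lower
    if (j < length(subs) &&
        merits[i] - merits[j + 1L] > cfg$drop_threshold) {
      log_decision(step, "case3", "terminate", subs[[j + 1L]]$mask,
                   merits[j + 1L], NA_real_,
                   sprintf("merit drop %.4f > %.4f", merits[i] - merits[j + 1L],
                           cfg$drop_threshold))
      break
    }
    i <- j + 1L
  }

  acc_vec <- vapply(evals, function(e) e$accuracy, numeric(1))
  best <- which.max(acc_vec)
  selected <- evals[[best]]$subset
  best_key <- mask_key(selected$mask)
  report <- reports[[best_key]]$report
  if (is.null(report) && is.null(evaluator)) {
    report <- acc_of(selected)$report
  }
  final_model <- if (is.null(evaluator)) {
    fit_bagged(learner, d, selected, B = B, seed = derive_seed(cfg$seed, 31L))
  } else NULL

  # Case 1 non-merged outcome: when the winner comes from an equal-merit
  # group whose merge was rejected, all the group's individuals are the
  # relevant feature sets; otherwise just the winner
  gid <- group_of[[best_key]]
  group_selected <- if (!is.null(gid)) group_members[[gid]] else list(selected)

  structure(list(selected = selected, group_selected = group_selected,
                 evaluations = data.frame(
                   mask = vapply(evals, function(e) mask_key(e$subset$mask),
                                 character(1)),
                   n_features = vapply(evals, function(e) sum(e$subset$mask),
                                       numeric(1)),
                   origin = vapply(evals, function(e) e$subset$origin,
                                   character(1)),
                   accuracy = acc_vec, stringsAsFactors = FALSE),
                 decisions = do.call(rbind, decisions),
                 final_model = final_model, report = report,
                 schedule_exhausted = schedule_exhausted,
                 ranking = ranking, learner = learner, config = cfg),
            class = "cpemm_merge")
}

#' @export
print.cpemm_merge <- function(x, ...) {
  cat("Merit Merge result\n")
  cat(sprintf("selected subset (%s): %d features, accuracy %.4f\n",
              x$selected$origin, sum(x$selected$mask),
              max(x$evaluations$accuracy)))
  nm <- names(x$selected$mask)
  if (!is.null(nm)) cat(" ", paste(nm[x$selected$mask], collapse = ", "), "\n")
  cat(sprintf("%d subsets evaluated; %d decisions logged%s\n",
              nrow(x$evaluations), nrow(x$decisions),
              if (x$schedule_exhausted) " (Case 2 schedule exhausted)" else ""))
  invisible(x)
}
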