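nm6 <- paste0("f", 1:6)

test_that("subset union is a bitwise OR with merged provenance", {
  a <- feature_subset(c("f1", "f2"), names = nm6)
  b <- feature_subset(c("f3"), names = nm6)
  u <- merge_subsets(a, b)
  expect_equal(names(u$mask)[u$mask], c("f1", "f2", "f3"))
  expect_equal(u$origin, "merged")
  expect_true(is.na(u$merit))
  expect_equal(merge_subsets(a, a)$mask, a$mask)           # idempotent
  expect_equal(merge_subsets(a, b)$mask, merge_subsets(b, a)$mask)
  expect_error(merge_subsets(a, feature_subset(TRUE, names = "z")),
               "length mismatch")
})

test_that("Case 1 keeps the merged union only when it strictly improves", {
  r <- manual_ranking(list(c("f1", "f2"), "f3"), c(0.90, 0.90), nm6)
  d <- make_planted(seed = 41)$dataset # unused by the stub
  improve <- stub_evaluator(setNames(
    list(0.90, 0.90, 0.95),
    c(mask_key_of(c("f1", "f2"), nm6), mask_key_of("f3", nm6),
      mask_key_of(c("f1", "f2", "f3"), nm6))))
  res <- merit_merge(r, d, cfg = merge_config(), evaluator = improve)
  expect_equal(sort(names(res$selected$mask)[res$selected$mask]),
               c("f1", "f2", "f3"))
  expect_equal(res$selected$origin, "merged")
  expect_true("merge_accepted" %in% res$decisions$action)

  reject <- stub_evaluator(setNames(
    list(0.90, 0.88, 0.88),
    c(mask_key_of(c("f1", "f2"), nm6), mask_key_of("f3", nm6),
      mask_key_of(c("f1", "f2", "f3"), nm6))))
  res2 <- merit_merge(r, d, cfg = merge_config(), evaluator = reject)
  expect_equal(sort(names(res2$selected$mask)[res2$selected$mask]),
               c("f1", "f2"))
  expect_equal(res2$selected$origin, "pso")
  expect_true("merge_rejected" %in% res2$decisions$action)
  # the non-merged outcome keeps the whole equal-merit group
  expect_length(res2$group_selected, 2)
})

test_that("Case 3 terminates the walk at a much-lower-merit successor", {
  r <- manual_ranking(list("f1", "f2", "f3"), c(0.90, 0.60, 0.59), nm6)
  d <- make_planted(seed = 42)$dataset
  count <- 0
  counter <- function(subset) { count <<- count + 1; 0.9 }
  res <- merit_merge(r, d, cfg = merge_config(drop_threshold = 0.05),
                     evaluator = counter)
  expect_equal(count, 1) # only the top subset is ever evaluated
  expect_true("case3" %in% res$decisions$case)
  expect_match(res$decisions$note[res$decisions$case == "case3"], "drop")
})

test_that("disabling the drop threshold evaluates every ranked subset", {
  r <- manual_ranking(list("f1", "f2", "f3"), c(0.90, 0.60, 0.30), nm6)
  d <- make_planted(seed = 43)$dataset
  count <- 0
  res <- merit_merge(r, d, cfg = merge_config(drop_threshold = 1),
                     evaluator = function(s) { count <<- count + 1; 0.5 })
  expect_equal(count, 3)
  expect_lte(sum(res$decisions$action == "evaluate_individual"),
             length(r$subsets))
})

test_that("Case 2 escalates iterations while the top merit floods the list", {
  # 3 of 4 subsets tie at the top -> more than 50%
  r <- manual_ranking(list("f1", "f2", "f3", c("f4", "f5")),
                      c(0.9, 0.9, 0.9, 0.7), nm6)
  d <- make_planted(seed = 44)$dataset
  calls <- integer(0)
  rerun <- function(iterations) {
    calls <<- c(calls, iterations)
    # escalation resolves the tie
    manual_ranking(list("f1", "f2"), c(0.9, 0.85), nm6)
  }
  res <- merit_merge(r, d, cfg = merge_config(), rerun = rerun,
                     evaluator = function(s) 0.8)
  expect_equal(calls, 80) # next entry of the 60-80-100 schedule
  expect_false(res$schedule_exhausted)
  expect_true("rerun_pso" %in% res$decisions$action)

  # an unresolvable flood exhausts the schedule and flags the result
  stubborn <- function(iterations) r
  res2 <- merit_merge(r, d, cfg = merge_config(), rerun = stubborn,
                      evaluator = function(s) 0.8)
  expect_true(res2$schedule_exhausted)
  expect_true("schedule_exhausted" %in% res2$decisions$action)
})

test_that("the selected subset is the accuracy argmax of the audit log", {
  r <- manual_ranking(list("f1", c("f2", "f3"), "f4"),
                      c(0.92, 0.91, 0.90), nm6)
  d <- make_planted(seed = 45)$dataset
  acc <- setNames(list(0.80, 0.88, 0.84),
                  c(mask_key_of("f1", nm6), mask_key_of(c("f2", "f3"), nm6),
                    mask_key_of("f4", nm6)))
  res <- merit_merge(r, d, cfg = merge_config(drop_threshold = 1),
                     evaluator = stub_evaluator(acc))
  expect_equal(max(res$evaluations$accuracy),
               res$evaluations$accuracy[res$evaluations$mask ==
                                          cpemm:::mask_key(res$selected$mask)])
  expect_equal(sort(names(res$selected$mask)[res$selected$mask]),
               c("f2", "f3"))
  # every decision row is logged with a case tag
  expect_true(all(res$decisions$case %in% c("walk", "case1", "case2", "case3")))
  expect_gt(nrow(res$decisions), 0)
})

test_that("merging never selects below a ranked mask (superset property)", {
  gen <- make_planted(seed = 46, delta = 3)
  d <- gen$dataset
  ranking <- run_pso(d, pso_config(iterations = 6, swarm_size = 6, folds = 3,
                                   B = 3, top_k = 6, seed = 8),
                     learner_config("c45"))
  res <- merit_merge(ranking, d, cfg = merge_config(seed = 1), B = 3)
  sel <- res$selected$mask
  # the selection is a ranked mask or a union of ranked masks, so it must
  # contain at least one ranked mask entirely
  expect_true(any(vapply(ranking$subsets,
                         function(s) all(sel[s$mask]), logical(1))))
  expect_s3_class(res$final_model, "cpemm_bagged")
  expect_s3_class(res$report, "cpemm_report")
})

test_that("empty rankings are rejected and svm judges draw a warning", {
  d <- make_planted(seed = 47)$dataset
  empty <- structure(list(subsets = list()), class = "subset_ranking")
  expect_error(merit_merge(empty, d), "empty ranking")
  r <- manual_ranking(list("f1"), 0.9, nm6)
  expect_warning(
    merit_merge(r, d, learner = learner_config("svm_rbf"),
                evaluator = function(s) 0.5),
    "not recommended")
})
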