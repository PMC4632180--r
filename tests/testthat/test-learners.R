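test_that("RBF kernel evaluates its closed form", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), gamma = 3), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 0), gamma = 1), exp(-1))
  expect_equal(rbf_kernel(c(5, 5), c(-2, 9), gamma = 0), 1)
  expect_error(rbf_kernel(c(1, 2), c(1, 2, 3), 1), "equal length")
})

test_that("learner configuration validates its domain", {
  expect_error(learner_config("svm_rbf", C = -1))
  expect_error(learner_config("rf", n_trees = 0))
  expect_error(learner_config("zzz"))
  cfg <- learner_config("rf", n_trees = 25)
  expect_equal(cfg$n_trees, 25L)
})

test_that("the tree learner realises a separable threshold exactly", {
  d <- make_separable_dataset()
  m <- fit_base(learner_config("c45"), d)
  expect_equal(mean(predict(m, d$X) == d$y), 1.0)
})

test_that("naive Bayes recovers well-separated Gaussian classes", {
  d <- make_separable_dataset(n_per_class = 50, sep = 4)
  m <- fit_base(learner_config("nb"), d)
  expect_gte(mean(predict(m, d$X) == d$y), 0.95)
})

test_that("fitting is deterministic given the config seed", {
  gen <- make_planted(seed = 3)
  d <- gen$dataset
  probe <- d$X[seq(1, n_instances(d), by = 7), ]
  for (kind in c("c45", "nb", "rf", "svm_rbf")) {
    cfg <- learner_config(kind, n_trees = 15, seed = 99)
    p1 <- predict(fit_base(cfg, d), probe)
    p2 <- predict(fit_base(cfg, d), probe)
    expect_identical(p1, p2)
  }
})

test_that("prediction contract: empty input, class-set membership, arity", {
  gen <- make_planted(seed = 4)
  d <- gen$dataset
  m <- fit_base(learner_config("c45"), d, subset = c("inf_01", "inf_02"))
  expect_length(predict(m, d$X[0, ]), 0)
  expect_true(all(predict(m, d$X) %in% levels(d$y)))
  expect_equal(as.character(predict(m, d$X[1, , drop = FALSE])),
               as.character(d$y[1]))
  expect_error(predict(m, d$X[, "noise_01", drop = FALSE]), "lacks feature")
  expect_error(fit_base(learner_config("c45"), d, character(0)), "empty")
})

test_that("score rows sum to one and argmax agrees with predict", {
  gen <- make_planted(seed = 5)
  d <- gen$dataset
  set.seed(1)
  probe <- d$X[sample(n_instances(d), 100, replace = TRUE), ]
  for (kind in c("c45", "nb", "rf", "svm_rbf")) {
    cfg <- learner_config(kind, n_trees = 15, seed = 7)
    m <- fit_base(cfg, d)
    s <- predict_scores(m, probe)
    expect_true(all(s >= 0))
    expect_equal(rowSums(s), rep(1, nrow(s)), tolerance = 1e-9)
    agree <- colnames(s)[max.col(s, ties.method = "first")]
    expect_equal(as.character(predict(m, probe)), agree)
  }
})

test_that("learners are label-permutation equivariant", {
  gen <- make_planted(seed = 6)
  d <- gen$dataset
  relabel <- c(NL = "Z1", MCI = "Z2", AD = "Z3")
  d2 <- cpemm_dataset(d$X, factor(relabel[as.character(d$y)],
                                  levels = relabel[levels(d$y)]))
  probe <- d$X[1:40, ]
  for (kind in c("c45", "nb")) {
    cfg <- learner_config(kind, seed = 3)
    p1 <- as.character(predict(fit_base(cfg, d), probe))
    p2 <- as.character(predict(fit_base(cfg, d2), probe))
    expect_equal(unname(relabel[p1]), p2)
  }
})

test_that("pruned trees never fall below the majority-class baseline", {
  for (seed in 1:3) {
    d <- make_noise_dataset(seed = seed)
    m <- fit_base(learner_config("c45"), d)
    baseline <- max(table(d$y)) / n_instances(d)
    expect_gte(mean(predict(m, d$X) == d$y), baseline)
  }
})

test_that("random-forest OOB error does not rise from 100 to 1000 trees", {
  gen <- make_planted(seed = 8, n_per = c(60, 80, 60))
  d <- gen$dataset
  oob <- vapply(c(100, 1000), function(nt) {
    set.seed(123)
    rf <- randomForest::randomForest(x = d$X, y = d$y, ntree = nt)
    rf$err.rate[nt, "OOB"]
  }, numeric(1))
  expect_lte(oob[2], oob[1] + 0.02)
})

test_that("SVM grid search returns the CV-best grid member", {
  d <- make_separable_dataset(n_per_class = 25)
  g1 <- grid_search_svm(d, C_grid = 2, gamma_grid = 0.5, folds = 3)
  expect_equal(g1$C, 2)
  expect_equal(g1$gamma, 0.5)
  g <- grid_search_svm(d, C_grid = c(0.1, 1, 10), gamma_grid = c(0.01, 1),
                       folds = 3, seed = 4)
  expect_true(g$C %in% c(0.1, 1, 10) && g$gamma %in% c(0.01, 1))
  best_row <- g$table[g$table$C == g$C & g$table$gamma == g$gamma, ]
  expect_true(all(best_row$accuracy >= g$table$accuracy))
  # ties break toward smaller C then smaller gamma
  tied <- g$table[g$table$accuracy == max(g$table$accuracy), ]
  tied <- tied[order(tied$C, tied$gamma), ]
  expect_equal(c(g$C, g$gamma), c(tied$C[1], tied$gamma[1]))
  expect_error(grid_search_svm(d, numeric(0), 1), "empty")
})

test_that("the compiled tree tracks an independent recursive-partitioning oracle", {
  skip_if_not_installed("rpart")
  gen <- make_planted(seed = 51, n_per = c(60, 80, 50), delta = 2)
  d <- gen$dataset
  acc_c45 <- accuracy(kfold_cv(d, k = 5, seed = 4, fit_predict = function(tr, te) {
    predict(fit_base(learner_config("c45"), tr), te)
  }))
  acc_rpart <- accuracy(kfold_cv(d, k = 5, seed = 4, fit_predict = function(tr, te) {
    df <- tr$X
    df$.y <- tr$y
    m <- rpart::rpart(.y ~ ., df, method = "class",
                      control = rpart::rpart.control(xval = 0))
    predict(m, te, type = "class")
  }))
  expect_gt(acc_c45, 0.7)
  expect_lt(abs(acc_c45 - acc_rpart), 0.1)
})

test_that("non-tree learners refuse missing cells; the tree accepts them", {
  X <- data.frame(a = c(1, NA, 3, 4, 0.5, 2), b = c(0, 1, 0, 1, 0.2, 0.8))
  d <- cpemm_dataset(X, rep(c("p", "q"), 3))
  expect_error(fit_base(learner_config("nb"), d), "imputed")
  expect_s3_class(fit_base(learner_config("c45"), d), "cpemm_model")
})
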