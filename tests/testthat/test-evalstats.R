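test_that("confusion-matrix metrics match hand arithmetic", {
  cm <- confusion_matrix(rep(c("a", "b"), c(50, 50)),
                         c(rep("a", 40), rep("b", 10), rep("a", 10), rep("b", 40)),
                         classes = c("a", "b"))
  expect_equal(accuracy(cm), 0.8)
  diag_only <- confusion_matrix(c("a", "b", "a"), c("a", "b", "a"),
                                c("a", "b"))
  expect_equal(accuracy(diag_only), 1.0)
  wrong <- confusion_matrix(c("a", "b"), c("b", "a"), c("a", "b"))
  expect_equal(accuracy(wrong), 0)
})

test_that("precision and recall follow TP/(TP+FP) and TP/(TP+FN)", {
  truth <- rep(c("pos", "neg"), c(50, 60))
  pred <- c(rep("pos", 45), rep("neg", 5), rep("pos", 10), rep("neg", 50))
  cm <- confusion_matrix(truth, pred, c("pos", "neg"))
  expect_equal(precision(cm, "pos"), 45 / 55)
  expect_equal(recall(cm, "pos"), 45 / 50)
  # degenerate conventions
  none_pred <- confusion_matrix(c("pos", "neg"), c("neg", "neg"),
                                c("pos", "neg"))
  expect_equal(precision(none_pred, "pos"), 0) # TP+FP = 0
  only_neg <- confusion_matrix(c("neg", "neg"), c("neg", "pos"),
                               c("pos", "neg"))
  expect_equal(recall(only_neg, "pos"), 0)     # TP+FN = 0
  expect_equal(recall(none_pred, "neg"), 1)    # FN = 0, TP > 0
  expect_error(precision(cm, "zz"), "unknown class")
})

test_that("accuracy conserves off-diagonal mass", {
  set.seed(8)
  truth <- sample(c("a", "b", "c"), 60, TRUE)
  pred <- sample(c("a", "b", "c"), 60, TRUE)
  cm <- confusion_matrix(truth, pred, c("a", "b", "c"))
  off <- sum(cm) - sum(diag(unclass(cm)))
  expect_equal(accuracy(cm), 1 - off / sum(cm))
})

test_that("one-vs-rest AUC equals Mann-Whitney pair counting", {
  y <- c("p", "p", "n", "n")
  expect_equal(roc_auc_ovr(c(0.9, 0.8, 0.7, 0.6), y, "p"), 1.0)
  expect_equal(roc_auc_ovr(c(0.9, 0.4, 0.6, 0.2), y, "p"), 0.75) # 3/4 pairs
  expect_equal(roc_auc_ovr(rep(0.5, 4), y, "p"), 0.5)            # all tied
  expect_error(roc_auc_ovr(c(1, 2), c("p", "p"), "p"), "negative")
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(9)
  y <- sample(c("p", "n"), 40, TRUE)
  s <- rnorm(40)
  a0 <- roc_auc_ovr(s, y, "p")
  expect_equal(roc_auc_ovr(exp(s), y, "p"), a0)
  expect_equal(roc_auc_ovr(3 * s + 100, y, "p"), a0)
})

test_that("two-class one-vs-rest AUCs are symmetric", {
  set.seed(10)
  y <- sample(c("p", "n"), 30, TRUE)
  sp <- runif(30)
  scores <- cbind(p = sp, n = 1 - sp)
  expect_equal(roc_auc_ovr(scores, y, "p"), roc_auc_ovr(scores, y, "n"))
})

test_that("Press' Q matches its closed form and chi-square reference", {
  q <- press_q(100, 90, 3)
  expect_equal(q$Q, 144.5) # (100 - 270)^2 / (100 * 2)
  expect_equal(press_q(90, 30, 3)$Q, 0) # exactly chance
  q1 <- press_q(100, 55, 2)             # Q = (100 - 110)^2 / 100 = 1
  expect_equal(q1$Q, 1)
  expect_equal(q1$p_value, 0.3173105, tolerance = 1e-6)
  # 5% boundary of chi-square(1)
  m <- 1000; n_corr <- 531 # Q = (1000-1062)^2/1000 = 3.844
  qb <- press_q(m, n_corr, 2)
  expect_equal(qb$p_value, 0.05, tolerance = 0.002)
  expect_error(press_q(10, 5, 1))
})

test_that("stratified k-fold CV partitions instances exactly once", {
  gen <- make_planted(seed = 21)
  d <- gen$dataset
  seen <- integer(n_instances(d))
  rep <- kfold_cv(d, k = 5, seed = 3, fit_predict = function(tr, te) {
    idx <- as.integer(rownames(te))
    seen[idx] <<- seen[idx] + 1L
    factor(rep(levels(d$y)[1], nrow(te)), levels = levels(d$y))
  })
  expect_true(all(seen == 1))
  expect_equal(rep$n, n_instances(d))
  # per-class fold sizes differ by at most one
  folds <- cpemm:::stratified_folds(d$y, 5, seed = 3)
  for (cl in levels(d$y)) {
    sizes <- table(folds[d$y == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_error(kfold_cv(make_planted(seed = 2, n_per = c(3, 40, 40))$dataset,
                        k = 5, fit_predict = function(tr, te) NULL),
               "at least k")
})

test_that("a perfect and a constant classifier bracket CV accuracy", {
  d <- make_separable_dataset(n_per_class = 25)
  perfect <- kfold_cv(d, k = 5, seed = 2, fit_predict = function(tr, te) {
    factor(ifelse(te$x1 < 3, "a", "b"), levels = c("a", "b"))
  })
  expect_equal(accuracy(perfect), 1.0)
  gen <- make_planted(seed = 22)
  const <- train_test_eval(gen$dataset, 0.3, seed = 5,
                           fit_predict = function(tr, te) {
    factor(rep("MCI", nrow(te)), levels = levels(gen$dataset$y))
  })
  counts <- table(gen$dataset$y)
  test_counts <- pmin(pmax(round(counts * 0.3), 1), counts - 1)
  expect_equal(accuracy(const),
               as.numeric(test_counts["MCI"] / sum(test_counts)))
})

test_that("train/test splits are stratified and seed-stable", {
  gen <- make_planted(seed = 23)
  d <- gen$dataset
  sizes <- c()
  grab <- function(tr, te) {
    sizes <<- nrow(te)
    factor(rep(levels(d$y)[1], nrow(te)), levels = levels(d$y))
  }
  r1 <- train_test_eval(d, 0.3, grab, seed = 11)
  n1 <- sizes
  r2 <- train_test_eval(d, 0.3, grab, seed = 11)
  expect_equal(r1$confusion, r2$confusion)
  counts <- table(d$y)
  expect_equal(n1, sum(pmin(pmax(round(counts * 0.3), 1), counts - 1)))
})

test_that("classifier comparison reports both conditions and real ablation drops", {
  # no redundant copies, so ablating the informative pair removes all signal
  gen <- generate_synthetic(synthetic_spec(
    class_counts = c(NL = 40, MCI = 50, AD = 40), n_informative = 2,
    n_redundant = 0, n_noise = 5, delta = 4, seed = 24))
  d <- gen$dataset
  tab <- compare_base_classifiers(d, kinds = c("c45", "nb"),
                                  ablate = c("inf_01", "inf_02"),
                                  seed = 2, n_trees = 10)
  expect_equal(nrow(tab), 4) # |kinds| x 2 conditions
  expect_setequal(unique(tab$condition), c("full", "ablated"))
  for (kind in c("c45", "nb")) {
    full <- tab$accuracy[tab$kind == kind & tab$condition == "full"]
    abl <- tab$accuracy[tab$kind == kind & tab$condition == "ablated"]
    expect_gt(full, abl) # removing the planted signal must hurt
  }
  expect_true(attr(tab, "winner") %in% c("c45", "nb"))
  one <- compare_base_classifiers(d, "c45", seed = 2)
  expect_equal(nrow(one), 2)
  expect_equal(one$accuracy[1], one$accuracy[2]) # identical conditions
  expect_error(compare_base_classifiers(d, "c45", ablate = "nope"), "absent")
  expect_error(compare_base_classifiers(d, character(0)), "no learner")
})
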