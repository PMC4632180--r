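# fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir()

# two well-separated Gaussian classes, single informative feature x1
make_separable_dataset <- function(n_per_class = 30, sep = 6, seed = 42) {
  set.seed(seed)
  X <- data.frame(
    x1 = c(rnorm(n_per_class, 0), rnorm(n_per_class, sep)),
    x2 = rnorm(2 * n_per_class))
  cpemm_dataset(X, rep(c("a", "b"), each = n_per_class))
}

# balanced 3-class data with no class signal at all
make_noise_dataset <- function(n_per_class = 30, d = 4, seed = 43) {
  set.seed(seed)
  n <- 3 * n_per_class
  X <- as.data.frame(matrix(rnorm(n * d), n, d))
  names(X) <- paste0("x", seq_len(d))
  cpemm_dataset(X, rep(c("u", "v", "w"), each = n_per_class))
}

# small planted-structure dataset through the package generator
make_planted <- function(seed = 7, n_per = c(40, 60, 30), d_extra = 4,
                         delta = 3) {
  generate_synthetic(synthetic_spec(
    class_counts = c(NL = n_per[1], MCI = n_per[2], AD = n_per[3]),
    n_informative = 2, n_redundant = 1, n_noise = d_extra,
    delta = delta, seed = seed))
}

# a manual subset ranking for merit-merge tests
manual_ranking <- function(masks, merits, names) {
  subsets <- Map(function(m, mer) {
    feature_subset(names %in% m, merit = mer, origin = "pso", names = names)
  }, masks, merits)
  structure(list(subsets = unname(subsets), gbest = subsets[[1]],
                 trace = numeric(0), n_evaluated = length(subsets),
                 config = NULL),
            class = "subset_ranking")
}

# stub evaluator defined by a lookup from mask key to accuracy
stub_evaluator <- function(table, default = 0.5) {
  function(subset) {
    key <- paste(as.integer(subset$mask), collapse = "")
    if (!is.null(table[[key]])) table[[key]] else default
  }
}

mask_key_of <- function(features, names) {
  paste(as.integer(names %in% features), collapse = "")
}
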