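#' Feature subsets
#'
#' A `feature_subset` is a named logical inclusion mask over a dataset's
#' features, optionally carrying the merit score its wrapper evaluation
#' produced and a provenance tag.
#'
#' @param mask logical vector (one entry per feature), or a character vector
#'   of feature names together with `names`.
#' @param merit merit in `[0, 1]`, or `NA` if not yet evaluated.
#' @param origin one of `"pso"`, `"merged"`, `"manual"`.
#' @param names feature names for the mask (required if `mask` is unnamed).
#' @return An object of class `feature_subset`.
#' @export
feature_subset <- function(mask, merit = NA_real_, origin = "manual",
                           names = NULL) {
  if (is.character(mask)) {
    stopifnot(!is.null(names))
    mask <- names %in% mask
  }
  stopifnot(is.logical(mask))
  if (!is.null(names)) names(mask) <- names
  if (!is.na(merit)) stopifnot(merit >= 0, merit <= 1)
  stopifnot(origin %in% c("pso", "merged", "manual"))
  structure(list(mask = mask, merit = as.numeric(merit), origin = origin),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  nm <- names(x$mask) %||% as.character(seq_along(x$mask))
  cat(sprintf("feature_subset (%s): %d/%d features, merit %s\n", x$origin,
              sum(x$mask), length(x$mask),
              if (is.na(x$merit)) "unset" else sprintf("%.4f", x$merit)))
  cat(" ", paste(nm[x$mask], collapse = ", "), "\n")
  invisible(x)
}

mask_key <- function(mask) paste(as.integer(mask), collapse = "")

#' Sigmoid transfer function for binary PSO
#'
#' Maps a real velocity to the probability that the corresponding bit is
#' set: `1 / (1 + exp(-v))`.
#'
#' @param v numeric velocity (vectorised).
#' @return Probabilities in `(0, 1)`.
#' @export
sigmoid_transfer <- function(v) 1 / (1 + exp(-v))

#' Wrapper merit of a feature subset
#'
#' Merit is the stratified k-fold cross-validated mean accuracy of a bagged
#' ensemble of the base learner trained on the candidate subset. It lies in
#' `[0, 1]` and is deterministic given `seed`.
#'
#' @param subset a [feature_subset()] (or logical mask / name vector).
#' @param d a preprocessed [cpemm_dataset].
#' @param learner a [learner_config()].
#' @param folds cross-validation folds (default 5).
#' @param B bagging rounds per evaluation (default 10).
#' @param seed integer seed for fold assignment and ensemble fitting.
#' @return Mean fold accuracy in `[0, 1]`.
#' @export
subset_merit <- function(subset, d, learner, folds = 5, B = 10, seed = 1L) {
  cols <- resolve_subset(d, subset)
  if (!length(cols)) stop("empty feature subset")
  if (n_instances(d) < folds) stop("fewer instances than folds")
  fold_id <- stratified_folds(d$y, folds, derive_seed(seed, 1L))
  if (learner$kind == "c45") {
    # compiled fast path: same protocol (stratified CV of a bagged tree
    # ensemble with prior tie-broken majority vote), own RNG stream
    enc <- attr(d, "c45_cache") %||% c45_encode(d$X)
    return(.c45_merit_cpp(enc$M, as.integer(d$y) - 1L, enc$ncat,
                          nlevels(d$y), match(cols, feature_names(d)) - 1L,
                          fold_id, as.integer(B), learner$minbucket, 30L,
                          learner$prune, learner$cf,
                          as.vector(prop.table(table(d$y))),
                          as.double(derive_seed(seed, 2L))))
  }
  acc <- vapply(seq_len(folds), function(f) {
    tr <- dataset_rows(d, which(fold_id != f))
    te <- which(fold_id == f)
    ens <- fit_bagged(learner, tr, cols, B = B, seed = derive_seed(seed, 10L + f))
    mean(predict(ens, d$X[te, , drop = FALSE]) == d$y[te])
  }, numeric(1))
  mean(acc)
}

#' Binary PSO configuration
#'
#' @param iterations swarm iterations (default 60; the searched range is
#'   60-100, larger values favouring smaller subsets).
#' @param swarm_size number of particles (default 30).
#' @param inertia,c1,c2 velocity-update constants (constriction-style
#'   defaults 0.729, 1.49445, 1.49445).
#' @param v_max velocity clamp (default 4).
#' @param top_k ranked subsets retained (default 20).
#' @param folds merit cross-validation folds (default 5).
#' @param B bagging rounds inside the merit evaluation (default 10).
#' @param seed integer master seed for the search.
#' @return An object of class `cpemm_pso_config`.
#' @export
pso_config <- function(iterations = 60, swarm_size = 30, inertia = 0.729,
                       c1 = 1.49445, c2 = 1.49445, v_max = 4, top_k = 20,
                       folds = 5, B = 10, seed = 1L) {
  stopifnot(iterations >= 1, swarm_size >= 2, v_max > 0, top_k >= 1)
  structure(list(iterations = as.integer(iterations),
                 swarm_size = as.integer(swarm_size), inertia = inertia,
                 c1 = c1, c2 = c2, v_max = v_max, top_k = as.integer(top_k),
                 folds = as.integer(folds), B = as.integer(B),
                 seed = as.integer(seed)),
            class = "cpemm_pso_config")
}

# evaluate a mask through the run-wide merit cache
cached_merit <- function(mask, cache, d, learner, cfg) {
  key <- mask_key(mask)
  hit <- cache$merits[[key]]
  if (!is.null(hit)) return(hit)
  m <- subset_merit(mask, d, learner, folds = cfg$folds, B = cfg$B,
                    seed = derive_seed(cfg$seed, 555L))
  cache$merits[[key]] <- m
  cache$masks[[key]] <- mask
  m
}

new_swarm_state <- function(d, cfg) {
  dn <- length(feature_names(d))
  cache <- new.env(parent = emptyenv())
  cache$merits <- list()
  cache$masks <- list()
  pos <- with_seed(derive_seed(cfg$seed, 1L), {
    p <- matrix(stats::runif(cfg$swarm_size * dn) < 0.5, cfg$swarm_size, dn)
    for (i in seq_len(cfg$swarm_size)) {
      if (!any(p[i, ])) p[i, sample.int(dn, 1)] <- TRUE
    }
    p
  })
  colnames(pos) <- feature_names(d)
  structure(list(positions = pos,
                 velocities = matrix(0, cfg$swarm_size, dn),
                 pbest = pos, pbest_merit = rep(-Inf, cfg$swarm_size),
                 gbest = NULL, gbest_merit = -Inf,
                 iteration = 0L, cache = cache),
            class = "cpemm_swarm_state")
}

# score current positions, refresh pbest/gbest: strict merit improvement,
# or equal merit with strictly fewer features (minimal-subset preference,
# matching the ranking's tie-break)
score_swarm <- function(s, d, cfg, learner) {
  for (i in seq_len(nrow(s$positions))) {
    pos <- s$positions[i, ]
    m <- cached_merit(pos, s$cache, d, learner, cfg)
    if (m > s$pbest_merit[i] ||
        (m == s$pbest_merit[i] && sum(pos) < sum(s$pbest[i, ]))) {
      s$pbest_merit[i] <- m
      s$pbest[i, ] <- pos
    }
    if (m > s$gbest_merit ||
        (m == s$gbest_merit && sum(pos) < sum(s$gbest))) {
      s$gbest_merit <- m
      s$gbest <- pos
    }
  }
  s
}

#' One binary-PSO iteration
#'
#' Updates every particle's velocity
#' `v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` (clamped to
#' `[-v_max, v_max]`), redraws each bit as Bernoulli(`sigmoid_transfer(v)`),
#' repairs all-zero positions by setting one uniformly random bit, evaluates
#' the new positions, and updates the personal/global bests on strict
#' improvement.
#'
#' @param s swarm state from [run_pso()] internals (or a fresh state).
#' @param d a preprocessed [cpemm_dataset].
#' @param cfg a [pso_config()].
#' @param learner a [learner_config()].
#' @return The successor swarm state.
#' @export
pso_step <- function(s, d, cfg, learner) {
  if (is.null(s$gbest)) s <- score_swarm(s, d, cfg, learner)
  P <- nrow(s$positions); dn <- ncol(s$positions)
  step_seed <- derive_seed(cfg$seed, 1000L + s$iteration)
  with_seed(step_seed, {
    r1 <- matrix(stats::runif(P * dn), P, dn)
    r2 <- matrix(stats::runif(P * dn), P, dn)
    v <- cfg$inertia * s$velocities +
      cfg$c1 * r1 * (s$pbest - s$positions) +
      cfg$c2 * r2 * (matrix(s$gbest, P, dn, byrow = TRUE) - s$positions)
    v <- pmin(pmax(v, -cfg$v_max), cfg$v_max)
    u <- matrix(stats::runif(P * dn), P, dn)
    pos <- u < sigmoid_transfer(v)
    for (i in seq_len(P)) {
      if (!any(pos[i, ])) pos[i, sample.int(dn, 1)] <- TRUE
    }
    colnames(pos) <- colnames(s$positions)
    s$velocities <- v
    s$positions <- pos
  })
  s$iteration <- s$iteration + 1L
  score_swarm(s, d, cfg, learner)
}

#' Binary PSO search over feature subsets
#'
#' Runs `cfg$iterations` swarm iterations from a uniform-random swarm,
#' caching every distinct subset merit evaluated anywhere in the run. The
#' result is the deduplicated list of visited subsets sorted by
#' non-increasing merit (ties: fewer features first, then lexicographic
#' mask), truncated to `cfg$top_k`.
#'
#' @param d a preprocessed [cpemm_dataset] (no missing cells unless the
#'   learner is the C4.5 tree).
#' @param cfg a [pso_config()].
#' @param learner a [learner_config()].
#' @return An object of class `subset_ranking`.
#' @export
run_pso <- function(d, cfg = pso_config(), learner = learner_config("c45")) {
  stopifnot(inherits(cfg, "cpemm_pso_config"))
  if (learner$kind == "c45" && is.null(attr(d, "c45_cache"))) {
    attr(d, "c45_cache") <- c45_encode(d$X) # encode once per run
  }
  s <- new_swarm_state(d, cfg)
  s <- score_swarm(s, d, cfg, learner)
  trace <- numeric(cfg$iterations)
  for (it in seq_len(cfg$iterations)) {
    s <- pso_step(s, d, cfg, learner)
    trace[it] <- s$gbest_merit
  }
  keys <- names(s$cache$merits)
  merits <- unlist(s$cache$merits, use.names = FALSE)
  masks <- s$cache$masks[keys]
  sizes <- vapply(masks, sum, numeric(1))
  ord <- order(-merits, sizes, keys)
  ord <- ord[seq_len(min(cfg$top_k, length(ord)))]
  subsets <- lapply(ord, function(i) {
    feature_subset(masks[[i]], merit = merits[i], origin = "pso")
  })
  structure(list(subsets = subsets, gbest = feature_subset(
    s$gbest, merit = s$gbest_merit, origin = "pso"),
    trace = trace, n_evaluated = length(keys), config = cfg),
    class = "subset_ranking")
}

#' @export
print.subset_ranking <- function(x, ...) {
  cat(sprintf("subset_ranking: %d subsets (of %d evaluated)\n",
              length(x$subsets), x$n_evaluated))
  df <- as.data.frame(x)
  print(utils::head(df, 10))
  if (nrow(df) > 10) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.subset_ranking <- function(x, ...) {
  data.frame(
    mask = vapply(x$subsets, function(s) mask_key(s$mask), character(1)),
    merit = vapply(x$subsets, function(s) s$merit, numeric(1)),
    n_features = vapply(x$subsets, function(s) sum(s$mask), numeric(1)),
    origin = vapply(x$subsets, function(s) s$origin, character(1)),
    stringsAsFactors = FALSE)
}

#' Read/write subset rankings as tab-separated text
#'
#' Columns: `mask` (bit string over the feature order), `merit`,
#' `n_features`, `origin`.
#'
#' @param x a `subset_ranking` (or object convertible via
#'   `as.data.frame`).
#' @param path file path.
#' @param feature_names feature names to attach to the masks on read.
#' @return `write_ranking()` returns `path` invisibly; `read_ranking()` a
#'   `subset_ranking`.
#' @export
write_ranking <- function(x, path) {
  df <- as.data.frame(x)
  df$merit <- sprintf("%.17g", df$merit)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path, feature_names = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric", "numeric",
                                         "character"))
  subsets <- lapply(seq_len(nrow(df)), function(i) {
    mask <- as.integer(strsplit(df$mask[i], "")[[1]]) == 1L
    if (!is.null(feature_names)) names(mask) <- feature_names
    feature_subset(mask, merit = df$merit[i], origin = df$origin[i])
  })
  structure(list(subsets = subsets, gbest = subsets[[1]],
                 trace = numeric(0), n_evaluated = nrow(df), config = NULL),
            class = "subset_ranking")
}
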