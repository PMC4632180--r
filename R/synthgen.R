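#' Specification for the synthetic clinical-tabular generator
#'
#' Describes a multiclass dataset with the statistical shape of a
#' neuropsychological study extract: a handful of informative features
#' whose class means are separated, redundant features that are noisy
#' copies of informative ones, class-independent noise features, optional
#' nominal (quantile-binned) features, class imbalance, and MCAR
#' missingness. The defaults mirror a typical dementia-cohort extract:
#' 750 instances x 48 attributes with classes NL/MCI/AD at 200/400/150.
#'
#' @param class_counts named integer vector of per-class instance counts
#'   (default `c(NL = 200, MCI = 400, AD = 150)`).
#' @param n_informative,n_redundant,n_noise feature counts (defaults
#'   6/6/36, i.e. d = 48).
#' @param delta class-mean separation of informative features, in
#'   within-class standard-deviation units (default 1.5).
#' @param sigma_r standard deviation of the noise added to redundant copies
#'   (default 0.1).
#' @param missing_rate MCAR per-cell missingness probability in `[0, 1)`
#'   (default 0).
#' @param nominal_fraction fraction of features converted to 3-category
#'   nominal features by quantile binning (default 0).
#' @param seed generator seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(class_counts = c(NL = 200, MCI = 400, AD = 150),
                           n_informative = 6, n_redundant = 6, n_noise = 36,
                           delta = 1.5, sigma_r = 0.1, missing_rate = 0,
                           nominal_fraction = 0, seed = 1L) {
  stopifnot(length(class_counts) >= 2, all(class_counts > 0),
            !is.null(names(class_counts)), n_informative >= 1,
            n_redundant >= 0, n_noise >= 0, delta >= 0, sigma_r >= 0,
            missing_rate >= 0, missing_rate < 1,
            nominal_fraction >= 0, nominal_fraction <= 1)
  structure(list(class_counts = class_counts,
                 n_informative = as.integer(n_informative),
                 n_redundant = as.integer(n_redundant),
                 n_noise = as.integer(n_noise), delta = delta,
                 sigma_r = sigma_r, missing_rate = missing_rate,
                 nominal_fraction = nominal_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic multiclass dataset with planted structure
#'
#' Informative feature j draws from `Normal(mu[c, j], 1)` where the class
#' means are spaced `delta` apart along a class ordering drawn independently
#' per feature (so no single feature separates all classes the same way).
#' Redundant features are an informative source plus `Normal(0, sigma_r)`
#' noise; noise features are `Normal(0, 1)` independent of the class.
#' Missing cells are MCAR. Fully deterministic given the spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @param seed optional override of `spec$seed`.
#' @return A list with `dataset` (a [cpemm_dataset]) and `truth`, the
#'   ground truth: logical masks `informative`, `redundant`, `noise`, the
#'   `redundant_source` map and the `class_means` matrix.
#' @export
generate_synthetic <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seed <- seed %||% spec$seed
  counts <- spec$class_counts
  classes <- names(counts)
  K <- length(classes)
  n <- sum(counts)
  d <- spec$n_informative + spec$n_redundant + spec$n_noise
  y <- factor(rep(classes, counts), levels = classes)

  nm <- c(sprintf("inf_%02d", seq_len(spec$n_informative)),
          if (spec$n_redundant) sprintf("red_%02d", seq_len(spec$n_redundant)),
          if (spec$n_noise) sprintf("noise_%02d", seq_len(spec$n_noise)))

  with_seed(seed, {
    mu <- matrix(0, K, spec$n_informative,
                 dimnames = list(classes, nm[seq_len(spec$n_informative)]))
    X <- matrix(NA_real_, n, d, dimnames = list(NULL, nm))
    for (j in seq_len(spec$n_informative)) {
      ord <- sample.int(K) # class ordering differs per feature
      mu[, j] <- (ord - 1) * spec$delta
      X[, j] <- stats::rnorm(n, mean = mu[as.integer(y), j], sd = 1)
    }
    redundant_source <- integer(0)
    if (spec$n_redundant) {
      redundant_source <- sample.int(spec$n_informative, spec$n_redundant,
                                     replace = TRUE)
      names(redundant_source) <- nm[spec$n_informative + seq_len(spec$n_redundant)]
      for (r in seq_len(spec$n_redundant)) {
        X[, spec$n_informative + r] <-
          X[, redundant_source[r]] + stats::rnorm(n, sd = spec$sigma_r)
      }
    }
    if (spec$n_noise) {
      X[, spec$n_informative + spec$n_redundant + seq_len(spec$n_noise)] <-
        stats::rnorm(n * spec$n_noise)
    }
    Xdf <- as.data.frame(X)
    if (spec$nominal_fraction > 0) {
      n_nom <- ceiling(spec$nominal_fraction * d)
      nom_cols <- sample.int(d, n_nom)
      for (j in nom_cols) {
        q <- stats::quantile(X[, j], c(1 / 3, 2 / 3), na.rm = TRUE)
        Xdf[[j]] <- factor(cut(X[, j], c(-Inf, q, Inf),
                               labels = c("low", "mid", "high")))
      }
    }
    if (spec$missing_rate > 0) {
      holes <- matrix(stats::runif(n * d) < spec$missing_rate, n, d)
      for (j in seq_len(d)) Xdf[[j]][holes[, j]] <- NA
    }
    truth <- list(
      informative = stats::setNames(seq_len(d) <= spec$n_informative, nm),
      redundant = stats::setNames(seq_len(d) > spec$n_informative &
        seq_len(d) <= spec$n_informative + spec$n_redundant, nm),
      noise = stats::setNames(
        seq_len(d) > spec$n_informative + spec$n_redundant, nm),
      redundant_source = redundant_source, class_means = mu)
    list(dataset = cpemm_dataset(Xdf, y), truth = truth)
  })
}

#' Generate a two-class synthetic dataset
#'
#' The two-class companion shape (650 instances x 108 attributes by
#' default, mirroring a neuroimaging-style extract). Identical generative
#' model to [generate_synthetic()] with `K = 2`.
#'
#' @param spec a [synthetic_spec()] with exactly two classes; the default
#'   uses `c(NL = 400, AD = 250)` and 8 informative / 8 redundant / 92
#'   noise features.
#' @param seed optional override of the spec seed.
#' @return As [generate_synthetic()].
#' @export
generate_two_class <- function(spec = synthetic_spec(
                                 class_counts = c(NL = 400, AD = 250),
                                 n_informative = 8, n_redundant = 8,
                                 n_noise = 92),
                               seed = NULL) {
  stopifnot(length(spec$class_counts) == 2)
  generate_synthetic(spec, seed = seed)
}

#' Write generator ground truth as plain text
#'
#' @param truth the `truth` element of a [generate_synthetic()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  lines <- c(
    paste("informative:", paste(names(which(truth$informative)), collapse = ",")),
    paste("redundant:", paste(names(which(truth$redundant)), collapse = ",")),
    paste("noise:", paste(names(which(truth$noise)), collapse = ",")),
    paste("redundant_source:",
          paste(sprintf("%s<-inf_%02d", names(truth$redundant_source),
                        truth$redundant_source), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}
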