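# internal helpers: deterministic seed derivation and scoped RNG

# Deterministic 31-bit child seed from (seed, salt). Arithmetic stays below
# 2^53 so the double computation is exact.
derive_seed <- function(seed, salt) {
  s <- abs(as.double(seed)) %% 2147483629
  as.integer((s * 69069 + abs(as.double(salt)) * 7919 + 1) %% 2147483629) + 1L
}

# Evaluate `code` under set.seed(seed) and restore the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so per-class fold sizes differ by at most one.
stratified_folds <- function(y, k, seed) {
  stopifnot(k >= 2)
  tab <- table(y)
  if (any(tab[tab > 0] < k)) {
    stop("every class must have at least k = ", k, " instances for stratification")
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

`%||%` <- function(a, b) if (is.null(a)) b else a
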