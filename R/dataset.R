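#' Construct a cpemm dataset
#'
#' A `cpemm_dataset` bundles a feature table, a class label vector and the
#' per-cell missingness pattern used throughout the package. Features are
#' either numeric or nominal (factor) columns; missing cells are `NA`.
#'
#' @param X data.frame of features (numeric or factor columns).
#' @param y class labels; coerced to factor. Must have at least 2 levels and
#'   one entry per row of `X`.
#' @param label name used for the class column when the dataset is written
#'   to file (default `"class"`).
#' @return An object of class `cpemm_dataset` with elements `X`, `y` and
#'   `label`.
#' @examples
#' d <- cpemm_dataset(data.frame(a = c(1, 2, 3)), c("u", "v", "u"))
#' n_instances(d)
#' @export
cpemm_dataset <- function(X, y, label = "class") {
  stopifnot(is.data.frame(X))
  y <- as.factor(y) # declared-but-unused categories are kept
  if (nrow(X) == 0L) stop("dataset has zero instances")
  if (nrow(X) != length(y)) stop("X and y dimensions are inconsistent")
  if (nlevels(y) < 2L) stop("class set must have at least 2 members")
  ok <- vapply(X, function(col) is.numeric(col) || is.factor(col), logical(1))
  if (!all(ok)) {
    bad <- names(X)[!ok]
    X[bad] <- lapply(X[bad], function(col) factor(as.character(col)))
  }
  structure(list(X = X, y = y, label = label), class = "cpemm_dataset")
}

#' @export
print.cpemm_dataset <- function(x, ...) {
  kinds <- feature_kinds(x)
  cat(sprintf("cpemm_dataset: %d instances x %d features (%d numeric, %d nominal)\n",
              n_instances(x), length(kinds), sum(kinds == "numeric"),
              sum(kinds == "nominal")))
  cat("classes:", paste(sprintf("%s (%d)", levels(x$y), tabulate(x$y)),
                        collapse = ", "), "\n")
  mf <- missing_fraction(x)
  if (any(mf > 0)) {
    cat(sprintf("missing cells: %.1f%% overall\n", 100 * mean(missing_mask(x))))
  }
  invisible(x)
}

#' Dataset accessors
#'
#' @param d a [cpemm_dataset].
#' @return `n_instances()` the number of rows; `feature_names()` the feature
#'   names in column order; `feature_kinds()` a named character vector with
#'   values `"numeric"` or `"nominal"`; `missing_mask()` an n x d logical
#'   matrix marking missing cells; `missing_fraction()` the per-feature
#'   fraction of missing cells.
#' @export
n_instances <- function(d) nrow(d$X)

#' @rdname n_instances
#' @export
feature_names <- function(d) names(d$X)

#' @rdname n_instances
#' @export
feature_kinds <- function(d) {
  vapply(d$X, function(col) if (is.factor(col)) "nominal" else "numeric",
         character(1))
}

#' @rdname n_instances
#' @export
missing_mask <- function(d) {
  m <- vapply(d$X, is.na, logical(n_instances(d)))
  if (is.null(dim(m))) m <- matrix(m, nrow = n_instances(d))
  dimnames(m) <- list(NULL, names(d$X))
  m
}

#' @rdname n_instances
#' @export
missing_fraction <- function(d) colMeans(missing_mask(d))

# subset rows (used by bootstrap and CV internals)
dataset_rows <- function(d, idx) {
  cpemm_dataset(d$X[idx, , drop = FALSE], d$y[idx], d$label)
}

# subset columns by a logical mask or name vector, keeping y
dataset_columns <- function(d, cols) {
  if (is.logical(cols)) cols <- names(d$X)[cols]
  missing_cols <- setdiff(cols, names(d$X))
  if (length(missing_cols)) {
    stop("unknown feature(s): ", paste(missing_cols, collapse = ", "))
  }
  cpemm_dataset(d$X[, cols, drop = FALSE], d$y, d$label)
}

#' Read a tabular dataset from CSV or ARFF
#'
#' CSV files need a header row; `""`, `"?"` and `"NA"` cells are read as
#' missing. ARFF files follow the standard `@relation`/`@attribute`/`@data`
#' dialect with `?` as the missing token; nominal category sets are taken
#' from the attribute declarations.
#'
#' @param path file to read.
#' @param format `"csv"` or `"arff"`; the default guesses from the file
#'   extension.
#' @param label name of the class column (default `"class"`).
#' @param sep CSV field delimiter.
#' @return A [cpemm_dataset].
#' @export
read_dataset <- function(path, format = c("guess", "csv", "arff"),
                         label = "class", sep = ",") {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (format == "csv") {
    utils::read.table(path, header = TRUE, sep = sep,
                      na.strings = c("", "?", "NA"), stringsAsFactors = TRUE,
                      check.names = FALSE)
  } else {
    read_arff_file(path)
  }
  if (nrow(df) == 0L) stop("dataset has zero instances")
  if (!label %in% names(df)) stop("label column '", label, "' not found")
  y <- df[[label]]
  if (anyNA(y)) stop("label column contains missing values")
  X <- df[setdiff(names(df), label)]
  cpemm_dataset(X, y, label)
}

#' Write a dataset to CSV or ARFF
#'
#' The CSV writer emits numeric cells with full double precision so that a
#' write-then-read round trip reproduces the dataset exactly; missing cells
#' are written as `?`.
#'
#' @param d a [cpemm_dataset].
#' @param path output file.
#' @param format `"csv"` or `"arff"` (default guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(d, path, format = c("guess", "csv", "arff")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  df <- d$X
  df[[d$label]] <- d$y
  if (format == "arff") {
    write_arff_file(df, path)
  } else {
    chr <- lapply(df, function(col) {
      out <- if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
      out[is.na(col)] <- "?"
      out
    })
    mat <- do.call(cbind, chr)
    colnames(mat) <- names(df)
    utils::write.table(mat, path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

# Dense @relation/@attribute/@data ARFF dialect. Handled in-package because
# the dataset contract requires (a) nominal category sets taken from the
# declarations even when a category never occurs in @data and (b) numeric
# round trips at full double precision.
read_arff_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  strip <- trimws(sub("%.*$", "", lines))
  data_at <- which(tolower(strip) == "@data")[1]
  if (is.na(data_at)) stop("no @data section in ARFF file")
  head <- strip[seq_len(data_at - 1L)]
  attrs <- head[grepl("^@attribute", head, ignore.case = TRUE)]
  if (!length(attrs)) stop("no @attribute declarations in ARFF file")
  unquote <- function(x) gsub("^['\"]|['\"]$", "", x)
  names_ <- character(length(attrs))
  levels_ <- vector("list", length(attrs))
  for (i in seq_along(attrs)) {
    body <- trimws(sub("^@attribute\\s+", "", attrs[i], ignore.case = TRUE))
    if (grepl("^['\"]", body)) {
      q <- substring(body, 1, 1)
      end <- regexpr(paste0(q, "[^", q, "]*$"), body)
      names_[i] <- substring(body, 2, end - 1)
      rest <- trimws(substring(body, end + 1))
    } else {
      names_[i] <- sub("\\s.*$", "", body)
      rest <- trimws(sub("^\\S+\\s*", "", body))
    }
    if (startsWith(rest, "{")) {
      inner <- sub("\\}\\s*$", "", sub("^\\{", "", rest))
      levels_[[i]] <- unquote(trimws(strsplit(inner, ",")[[1]]))
    } else if (!tolower(rest) %in% c("numeric", "real", "integer")) {
      levels_[[i]] <- character(0) # string attribute: free-text nominal
    }
  }
  body_lines <- strip[seq(data_at + 1L, length(strip))]
  body_lines <- body_lines[nzchar(body_lines)]
  df <- utils::read.table(text = paste(body_lines, collapse = "\n"),
                          sep = ",", quote = "'\"", na.strings = "?",
                          strip.white = TRUE, stringsAsFactors = FALSE,
                          col.names = names_, check.names = FALSE)
  for (i in seq_along(names_)) {
    if (is.null(levels_[[i]])) {
      df[[i]] <- as.numeric(df[[i]])
    } else {
      lv <- if (length(levels_[[i]])) levels_[[i]] else
        sort(unique(stats::na.omit(df[[i]])))
      df[[i]] <- factor(df[[i]], levels = lv)
    }
  }
  df
}

write_arff_file <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@relation cpemm", con)
  for (nm in names(df)) {
    col <- df[[nm]]
    decl <- if (is.factor(col)) {
      paste0("{", paste(levels(col), collapse = ","), "}")
    } else "numeric"
    writeLines(sprintf("@attribute %s %s", nm, decl), con)
  }
  writeLines("@data", con)
  cells <- lapply(df, function(col) {
    out <- if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
    out[is.na(col)] <- "?"
    out
  })
  writeLines(do.call(paste, c(cells, sep = ",")), con)
  invisible(path)
}
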