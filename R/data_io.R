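# Canonical column order for dataset files: three CIELAB coordinates followed
# by the five powder mass fractions.
LAB_COLS <- c("L", "a", "b")
POWDER_COLS <- c("A1", "A4", "B4", "C4", "D4")
DATASET_COLS <- c(LAB_COLS, POWDER_COLS)

# Every recipe in the specimen database lies on a 0.08-step grid and sums
# to 0.40 g of powder.
RECIPE_STEP <- 0.08
RECIPE_TOTAL <- 0.40

#' Construct a color-matching dataset
#'
#' A `ccm_dataset` pairs CIELAB color measurements with the porcelain powder
#' recipes that produced them. Color is the network input; the recipe
#' (mass fractions of the A1, A4, B4, C4 and D4 dentin powders) is the
#' prediction target.
#'
#' @param lab Numeric matrix (or coercible) with 3 columns: L*, a*, b*.
#' @param recipe Numeric matrix with 5 columns: mass fractions of the five
#'   powders. Entries must be non-negative.
#' @param name Optional label for the dataset.
#' @return An object of class `ccm_dataset` with elements `lab` (n x 3
#'   matrix), `recipe` (n x 5 matrix) and `name`.
#' @export
ccm_dataset <- function(lab, recipe, name = "dataset") {
  lab <- as.matrix(lab)
  recipe <- as.matrix(recipe)
  if (ncol(lab) != 3L) {
    stop("`lab` must have 3 columns (L*, a*, b*), got ", ncol(lab))
  }
  if (ncol(recipe) != 5L) {
    stop("`recipe` must have 5 columns (A1, A4, B4, C4, D4), got ",
         ncol(recipe))
  }
  if (nrow(lab) != nrow(recipe)) {
    stop("`lab` and `recipe` must have the same number of rows")
  }
  storage.mode(lab) <- "double"
  storage.mode(recipe) <- "double"
  if (nrow(recipe) && any(recipe < -1e-12)) {
    stop("recipe mass fractions must be non-negative")
  }
  colnames(lab) <- LAB_COLS
  colnames(recipe) <- POWDER_COLS
  structure(list(lab = lab, recipe = recipe, name = as.character(name)[1]),
            class = "ccm_dataset")
}

#' @export
print.ccm_dataset <- function(x, ...) {
  cat(sprintf("<ccm_dataset '%s': %d samples>\n", x$name, nrow(x$lab)))
  if (nrow(x$lab)) {
    rng <- apply(x$lab, 2, range)
    cat(sprintf("  L* %.2f..%.2f  a* %.2f..%.2f  b* %.2f..%.2f\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2],
                rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

#' @export
as.data.frame.ccm_dataset <- function(x, ...) {
  as.data.frame(cbind(x$lab, x$recipe))
}

#' Number of samples in a dataset
#' @param d A `ccm_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(d) {
  stopifnot(inherits(d, "ccm_dataset"))
  nrow(d$lab)
}

#' Read a dataset from a delimited text file
#'
#' Expects comma-separated values with a dot decimal separator and the
#' header `L,a,b,A1,A4,B4,C4,D4`. Headerless files are supported by passing
#' the column order explicitly via `columns`.
#'
#' @param path Path to a CSV file.
#' @param columns Optional character vector naming the columns in file
#'   order (used for headerless files). Must be a permutation of
#'   `L,a,b,A1,A4,B4,C4,D4`.
#' @param name Dataset label; defaults to the file name.
#' @return A [ccm_dataset()].
#' @export
read_dataset <- function(path, columns = NULL, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(columns)) {
    df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                          check.names = FALSE)
    missing <- setdiff(DATASET_COLS, names(df))
    if (length(missing)) {
      stop("missing column(s) in ", path, ": ",
           paste(missing, collapse = ", "))
    }
  } else {
    if (!setequal(columns, DATASET_COLS) || length(columns) != 8L) {
      stop("`columns` must be a permutation of ",
           paste(DATASET_COLS, collapse = ","))
    }
    df <- utils::read.csv(path, header = FALSE, colClasses = "character")
    if (ncol(df) != 8L) {
      stop("expected 8 columns, found ", ncol(df), " in ", path)
    }
    names(df) <- columns
  }
  df <- df[, DATASET_COLS, drop = FALSE]
  num <- matrix(NA_real_, nrow(df), 8L, dimnames = list(NULL, DATASET_COLS))
  for (j in seq_len(8L)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) & nzchar(trimws(df[[j]])))
    if (any(is.na(v))) {
      row <- if (length(bad)) bad[1] else which(is.na(v))[1]
      stop(sprintf("non-numeric value '%s' in column %s at data row %d of %s",
                   df[[j]][row], DATASET_COLS[j], row, path))
    }
    num[, j] <- v
  }
  ccm_dataset(num[, LAB_COLS, drop = FALSE],
              num[, POWDER_COLS, drop = FALSE],
              name = if (is.null(name)) basename(path) else name)
}

#' Write a dataset to CSV
#'
#' Writes the canonical `L,a,b,A1,A4,B4,C4,D4` comma-separated layout with a
#' header row, dot decimal separator, full double precision.
#'
#' @param d A `ccm_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(d, path) {
  stopifnot(inherits(d, "ccm_dataset"))
  df <- as.data.frame(d)
  # format() keeps full precision and locale-independent dot decimals
  out <- vapply(seq_len(nrow(df)), function(i) {
    paste(vapply(as.numeric(df[i, ]), function(v) {
      format(v, digits = 17, scientific = FALSE, trim = TRUE)
    }, character(1)), collapse = ",")
  }, character(1))
  writeLines(c(paste(DATASET_COLS, collapse = ","), out), path)
  invisible(path)
}

#' Split a dataset into training and test parts
#'
#' Uniform random shuffle driven only by `seed`; the training part takes
#' `round(train_fraction * n)` samples, as in the study's 75/25 division of
#' 119 specimens into 89 training and 30 test records.
#'
#' @param d A `ccm_dataset` with at least 2 samples.
#' @param train_fraction Fraction in (0, 1) assigned to the training part.
#' @param seed Integer seed; the same seed always yields the same split.
#' @return List with elements `train` and `test`, both `ccm_dataset`s;
#'   together they partition `d`.
#' @export
split_dataset <- function(d, train_fraction = 0.75, seed) {
  stopifnot(inherits(d, "ccm_dataset"))
  n <- n_samples(d)
  if (n < 2L) stop("need at least 2 samples to split")
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1")
  }
  set.seed(as.integer(seed))
  idx <- sample.int(n)
  n_train <- round(train_fraction * n)
  n_train <- max(1L, min(n - 1L, as.integer(n_train)))
  take <- sort(idx[seq_len(n_train)])
  rest <- sort(idx[-seq_len(n_train)])
  list(
    train = ccm_dataset(d$lab[take, , drop = FALSE],
                        d$recipe[take, , drop = FALSE],
                        name = paste0(d$name, "/train")),
    test = ccm_dataset(d$lab[rest, , drop = FALSE],
                       d$recipe[rest, , drop = FALSE],
                       name = paste0(d$name, "/test"))
  )
}

#' Fit a per-dimension min-max normalizer for the color inputs
#'
#' Each of the three CIELAB input dimensions is mapped affinely so that the
#' fitted minimum goes to `lo` and the fitted maximum to `hi`. Recipe outputs
#' are left in raw mass-fraction units (they already sit comfortably inside
#' both activations' ranges).
#'
#' @param d A non-empty `ccm_dataset` (normally the training split only).
#' @param lo,hi Target interval endpoints. The package default is
#'   `[0.1, 0.9]` for the logistic activation and `[-1, 1]` for the tangent
#'   activation (see [normalizer_for_activation()]).
#' @return A `ccm_normalizer` with per-dimension `min`, `max` and the target
#'   interval.
#' @export
fit_normalizer <- function(d, lo = 0.1, hi = 0.9) {
  stopifnot(inherits(d, "ccm_dataset"))
  if (n_samples(d) < 1L) stop("cannot fit a normalizer on an empty dataset")
  if (!(hi > lo)) stop("`hi` must exceed `lo`")
  mins <- apply(d$lab, 2, min)
  maxs <- apply(d$lab, 2, max)
  degenerate <- which(maxs - mins <= 0)
  if (length(degenerate)) {
    stop("degenerate (constant) input dimension(s): ",
         paste(LAB_COLS[degenerate], collapse = ", "))
  }
  structure(list(min = mins, max = maxs, lo = lo, hi = hi),
            class = "ccm_normalizer")
}

#' Interval defaults per activation
#'
#' Returns the normalization target interval used by the training pipelines:
#' `[0.1, 0.9]` for the logistic activation and `[-1, 1]` for the tangent
#' activation, keeping inputs away from the saturation asymptotes.
#'
#' @param activation `"logistic"` or `"tangent"`.
#' @return Numeric length-2 vector `c(lo, hi)`.
#' @export
normalizer_for_activation <- function(activation) {
  switch(match.arg(activation, c("logistic", "tangent", "linear")),
         logistic = c(0.1, 0.9),
         tangent = c(-1, 1),
         linear = c(-1, 1))
}

#' Apply or invert a fitted normalizer
#'
#' @param nrm A `ccm_normalizer` from [fit_normalizer()].
#' @param lab Numeric 3-vector or n x 3 matrix of CIELAB values (for
#'   `normalize_lab`) or normalized values (for `denormalize_lab`).
#' @return Matrix of the same shape, mapped into (out of) the target
#'   interval. `denormalize_lab(nrm, normalize_lab(nrm, x))` returns `x`
#'   to within 1e-12.
#' @export
normalize_lab <- function(nrm, lab) {
  stopifnot(inherits(nrm, "ccm_normalizer"))
  lab <- to_lab_matrix(lab)
  span <- nrm$max - nrm$min
  scaled <- sweep(lab, 2, nrm$min)
  scaled <- sweep(scaled, 2, span, "/")
  nrm$lo + scaled * (nrm$hi - nrm$lo)
}

#' @rdname normalize_lab
#' @export
denormalize_lab <- function(nrm, lab) {
  stopifnot(inherits(nrm, "ccm_normalizer"))
  lab <- to_lab_matrix(lab)
  span <- nrm$max - nrm$min
  scaled <- (lab - nrm$lo) / (nrm$hi - nrm$lo)
  sweep(sweep(scaled, 2, span, "*"), 2, nrm$min, "+")
}

to_lab_matrix <- function(lab) {
  if (is.null(dim(lab))) {
    if (length(lab) != 3L) stop("expected a 3-vector of L*, a*, b*")
    lab <- matrix(lab, nrow = 1L)
  }
  lab <- as.matrix(lab)
  if (ncol(lab) != 3L) stop("expected 3 columns (L*, a*, b*)")
  storage.mode(lab) <- "double"
  lab
}

#' Check that recipes obey the specimen composition law
#'
#' In the specimen database every recipe's five mass fractions are
#' non-negative multiples of 0.08 that sum to 0.40. Synthetic data follows
#' the same law.
#'
#' @param recipe 5-vector or n x 5 matrix of mass fractions.
#' @param tol Absolute tolerance.
#' @return Logical vector, one entry per recipe row.
#' @export
is_valid_recipe <- function(recipe, tol = 1e-9) {
  if (is.null(dim(recipe))) recipe <- matrix(recipe, nrow = 1L)
  ok_sum <- abs(rowSums(recipe) - RECIPE_TOTAL) <= tol
  units <- recipe / RECIPE_STEP
  ok_grid <- apply(abs(units - round(units)) <= tol / RECIPE_STEP, 1, all)
  ok_pos <- apply(recipe >= -tol, 1, all)
  ok_sum & ok_grid & ok_pos
}
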