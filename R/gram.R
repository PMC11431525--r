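#' Cached cross-product matrix for fast subset refits
#'
#' Subset searches evaluate thousands of candidate models on the same data.
#' All least-squares quantities for any subset can be read off the
#' cross-product (Gram) matrix of the column block `[1, X, y]`, so the cache
#' makes the cost of a refit independent of the number of observations.
#' `refresh_y()` swaps in a new response, touching only the final row/column
#' -- the hot path of the parametric bootstrap, where the design is fixed and
#' only the simulated response changes.
#'
#' @param data A data frame with the outcome and candidate predictor columns.
#' @param outcome Name of the outcome column in `data`.
#'
#' @return An object of class `"gram_cache"`: list with `G` (the
#'   `(p+2) x (p+2)` cross-product matrix), `n`, `p` and `names`
#'   (predictor labels).
#' @examples
#' d <- data.frame(y = rnorm(20), a = rnorm(20), b = rnorm(20))
#' g <- gram_cache(d, "y")
#' g$n
#' @export
gram_cache <- function(data, outcome) {
  ds <- split_outcome(data, outcome)
  B <- cbind(`(Intercept)` = 1, ds$X, .y = ds$y)
  structure(
    list(G = crossprod(B), n = ds$n, p = ds$p, names = ds$names),
    class = "gram_cache"
  )
}

#' @rdname gram_cache
#' @param gram A `"gram_cache"` object.
#' @param y New outcome vector of length `gram$n`.
#' @export
refresh_y <- function(gram, y) {
  stopifnot(inherits(gram, "gram_cache"))
  if (length(y) != gram$n) abort("replacement outcome has the wrong length.")
  if (anyNA(y)) abort("replacement outcome contains missing values.")
  m <- gram$p + 2
  G <- gram$G
  xty <- c(sum(y), crossprod_cols(gram, y))
  G[m, -m] <- xty
  G[-m, m] <- xty
  G[m, m] <- sum(y * y)
  gram$G <- G
  gram
}

# X'y for refresh_y without storing X: not possible from the Gram alone, so
# the cache optionally carries the design. gram_cache() stores it lazily only
# when refresh is requested on a cache built with keep_X = TRUE; the default
# refresh path therefore recomputes from the design kept on the cache.
crossprod_cols <- function(gram, y) {
  if (is.null(gram$X)) abort("this gram_cache was built without the design; rebuild with gram_cache_keep().")
  as.numeric(crossprod(gram$X, y))
}

#' @rdname gram_cache
#' @export
gram_cache_keep <- function(data, outcome) {
  g <- gram_cache(data, outcome)
  ds <- split_outcome(data, outcome)
  g$X <- ds$X
  g
}

#' @export
print.gram_cache <- function(x, ...) {
  cat(sprintf("<gram_cache> n = %d, p = %d predictors\n", x$n, x$p))
  invisible(x)
}

# ---- internal dataset validation -------------------------------------------

# Splits a data frame into (y, X) with the checks every entry point relies on:
# numeric columns, no missing values, unique labels.
split_outcome <- function(data, outcome, require_full_rank_n = FALSE) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  nm <- names(data)
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate column labels: %s",
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  if (!is.character(outcome) || length(outcome) != 1 || !outcome %in% nm)
    abort(sprintf("outcome column '%s' not found in `data`.", as.character(outcome)[1]))
  bad_type <- nm[!vapply(data, is.numeric, logical(1))]
  if (length(bad_type))
    abort(sprintf("non-numeric column(s): %s", paste(bad_type, collapse = ", ")))
  for (j in nm) {
    miss <- which(is.na(data[[j]]))
    if (length(miss))
      abort(sprintf("missing value in column '%s', row %d", j, miss[1]))
  }
  y <- as.numeric(data[[outcome]])
  pred <- setdiff(nm, outcome)
  X <- as.matrix(data[pred])
  n <- nrow(X)
  p <- ncol(X)
  if (p < 1) abort("no predictor columns remain after removing the outcome.")
  if (require_full_rank_n && n <= p + 1)
    abort(sprintf("full-model fitting needs n > p + 1 (n = %d, p = %d).", n, p))
  list(y = y, X = X, names = pred, n = n, p = p)
}

# Map user-supplied variable references (names or indices) to sorted integer
# indices into the predictor set.
match_vars <- function(vars, names, what = "variable") {
  if (is.null(vars) || length(vars) == 0) return(integer(0))
  if (is.character(vars)) {
    idx <- match(vars, names)
    if (anyNA(idx))
      abort(sprintf("unknown %s(s): %s", what,
                    paste(vars[is.na(idx)], collapse = ", ")))
  } else if (is.numeric(vars)) {
    idx <- as.integer(vars)
    if (any(idx < 1 | idx > length(names)))
      abort(sprintf("%s index out of range 1..%d", what, length(names)))
  } else {
    abort(sprintf("%s must be given as column names or indices.", what))
  }
  sort(unique(idx))
}
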