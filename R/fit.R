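#' Fit one predictor subset from a cached Gram matrix
#'
#' Solves the least-squares problem for the intercept plus the predictors in
#' `active`, entirely from the cross-product cache. The reported `-2 logLik`
#' uses the profiled Gaussian likelihood with the maximum-likelihood variance
#' `sigma2 = rss / n`, so `neg2ll = n * (log(2 * pi * rss / n) + 1)`, and the
#' penalized score is `q = neg2ll + lambda * length(active)`. The intercept is
#' always included and never counted in the penalty.
#'
#' @param gram A `"gram_cache"` object (see [gram_cache()]).
#' @param active Predictor subset, as column names or indices; may be empty.
#' @param lambda Non-negative per-parameter penalty.
#'
#' @return A list of class `"subset_fit"` with elements `active` (integer
#'   indices), `terms` (labels, intercept first), `coefficients`, `rss`,
#'   `neg2ll` and `q`.
#' @examples
#' d <- data.frame(y = rnorm(30), a = rnorm(30), b = rnorm(30))
#' g <- gram_cache(d, "y")
#' fit_subset(g, "a", lambda = 2)
#' fit_subset(g, character(0), lambda = 2)  # intercept-only
#' @export
fit_subset <- function(gram, active, lambda = 0) {
  stopifnot(inherits(gram, "gram_cache"))
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0)
    abort("`lambda` must be a single non-negative number.")
  act <- match_vars(active, gram$names, "predictor")
  res <- .cpp_gram_fit(gram$G, gram$n, act - 1L, lambda)
  structure(
    list(active = res$active + 1L,
         terms = c("(Intercept)", gram$names[res$active + 1L]),
         coefficients = setNames(res$coefficients,
                                 c("(Intercept)", gram$names[res$active + 1L])),
         rss = res$rss, neg2ll = res$neg2ll, q = res$q,
         lambda = lambda, n = gram$n),
    class = "subset_fit"
  )
}

#' @export
print.subset_fit <- function(x, ...) {
  cat(sprintf("<subset_fit> %d predictor(s), rss = %.4f, Q = %.4f (lambda = %.4g)\n",
              length(x$active), x$rss, x$q, x$lambda))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Squared Wald statistic from the full model
#'
#' The conventional full-model importance summary: for a single variable, the
#' squared t statistic of its coefficient in the model containing all
#' candidate predictors, using the unbiased variance estimate
#' `rss / (n - p - 1)`; for a set of variables, the Wald chi-squared quadratic
#' form for their joint exclusion.
#'
#' @param data A data frame with outcome and predictors.
#' @param outcome Name of the outcome column.
#' @param group Variable (or set of variables) to test, as names or indices
#'   into the predictor columns.
#'
#' @return A single number: the squared Wald statistic.
#' @examples
#' d <- data.frame(y = rnorm(40), a = rnorm(40), b = rnorm(40))
#' wald_squared(d, "y", "a")
#' @export
wald_squared <- function(data, outcome, group) {
  ds <- split_outcome(data, outcome, require_full_rank_n = TRUE)
  idx <- match_vars(group, ds$names, "group member")
  if (length(idx) == 0) abort("`group` must name at least one predictor.")
  w <- full_model_wald(ds)
  if (length(idx) == 1) return(unname(w$t[idx]^2))
  V <- w$vcov[idx + 1L, idx + 1L, drop = FALSE]
  b <- w$beta[idx + 1L]
  as.numeric(t(b) %*% solve(V, b))
}

# Full-model OLS pieces shared by wald_squared and the report tables.
full_model_wald <- function(ds) {
  Xf <- cbind(1, ds$X)
  M <- crossprod(Xf)
  piv <- diag(M)
  ch <- tryCatch(chol(M), error = function(e)
    abort("full model is rank deficient; drop collinear predictors."))
  Minv <- chol2inv(ch)
  beta <- Minv %*% crossprod(Xf, ds$y)
  rss <- sum((ds$y - Xf %*% beta)^2)
  dfres <- ds$n - ds$p - 1
  s2 <- rss / dfres
  vcov <- s2 * Minv
  se <- sqrt(diag(vcov))
  tstat <- as.numeric(beta) / se
  list(beta = as.numeric(beta), vcov = vcov, se = se,
       t = setNames(tstat[-1], ds$names), rss = rss, df = dfres,
       p = setNames(2 * pt(-abs(tstat[-1]), dfres), ds$names))
}
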