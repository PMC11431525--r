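#' Per-parameter penalty for an information criterion
#'
#' Best subset selection minimises `Q = -2 * logLik + lambda * k`, where `k`
#' counts the non-intercept coefficients in the model. `penalty_value()`
#' returns the per-parameter penalty `lambda` implied by a criterion at a
#' given sample size: AIC uses `lambda = 2`, BIC uses `lambda = log(n)` and
#' HQIC uses `lambda = 2 * log(log(n))`.
#'
#' @param criterion One of `"AIC"`, `"BIC"`, `"HQIC"` or `"custom"`
#'   (case-insensitive).
#' @param n Sample size; required for BIC and HQIC.
#' @param lambda Penalty value when `criterion = "custom"`; must be `>= 0`.
#'
#' @return An object of class `"penalty"`: a list with elements `criterion`
#'   and `lambda`.
#' @examples
#' penalty_value("AIC")
#' penalty_value("BIC", n = 250)
#' penalty_value("HQIC", n = 1000)
#' penalty_value("custom", lambda = 4)
#' @export
penalty_value <- function(criterion, n = NULL, lambda = NULL) {
  crit <- toupper(match.arg(tolower(criterion),
                            c("aic", "bic", "hqic", "custom")))
  lam <- switch(crit,
    AIC = 2,
    BIC = {
      if (is.null(n)) abort("BIC requires the sample size `n`.")
      if (n < 1) abort("BIC requires n >= 1.")
      log(n)
    },
    HQIC = {
      if (is.null(n)) abort("HQIC requires the sample size `n`.")
      if (n < 3) abort("HQIC requires n >= 3 (2*log(log(n)) is undefined or negative below that).")
      2 * log(log(n))
    },
    CUSTOM = {
      if (is.null(lambda)) abort("criterion = \"custom\" requires `lambda`.")
      if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) || lambda < 0)
        abort("custom `lambda` must be a single non-negative number.")
      as.numeric(lambda)
    }
  )
  structure(list(criterion = crit, lambda = lam), class = "penalty")
}

#' @export
print.penalty <- function(x, ...) {
  cat(sprintf("<penalty> %s: lambda = %.6g\n", x$criterion, x$lambda))
  invisible(x)
}

# Resolve (criterion, lambda) arguments used across the user-facing functions.
resolve_penalty <- function(criterion, n, lambda = NULL) {
  if (inherits(criterion, "penalty")) return(criterion)
  penalty_value(criterion, n = n, lambda = lambda)
}
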