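#' Standardize predictor columns
#'
#' Centers every predictor and scales it to unit sample standard deviation
#' (denominator `n - 1`); the outcome column is left untouched. Because the
#' intercept is always in the model, subset-selection results -- active sets,
#' Q differences, VI and mVI -- are identical before and after; only the
#' coefficient scale changes (standardized slope = raw slope * sd of the
#' column). The original centers/scales are attached so raw coefficients stay
#' recoverable.
#'
#' @param data A data frame with outcome and predictors.
#' @param outcome Name of the outcome column.
#'
#' @return A tibble like `data` with predictors standardized, carrying
#'   attributes `scaled_center` and `scaled_scale` (named numeric vectors).
#' @examples
#' d <- data.frame(y = rnorm(30), a = 5 + 2 * rnorm(30), b = rnorm(30))
#' s <- standardize_predictors(d, "y")
#' round(vapply(s[c("a", "b")], sd, numeric(1)), 10)
#' @export
standardize_predictors <- function(data, outcome) {
  ds <- split_outcome(data, outcome)
  scales <- vapply(as.data.frame(ds$X), sd, numeric(1))
  if (any(scales <= 0)) {
    abort(sprintf("constant predictor column(s) cannot be standardized: %s",
                  paste(ds$names[scales <= 0], collapse = ", ")))
  }
  centers <- colMeans(ds$X)
  out <- tibble::as_tibble(data)
  for (j in ds$names) out[[j]] <- (out[[j]] - centers[[j]]) / scales[[j]]
  attr(out, "scaled_center") <- setNames(centers, ds$names)
  attr(out, "scaled_scale") <- setNames(scales, ds$names)
  out
}
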