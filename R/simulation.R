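#' Equicorrelation covariance matrix
#'
#' `rho * J + (1 - rho) * I`: unit variances, all pairwise correlations equal
#' to `rho`. Positive definite for `-1/(p-1) < rho < 1` (eigenvalues
#' `1 + (p-1) rho` and `1 - rho`).
#'
#' @param p Dimension.
#' @param rho Common correlation.
#' @return A `p x p` covariance matrix.
#' @examples
#' equicorrelation_matrix(6, 0.9)[1:2, 1:2]
#' @export
equicorrelation_matrix <- function(p, rho) {
  if (p < 1) abort("`p` must be >= 1.")
  if (p > 1 && (rho <= -1 / (p - 1) || rho >= 1))
    abort(sprintf("equicorrelation matrix is not positive definite: need -1/(p-1) < rho < 1, got rho = %g with p = %d.", rho, p))
  matrix(rho, p, p) + diag(1 - rho, p)
}

#' Noise variance implied by a signal-to-noise ratio
#'
#' With `SNR = Var(x' beta) / sigma2` and `Var(x' beta) = beta' Sigma beta`,
#' the noise variance is `sigma2 = beta' Sigma beta / SNR`. The population
#' coefficient of determination is then `R2 = SNR / (1 + SNR)` (e.g.
#' `SNR = 3/7` gives `R2 = 0.3`).
#'
#' @param beta Coefficient vector (excluding intercept).
#' @param Sigma Covariance matrix of the predictors.
#' @param snr Signal-to-noise ratio, `> 0`.
#' @return The noise variance `sigma2`.
#' @examples
#' sigma2_from_snr(c(1, 0), diag(2), snr = 1)
#' @export
sigma2_from_snr <- function(beta, Sigma, snr) {
  if (!is.numeric(snr) || length(snr) != 1 || snr <= 0)
    abort("`snr` must be a single positive number.")
  as.numeric(t(beta) %*% Sigma %*% beta) / snr
}

#' Simulation design for the null-distribution and type-I-error studies
#'
#' The generating model: covariates `x_i ~ N_p(1, Sigma)` with
#' `Sigma = rho J + (1 - rho) I`; a base coefficient vector (default
#' `(2, 3, 4, 5, 6, 7)`) of which `n_null` entries (default 3), chosen
#' uniformly at random per dataset, are set to zero, creating true-null
#' effects whose p-values calibrate the tests; response
#' `y_i ~ N(x_i' beta + 1, sigma2)` with `sigma2` set from the
#' signal-to-noise ratio (default `3/7`, i.e. `R2 = 0.3` -- a deliberately
#' noisy regime). The noise variance is computed from the *post-zeroing*
#' coefficients, i.e. from the model that actually generates the data;
#' `sigma2_from` switches to the pre-zeroing vector.
#'
#' @param beta_base Base coefficient vector.
#' @param n_null How many coefficients are zeroed per dataset.
#' @param rho Common predictor correlation.
#' @param snr Signal-to-noise ratio.
#' @param n Observations per dataset.
#' @param sigma2_from `"post_zero"` (default) or `"pre_zero"`.
#' @return A `"sim_design"` object.
#' @examples
#' sim_design(rho = 0.9)
#' @export
sim_design <- function(beta_base = c(2, 3, 4, 5, 6, 7), n_null = 3,
                       rho = 0, snr = 3 / 7, n = 1000,
                       sigma2_from = c("post_zero", "pre_zero")) {
  sigma2_from <- match.arg(sigma2_from)
  p <- length(beta_base)
  if (n_null < 0 || n_null > p) abort("`n_null` must be between 0 and length(beta_base).")
  Sigma <- equicorrelation_matrix(p, rho)
  structure(
    list(beta_base = beta_base, n_null = n_null, rho = rho, snr = snr,
         n = n, p = p, Sigma = Sigma, sigma2_from = sigma2_from),
    class = "sim_design"
  )
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("<sim_design> p = %d, n = %d, rho = %.3g, SNR = %.4g, %d null effect(s)\n",
              x$p, x$n, x$rho, x$snr, x$n_null))
  invisible(x)
}

#' Simulate one dataset from a design
#'
#' @param design A [sim_design()] object.
#' @param seed Integer seed; the draw is fully reproducible from it.
#' @return A tibble with columns `y`, `x1..xp`, carrying attributes `beta`
#'   (post-zeroing coefficients), `null_idx` (indices of the zeroed, i.e.
#'   true-null, coefficients) and `sigma2`.
#' @examples
#' d <- simulate_dataset(sim_design(n = 100), seed = 1)
#' attr(d, "null_idx")
#' @export
simulate_dataset <- function(design, seed) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(seed)
  p <- design$p
  null_idx <- sort(sample.int(p, design$n_null))
  beta <- design$beta_base
  beta[null_idx] <- 0
  sigma2 <- sigma2_from_snr(
    if (design$sigma2_from == "post_zero") beta else design$beta_base,
    design$Sigma, design$snr)
  R <- chol(design$Sigma)
  X <- matrix(rnorm(design$n * p), design$n, p) %*% R + 1
  y <- as.numeric(X %*% beta) + 1 + rnorm(design$n, sd = sqrt(sigma2))
  out <- tibble::as_tibble(as.data.frame(X, col.names = paste0("x", 1:p)))
  names(out) <- paste0("x", 1:p)
  out <- tibble::add_column(out, y = y, .before = 1)
  attr(out, "beta") <- beta
  attr(out, "null_idx") <- null_idx
  attr(out, "sigma2") <- sigma2
  out
}

#' Pooled null distribution of mVI
#'
#' Generates `n_models` datasets from the design and computes the mVI of
#' every true-null coefficient (so `n_null` draws per dataset, pooled). Under
#' independence (`rho = 0`) the pooled draws are roughly chi-squared with 1
#' degree of freedom; under strong correlation they deviate, increasingly so
#' as the penalty grows.
#'
#' @inheritParams simulate_dataset
#' @param n_models Number of simulated datasets.
#' @param criterion,lambda Selection penalty (see [penalty_value()]).
#' @param seed Root seed; dataset `i` uses `seed + i`.
#' @return A tibble (class `"vi_nulldist"`) with columns `model`, `variable`,
#'   `mvi`.
#' @examples
#' nd <- null_mvi_distribution(sim_design(n = 200), n_models = 20, seed = 1)
#' all(nd$mvi >= 0)
#' @export
null_mvi_distribution <- function(design, n_models = 1000,
                                  criterion = "AIC", lambda = NULL, seed = 1) {
  stopifnot(inherits(design, "sim_design"))
  if (n_models < 1) abort("`n_models` must be >= 1.")
  pen <- resolve_penalty(criterion, n = design$n, lambda = lambda)
  rows <- vector("list", n_models)
  for (i in seq_len(n_models)) {
    d <- simulate_dataset(design, seed = seed + i)
    X <- as.matrix(d[paste0("x", 1:design$p)])
    nil <- attr(d, "null_idx")
    mvis <- vapply(nil, function(v) {
      as.numeric(.cpp_mvi_boot(X, d$y, v - 1L, pen$lambda, 0L, TRUE)$mvi_obs)
    }, numeric(1))
    rows[[i]] <- tibble::tibble(model = i, variable = nil, mvi = mvis)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("vi_nulldist", class(out))
  attr(out, "criterion") <- pen$criterion
  attr(out, "lambda") <- pen$lambda
  attr(out, "design") <- design
  out
}

#' Empirical type-I error of mVI-based tests
#'
#' Simulates datasets from the design, computes a p-value for every true-null
#' coefficient under each criterion -- either the naive chi-squared reference
#' or the parametric bootstrap -- and tabulates the fraction rejected at each
#' nominal level.
#'
#' @inheritParams null_mvi_distribution
#' @param method `"naive"` (chi-squared reference) or `"bootstrap"`.
#' @param criteria Criteria to evaluate (share the same simulated data and,
#'   for the bootstrap, the same replicate responses).
#' @param levels Nominal significance levels.
#' @param nboot Bootstrap replicates per p-value (`method = "bootstrap"`).
#' @return A tibble (class `"vi_type1"`) with columns `criterion`, `level`,
#'   `rate`, `mc_se` (binomial standard error of the estimated rate) and `n`
#'   (number of null p-values). The underlying p-values are kept in
#'   `attr(, "pvalues")`.
#' @examples
#' r <- type1_error_rates(sim_design(n = 200), method = "naive",
#'                        criteria = "AIC", n_models = 20, seed = 1)
#' r
#' @export
type1_error_rates <- function(design, method = c("naive", "bootstrap"),
                              criteria = c("AIC", "BIC", "HQIC"),
                              levels = c(0.01, 0.05, 0.10),
                              n_models = 1000, nboot = 100, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(design, "sim_design"))
  if (any(levels < 0 | levels >= 1)) abort("`levels` must lie in [0, 1).")
  pens <- lapply(criteria, resolve_penalty, n = design$n)
  lambdas <- vapply(pens, `[[`, numeric(1), "lambda")
  crit_names <- vapply(pens, `[[`, character(1), "criterion")

  pvals <- vector("list", n_models)
  B <- if (method == "bootstrap") as.integer(nboot) else 0L
  for (i in seq_len(n_models)) {
    d <- simulate_dataset(design, seed = seed + i)
    X <- as.matrix(d[paste0("x", 1:design$p)])
    nil <- attr(d, "null_idx")
    pv <- matrix(NA_real_, length(nil), length(lambdas))
    for (k in seq_along(nil)) {
      res <- .cpp_mvi_boot(X, d$y, nil[k] - 1L, lambdas, B, TRUE)
      pv[k, ] <- if (method == "naive") {
        chisq_pvalue(as.numeric(res$mvi_obs), df = 1)
      } else {
        vapply(seq_along(lambdas), function(l)
          bootstrap_pvalue(res$mvi_obs[l], res$draws[, l]), numeric(1))
      }
    }
    colnames(pv) <- crit_names
    pvals[[i]] <- tibble::as_tibble(pv)
  }
  pv_all <- dplyr::bind_rows(pvals)
  n_p <- nrow(pv_all)

  out <- tidyr::expand_grid(criterion = crit_names, level = sort(levels))
  out$rate <- purrr::map2_dbl(out$criterion, out$level,
                              function(cr, al) mean(pv_all[[cr]] <= al))
  out$mc_se <- sqrt(out$rate * (1 - out$rate) / n_p)
  out$n <- n_p
  class(out) <- c("vi_type1", class(out))
  attr(out, "pvalues") <- pv_all
  attr(out, "method") <- method
  attr(out, "design") <- design
  attr(out, "nboot") <- if (method == "bootstrap") as.integer(nboot) else NA_integer_
  attr(out, "seed") <- seed
  out
}
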