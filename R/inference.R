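#' Naive chi-squared p-value for mVI
#'
#' Under independence the null distribution of `mVI` for a set of `df`
#' variables is roughly chi-squared with `df` degrees of freedom; this
#' returns the upper-tail probability. The approximation degrades -- and the
#' resulting test over-rejects -- when predictors are strongly correlated and
#' the penalty grows with `n` (BIC, HQIC); prefer the parametric bootstrap in
#' those settings.
#'
#' @param mvi_obs Observed mVI value(s); must be non-negative (a negative
#'   value signals a heuristic-engine artifact, since exact engines guarantee
#'   `mVI >= 0`).
#' @param df Degrees of freedom: the group size `|S|`.
#' @return Upper-tail p-value(s) in `(0, 1]`.
#' @examples
#' chisq_pvalue(3.841459, df = 1)  # ~0.05
#' @export
chisq_pvalue <- function(mvi_obs, df = 1) {
  if (any(mvi_obs < 0))
    abort("negative mVI: exact search engines guarantee mVI >= 0; a negative value indicates a heuristic-engine artifact.")
  if (any(df < 1)) abort("`df` must be >= 1.")
  pchisq(mvi_obs, df = df, lower.tail = FALSE)
}

#' Parametric-bootstrap null sample for mVI
#'
#' Approximates the null distribution of `mVI` for one variable group by the
#' parametric bootstrap: the Gaussian model containing every predictor
#' *except* the group is fit, new responses are simulated from it
#' (`y* = fitted + N(0, sigma2)` with `sigma2 = rss / n` by default), and the
#' group's mVI is recomputed on each simulated response with the design held
#' fixed -- which preserves the correlation structure among the predictors.
#' Each replicate costs two constrained best-subset searches; these run on
#' cached cross-products so the per-replicate cost does not grow with `n`.
#'
#' @inheritParams variable_importance
#' @param nboot Number of bootstrap replicates `B`.
#' @param seed Optional integer seed (set before drawing).
#' @param sigma2 Variance estimate used by the generator: `"mle"`
#'   (`rss / n`, coherent with the profile likelihood) or `"unbiased"`
#'   (`rss / (n - k)`).
#'
#' @return An object of class `"vi_boot"`: list with `group`, `mvi_obs`,
#'   `draws` (length-`B` non-negative vector), `p` (add-one estimator),
#'   `criterion`, `lambda`, `nboot`, `n_searches`.
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rnorm(60), x2 = rnorm(60))
#' d$y <- d$x1 + rnorm(60)
#' bootstrap_null_sample(d, "y", group = "x2", criterion = "AIC",
#'                       nboot = 20, seed = 7)$p
#' @export
bootstrap_null_sample <- function(data, outcome = NULL, group,
                                  criterion = "AIC", lambda = NULL,
                                  nboot = 100, seed = NULL,
                                  sigma2 = c("mle", "unbiased"),
                                  engine = "exhaustive") {
  sigma2 <- match.arg(sigma2)
  if (nboot < 1) abort("`nboot` must be >= 1.")
  ds <- split_outcome(data, outcome)
  pen <- resolve_penalty(criterion, n = ds$n, lambda = lambda)
  idx <- match_vars(group, ds$names, "group member")
  if (length(idx) == 0) abort("`group` must contain at least one predictor.")
  if (!is.null(seed)) set.seed(seed)
  res <- .cpp_mvi_boot(ds$X, ds$y, idx - 1L, pen$lambda, as.integer(nboot),
                       sigma2 == "mle")
  draws <- as.numeric(res$draws)
  structure(
    list(group = paste(ds$names[idx], collapse = "+"),
         members = ds$names[idx],
         mvi_obs = as.numeric(res$mvi_obs), draws = draws,
         p = bootstrap_pvalue(as.numeric(res$mvi_obs), draws),
         sigma2 = res$sigma2,
         criterion = pen$criterion, lambda = pen$lambda,
         nboot = as.integer(nboot), n_searches = res$n_searches),
    class = "vi_boot"
  )
}

#' @export
print.vi_boot <- function(x, ...) {
  cat(sprintf("<vi_boot> group %s, %s (lambda = %.4g)\n",
              x$group, x$criterion, x$lambda))
  cat(sprintf("  mVI = %.4f, B = %d null draws, p = %.4f\n",
              x$mvi_obs, x$nboot, x$p))
  invisible(x)
}

#' Bootstrap p-value from null draws
#'
#' Add-one estimator `p = (1 + #\{draws >= mvi_obs\}) / (B + 1)`, which is
#' never zero and yields a valid test at any finite `B`.
#'
#' @param mvi_obs Observed statistic.
#' @param draws Numeric vector of null draws.
#' @return p-value in `(0, 1]`.
#' @examples
#' bootstrap_pvalue(2.5, rchisq(99, 1))
#' @export
bootstrap_pvalue <- function(mvi_obs, draws) {
  if (length(draws) == 0) abort("`draws` must be non-empty.")
  (1 + sum(draws >= mvi_obs)) / (length(draws) + 1)
}

#' p-value table across criteria
#'
#' One row per variable group: the full-model Wald p-value, then for each
#' criterion the mVI p-value (parametric bootstrap by default, or the naive
#' chi-squared reference) and the post-selection Wald p-value from the model
#' selected by that criterion (`NA` for groups not fully included -- those
#' variables have no coefficient in the selected model). No multiplicity
#' adjustment is applied; the columns are raw per-group p-values.
#'
#' @inheritParams importance_table
#' @inheritParams bootstrap_null_sample
#' @param method `"bootstrap"` or `"chisq"`.
#' @param seed Root seed; each group gets a deterministic substream
#'   (`seed + 7919 * group index`).
#'
#' @return A tibble (class `"vi_pvalues"`) with columns `group`,
#'   `p_full_wald`, then `p_<criterion>` and `p_wald_<criterion>` per
#'   criterion. Attribute `n_searches_per_criterion` counts the constrained
#'   searches spent on null draws (2 * #groups * B for singleton groupings).
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rnorm(60), x2 = rnorm(60))
#' d$y <- d$x1 + rnorm(60)
#' pvalue_table(d, "y", criteria = "AIC", nboot = 20, seed = 3)
#' @export
pvalue_table <- function(data, outcome, groups = NULL,
                         criteria = c("AIC", "HQIC", "BIC"),
                         method = c("bootstrap", "chisq"),
                         nboot = 100, seed = 1,
                         sigma2 = c("mle", "unbiased")) {
  method <- match.arg(method)
  sigma2 <- match.arg(sigma2)
  ds <- split_outcome(data, outcome, require_full_rank_n = TRUE)
  gram <- gram_cache(data, outcome)
  groups <- resolve_groups(groups, gram$names)
  pens <- lapply(criteria, resolve_penalty, n = gram$n)
  lambdas <- vapply(pens, `[[`, numeric(1), "lambda")
  crit_names <- vapply(pens, `[[`, character(1), "criterion")

  w <- full_model_wald(ds)
  p_full <- vapply(groups, function(g) {
    idx <- match_vars(g, ds$names, "group member")
    if (length(idx) == 1) return(unname(w$p[idx]))
    stat <- wald_squared(data, outcome, g)
    pchisq(stat, df = length(idx), lower.tail = FALSE)
  }, numeric(1))
  out <- tibble::tibble(group = names(groups), p_full_wald = unname(p_full))

  # mVI p-values; bootstrap draws are shared across criteria (the null
  # generator does not depend on lambda)
  total_searches <- 0
  pmat <- matrix(NA_real_, nrow = length(groups), ncol = length(pens))
  for (i in seq_along(groups)) {
    idx <- match_vars(groups[[i]], ds$names, "group member")
    if (method == "chisq") {
      for (l in seq_along(pens)) {
        rec <- variable_importance(gram, group = idx, criterion = pens[[l]],
                                   engine = "exhaustive")
        pmat[i, l] <- chisq_pvalue(rec$mvi, df = length(idx))
      }
    } else {
      set.seed((seed + 7919L * i) %% .Machine$integer.max)
      res <- .cpp_mvi_boot(ds$X, ds$y, idx - 1L, lambdas, as.integer(nboot),
                           sigma2 == "mle")
      for (l in seq_along(pens))
        pmat[i, l] <- bootstrap_pvalue(res$mvi_obs[l], res$draws[, l])
      total_searches <- total_searches + res$n_searches
    }
  }

  # post-selection Wald p-values from each criterion's selected model
  for (l in seq_along(pens)) {
    sel <- best_subset(gram, criterion = pens[[l]])
    psel <- rep(NA_real_, length(groups))
    if (length(sel$active) > 0 && ds$n > length(sel$active) + 1) {
      sub <- as.data.frame(data)[c(outcome, gram$names[sel$active])]
      wsel <- full_model_wald(split_outcome(sub, outcome))
      for (i in seq_along(groups)) {
        idx <- match_vars(groups[[i]], ds$names, "group member")
        if (all(idx %in% sel$active)) {
          pos <- match(gram$names[idx], names(wsel$p))
          psel[i] <- if (length(pos) == 1) unname(wsel$p[pos]) else {
            stat_idx <- match(gram$names[idx], names(wsel$p))
            V <- wsel$vcov[stat_idx + 1L, stat_idx + 1L, drop = FALSE]
            b <- wsel$beta[stat_idx + 1L]
            pchisq(as.numeric(t(b) %*% solve(V, b)), df = length(idx),
                   lower.tail = FALSE)
          }
        }
      }
    }
    out[[paste0("p_", crit_names[l])]] <- pmat[, l]
    out[[paste0("p_wald_", crit_names[l])]] <- psel
  }
  class(out) <- c("vi_pvalues", class(out))
  attr(out, "method") <- method
  attr(out, "nboot") <- as.integer(nboot)
  attr(out, "n_searches_per_criterion") <-
    if (method == "bootstrap") total_searches / length(pens) else 0
  out
}
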