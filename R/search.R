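#' Best subset selection under an L0-penalized Gaussian likelihood
#'
#' Finds the predictor subset minimising `Q = -2 logLik + lambda * |A|`,
#' optionally under force-include / force-exclude constraints. Two exact
#' engines are available -- exhaustive enumeration (guarded at 25 free
#' variables) and a branch-and-bound search that prunes a node whenever even
#' the fully saturated descendant cannot beat the incumbent -- plus greedy
#' forward-selection and backward-elimination heuristics. Exact engines break
#' Q ties (within 1e-9) in favour of fewer variables, then the
#' lexicographically smallest index sequence, so results are deterministic.
#'
#' @param data A data frame with outcome and predictors, or a
#'   `"gram_cache"` built from one.
#' @param outcome Name of the outcome column (ignored when `data` is already
#'   a `gram_cache`).
#' @param criterion `"AIC"`, `"BIC"`, `"HQIC"` or `"custom"`; alternatively a
#'   `"penalty"` object.
#' @param lambda Penalty value for `criterion = "custom"`.
#' @param engine `"branch_and_bound"` (default), `"exhaustive"`, `"forward"`
#'   or `"backward"`.
#' @param force_in,force_out Predictors (names or indices) constrained into /
#'   out of every candidate model; must be disjoint.
#'
#' @return An object of class `"best_subset"`: the selected active set,
#'   coefficients, `rss`, `neg2ll`, minimised `q`, penalty, engine and node
#'   diagnostics. Use [tidy()] / [glance()] for tibble summaries.
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rnorm(80), x2 = rnorm(80), x3 = rnorm(80))
#' d$y <- 2 * d$x1 + rnorm(80)
#' best_subset(d, "y", criterion = "BIC")
#' @export
best_subset <- function(data, outcome = NULL, criterion = "AIC", lambda = NULL,
                        engine = c("branch_and_bound", "exhaustive",
                                   "forward", "backward"),
                        force_in = NULL, force_out = NULL) {
  engine <- match.arg(engine)
  gram <- if (inherits(data, "gram_cache")) data else gram_cache(data, outcome)
  pen <- resolve_penalty(criterion, n = gram$n, lambda = lambda)
  fin <- match_vars(force_in, gram$names, "force_in")
  fout <- match_vars(force_out, gram$names, "force_out")
  if (length(intersect(fin, fout)))
    abort("force_in and force_out must be disjoint.")

  if (engine %in% c("exhaustive", "branch_and_bound")) {
    res <- .cpp_search(gram$G, gram$n, pen$lambda, fin - 1L, fout - 1L, engine)
    active <- res$active + 1L
    nodes <- res$nodes
    fit <- list(coefficients = res$coefficients, rss = res$rss,
                neg2ll = res$neg2ll, q = res$q)
  } else {
    res <- greedy_search(gram, pen$lambda, fin, fout, engine)
    active <- res$active
    nodes <- res$nodes
    fit <- res$fit
  }

  structure(
    list(active = active,
         terms = gram$names[active],
         coefficients = setNames(fit$coefficients,
                                 c("(Intercept)", gram$names[active])),
         rss = fit$rss, neg2ll = fit$neg2ll, q = fit$q,
         penalty = pen, engine = engine, nodes_visited = nodes,
         force_in = fin, force_out = fout,
         n = gram$n, p = gram$p, names = gram$names),
    class = "best_subset"
  )
}

# Greedy forward/backward passes. Locally optimal only; q >= exact minimum.
greedy_search <- function(gram, lambda, fin, fout, engine) {
  free <- setdiff(seq_len(gram$p), c(fin, fout))
  nodes <- 0L
  q_of <- function(act) {
    nodes <<- nodes + 1L
    fit_subset(gram, act, lambda)
  }
  cur <- if (engine == "forward") sort(fin) else sort(c(fin, free))
  fit <- q_of(cur)
  repeat {
    moves <- if (engine == "forward") setdiff(free, cur) else setdiff(cur, fin)
    if (!length(moves)) break
    cand <- lapply(moves, function(v) {
      act <- if (engine == "forward") sort(c(cur, v)) else setdiff(cur, v)
      q_of(act)
    })
    qs <- vapply(cand, `[[`, numeric(1), "q")
    best <- which.min(qs)
    if (qs[best] < fit$q - 1e-9) {
      fit <- cand[[best]]
      cur <- fit$active
    } else break
  }
  list(active = sort(cur), fit = fit, nodes = nodes)
}

#' @export
print.best_subset <- function(x, ...) {
  cat(sprintf("<best_subset> %s (lambda = %.4g), engine = %s\n",
              x$penalty$criterion, x$penalty$lambda, x$engine))
  cat(sprintf("  selected %d of %d predictors: %s\n", length(x$active), x$p,
              if (length(x$terms)) paste(x$terms, collapse = ", ") else "(none)"))
  cat(sprintf("  Q = %.4f, -2 logLik = %.4f, rss = %.4f\n",
              x$q, x$neg2ll, x$rss))
  invisible(x)
}

#' @rdname best_subset
#' @param x A `"best_subset"` object.
#' @param ... Unused.
#' @export
tidy.best_subset <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    selected = TRUE
  )
}

#' @rdname best_subset
#' @export
glance.best_subset <- function(x, ...) {
  tibble::tibble(
    criterion = x$penalty$criterion, lambda = x$penalty$lambda,
    engine = x$engine, n_selected = length(x$active),
    q = x$q, neg2ll = x$neg2ll, rss = x$rss,
    nodes_visited = x$nodes_visited, n = x$n, p = x$p
  )
}
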