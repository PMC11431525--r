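#' Variable importance under best subset selection
#'
#' For a variable (or set of variables) `S`, the importance statistic is the
#' gap between the two constrained optima of the penalized score:
#' `VI = min Q(excluding S) - min Q(including S)`, where "including" forces
#' every member of `S` into the model and "excluding" forces every member
#' out. `VI > 0` exactly when `S` belongs to the unconstrained best subset;
#' it is bounded below by `-lambda * |S|`. The modified statistic
#' `mVI = VI + lambda * |S|` is non-negative and serves as the test statistic
#' for inference (see [chisq_pvalue()] and [bootstrap_null_sample()]).
#'
#' @inheritParams best_subset
#' @param group Members of the variable set, as predictor names or indices.
#' @param unconstrained Optionally, a precomputed unconstrained
#'   [best_subset()] result for the same data/penalty, used to set the
#'   `selected` flag without re-searching.
#'
#' @return A one-row tibble (class `"vi_record"`) with columns `group`
#'   (label), `members` (list of names), `size`, `vi`, `mvi`, `selected`,
#'   `q_excluded`, `q_included`, `criterion`, `lambda` and `engine`.
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rnorm(60), x2 = rnorm(60))
#' d$y <- d$x1 + rnorm(60)
#' variable_importance(d, "y", group = "x1", criterion = "AIC")
#' @export
variable_importance <- function(data, outcome = NULL, group,
                                criterion = "AIC", lambda = NULL,
                                engine = c("branch_and_bound", "exhaustive",
                                           "forward", "backward"),
                                force_in = NULL, force_out = NULL,
                                unconstrained = NULL) {
  engine <- match.arg(engine)
  gram <- if (inherits(data, "gram_cache")) data else gram_cache(data, outcome)
  pen <- resolve_penalty(criterion, n = gram$n, lambda = lambda)
  idx <- match_vars(group, gram$names, "group member")
  if (length(idx) == 0) abort("`group` must contain at least one predictor.")
  fin <- match_vars(force_in, gram$names, "force_in")
  fout <- match_vars(force_out, gram$names, "force_out")
  if (length(intersect(idx, c(fin, fout))))
    abort("`group` must be disjoint from force_in and force_out.")
  if (engine %in% c("forward", "backward"))
    warning("heuristic engines do not guarantee mVI >= 0; exact engines do.",
            call. = FALSE)

  excl <- best_subset(gram, criterion = pen, engine = engine,
                      force_in = fin, force_out = sort(c(fout, idx)))
  incl <- best_subset(gram, criterion = pen, engine = engine,
                      force_in = sort(c(fin, idx)), force_out = fout)
  vi <- excl$q - incl$q
  mvi <- vi + pen$lambda * length(idx)

  if (is.null(unconstrained)) {
    unconstrained <- best_subset(gram, criterion = pen, engine = engine,
                                 force_in = fin, force_out = fout)
  }
  selected <- all(idx %in% unconstrained$active)

  out <- tibble::tibble(
    group = paste(gram$names[idx], collapse = "+"),
    members = list(gram$names[idx]),
    size = length(idx),
    vi = vi, mvi = mvi, selected = selected,
    q_excluded = excl$q, q_included = incl$q,
    criterion = pen$criterion, lambda = pen$lambda, engine = engine
  )
  class(out) <- c("vi_record", class(out))
  out
}

#' Modified variable importance from a computed record
#'
#' Applies the shift `mVI = VI + lambda * |S|` to an importance record,
#' checking that the penalty used to compute the record matches.
#'
#' @param record A `"vi_record"` row from [variable_importance()].
#' @param penalty A `"penalty"` object (or criterion name resolvable without
#'   `n`, e.g. `"AIC"`).
#' @return The non-negative mVI value.
#' @export
modified_importance <- function(record, penalty) {
  if (!inherits(record, "vi_record")) abort("`record` must be a vi_record.")
  if (!inherits(penalty, "penalty"))
    abort("`penalty` must be a penalty object from penalty_value().")
  if (abs(record$lambda - penalty$lambda) > 1e-12)
    abort(sprintf("penalty mismatch: record used lambda = %.6g, supplied %.6g",
                  record$lambda, penalty$lambda))
  record$vi + penalty$lambda * record$size
}

#' Importance table across criteria
#'
#' One row per variable group: the full-model squared Wald statistic (the
#' conventional importance summary) alongside `vi` and `mvi` for each
#' selection criterion.
#'
#' @inheritParams best_subset
#' @param groups A named list of predictor-name vectors. Defaults to one
#'   singleton group per predictor.
#' @param criteria Character vector of criteria to tabulate.
#'
#' @return A tibble (class `"vi_table"`) with columns `group`, `wald`, then
#'   `vi_<criterion>`, `mvi_<criterion>` and `in_<criterion>` per criterion.
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rnorm(60), x2 = rnorm(60))
#' d$y <- d$x1 + rnorm(60)
#' importance_table(d, "y", criteria = c("AIC", "BIC"))
#' @export
importance_table <- function(data, outcome, groups = NULL,
                             criteria = c("AIC", "HQIC", "BIC"),
                             engine = c("branch_and_bound", "exhaustive",
                                        "forward", "backward")) {
  engine <- match.arg(engine)
  ds <- split_outcome(data, outcome, require_full_rank_n = TRUE)
  gram <- gram_cache(data, outcome)
  groups <- resolve_groups(groups, gram$names)

  wald <- vapply(groups, function(g) wald_squared(data, outcome, g), numeric(1))
  out <- tibble::tibble(group = names(groups), wald = unname(wald))

  for (crit in criteria) {
    pen <- resolve_penalty(crit, n = gram$n)
    opt <- best_subset(gram, criterion = pen, engine = engine)
    recs <- purrr::map(groups, function(g) {
      variable_importance(gram, group = g, criterion = pen, engine = engine,
                          unconstrained = opt)
    })
    out[[paste0("vi_", pen$criterion)]] <-
      unname(vapply(recs, `[[`, numeric(1), "vi"))
    out[[paste0("mvi_", pen$criterion)]] <-
      unname(vapply(recs, `[[`, numeric(1), "mvi"))
    out[[paste0("in_", pen$criterion)]] <-
      unname(vapply(recs, `[[`, logical(1), "selected"))
  }
  class(out) <- c("vi_table", class(out))
  attr(out, "criteria") <- toupper(criteria)
  out
}

# Normalise a grouping: named list of member vectors; default singletons.
# Groups must be non-empty and pairwise disjoint.
resolve_groups <- function(groups, names) {
  if (is.null(groups)) {
    groups <- as.list(names)
    names(groups) <- names
  }
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    abort("`groups` must be a named list of predictor-name vectors.")
  idx <- lapply(groups, match_vars, names = names, what = "group member")
  if (any(lengths(idx) == 0)) abort("every group must be non-empty.")
  all_idx <- unlist(idx)
  if (anyDuplicated(all_idx))
    abort("groups must be disjoint (a predictor appears in two groups).")
  lapply(idx, function(i) names[i])
}
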