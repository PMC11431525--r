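#' QQ plot of pooled null mVI draws against a chi-squared reference
#'
#' @param object A `"vi_nulldist"` tibble from [null_mvi_distribution()], or
#'   any numeric vector of non-negative draws.
#' @param df Reference degrees of freedom (1 for singleton groups).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_null_mvi <- function(object, df = 1, ...) {
  draws <- if (is.data.frame(object)) object$mvi else as.numeric(object)
  n <- length(draws)
  probs <- (seq_len(n) - 0.5) / n
  dat <- tibble::tibble(
    theoretical = qchisq(probs, df = df),
    empirical = sort(draws)
  )
  lab <- if (is.data.frame(object) && !is.null(attr(object, "criterion")))
    sprintf("Null mVI draws, %s", attr(object, "criterion")) else "Null mVI draws"
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$theoretical, y = .data$empirical)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(size = 0.7, alpha = 0.6) +
    ggplot2::labs(x = sprintf("Chi-squared(%d) quantiles", df),
                  y = "Empirical mVI quantiles", title = lab) +
    ggplot2::theme_minimal()
}

#' @rdname plot_null_mvi
#' @export
autoplot.vi_nulldist <- function(object, df = 1, ...) {
  plot_null_mvi(object, df = df, ...)
}

#' Type-I error rates against nominal levels
#'
#' Points are empirical rejection rates for true-null effects with +-3
#' Monte-Carlo standard error bars; the dashed line marks exact calibration.
#'
#' @param object A `"vi_type1"` tibble from [type1_error_rates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vi_type1 <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$level, y = .data$rate,
                               colour = .data$criterion)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(0, .data$rate - 3 * .data$mc_se),
                                          ymax = .data$rate + 3 * .data$mc_se),
                             position = ggplot2::position_dodge(width = 0.004)) +
    ggplot2::labs(x = "Nominal level", y = "Empirical type-I error",
                  colour = "Criterion",
                  title = sprintf("Type-I error (%s method)",
                                  attr(object, "method") %||% "")) +
    ggplot2::theme_minimal()
}

#' Importance table as a bar chart
#'
#' mVI per group and criterion, with the full-model squared Wald statistic
#' shown as its own facet for comparison.
#'
#' @param object A `"vi_table"` from [importance_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vi_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("group", "wald",
                                grep("^mvi_", names(object), value = TRUE))],
    -"group", names_to = "method", values_to = "value")
  long$method <- sub("^mvi_", "", long$method)
  long$method <- sub("^wald$", "Full (Wald^2)", long$method)
  ord <- object$group[order(object$wald)]
  long$group <- factor(long$group, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$group)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~method, nrow = 1) +
    ggplot2::labs(x = "Importance", y = NULL) +
    ggplot2::theme_minimal()
}
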