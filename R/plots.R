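#' Funnel plot of effect sizes against precision
#'
#' Correlation-scale effects against 1/SE (Zr scale); in the absence of
#' publication bias the cloud is symmetric around the mean, narrowing as
#' precision grows. The dashed line marks the model's mean effect when a
#' fit is supplied.
#'
#' @param data An `mc_data` object.
#' @param fit Optional intercept-only `mc_fit` whose mean is drawn.
#' @return A ggplot object.
#' @export
plot_funnel <- function(data, fit = NULL) {
  fd <- funnel_data(data)
  p <- ggplot2::ggplot(fd, ggplot2::aes(x = .data$r, y = .data$precision)) +
    ggplot2::geom_point(alpha = 0.6, shape = 21) +
    ggplot2::labs(x = "Correlation coefficient r",
                  y = "Precision (1 / SE)") +
    ggplot2::theme_minimal()
  if (!is.null(fit) && !is.null(fit$mean_r)) {
    p <- p + ggplot2::geom_vline(xintercept = fit$mean_r, linetype = "dashed")
  }
  p
}

#' Orchard-style plot of per-category means
#'
#' Each moderator level's mean correlation and confidence interval over
#' the raw effects, point size scaled by precision.
#'
#' @param x An `mc_moderator` from [moderator_analysis()].
#' @return A ggplot object.
#' @export
plot_orchard <- function(x) {
  stopifnot(inherits(x, "mc_moderator"))
  eff <- x$fit_means$model$effects
  raw <- tibble::tibble(level = as.character(eff$.moderator), r = eff$r,
                        precision = 1 / sqrt(eff$v))
  ggplot2::ggplot(x$levels, ggplot2::aes(x = .data$level, y = .data$mean_r)) +
    ggplot2::geom_jitter(data = raw,
                         ggplot2::aes(y = .data$r, size = .data$precision),
                         width = 0.15, alpha = 0.3, shape = 21,
                         inherit.aes = TRUE) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower_r,
                                          ymax = .data$ci_upper_r),
                             linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Mean correlation r", size = "1/SE") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a multilevel meta-analytic fit
#'
#' Forest-style display: each coefficient's estimate and confidence
#' interval on the Fisher-Z scale.
#'
#' @param object An `mc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mc_fit <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Estimate (Zr scale)") +
    ggplot2::theme_minimal()
}
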