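#' Regression plot with 95% band
#'
#' Observed ln CMC against the integrated-radius score, the fitted line and
#' the mean-response confidence band back of the fit — the standard display
#' of a one-predictor criteria model.
#'
#' @param object A `ppcr_fit` (needs its training data).
#' @param level Band coverage (default 0.95).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppcr_fit
#' @export
autoplot.ppcr_fit <- function(object, level = 0.95, ...) {
  if (is.null(object$data)) abort("fit was reloaded without training data; refit to plot")
  obs <- augment(object)
  grid_s <- seq(min(obs$score), max(obs$score), length.out = 100)
  se <- object$rse * sqrt(1 / object$n + (grid_s - object$score_mean)^2 / object$score_ssx)
  tcrit <- qt(1 - (1 - level) / 2, df = object$n - 2L)
  band <- tibble::tibble(score = grid_s,
                         fit = object$intercept + object$slope * grid_s,
                         lwr = .data$fit - tcrit * se,
                         upr = .data$fit + tcrit * se)
  ggplot2::ggplot(band, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr),
                         fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "steelblue") +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$ln_cmc)) +
    ggplot2::geom_text(data = obs,
                       ggplot2::aes(y = .data$ln_cmc, label = .data$metal_id),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "integrated-radius score X1", y = "ln CMC (ln µg/L)",
                  title = ppcr_equation(object),
                  subtitle = sprintf("%.0f%% confidence band", 100 * level)) +
    ggplot2::theme_minimal()
}

#' Williams plot
#'
#' Standardized residuals against leverage, with the warning leverage h*
#' and the |3| residual guides; the visual check that the training metals
#' (and any query metals) sit inside the applicability domain.
#'
#' @param object A [hat_values()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metcrit_domain
#' @export
autoplot.metcrit_domain <- function(object, ...) {
  hstar <- attr(object, "h_star")
  dat <- williams_export(object)
  dat$std_resid[is.na(dat$std_resid)] <- 0
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$hat, y = .data$std_resid)) +
    ggplot2::geom_vline(xintercept = hstar, linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_hline(yintercept = c(-3, 3), linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_domain)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$metal_id), vjust = -0.8, size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "firebrick")) +
    ggplot2::labs(x = "leverage h", y = "standardized residual",
                  title = sprintf("Williams plot (h* = %.3f)", hstar)) +
    ggplot2::theme_minimal()
}
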