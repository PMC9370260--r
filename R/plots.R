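#' Scatter plot of instrument effects with fitted causal slopes
#'
#' Plots outcome against exposure effects (oriented so exposure effects are
#' positive) with 1-SE error bars and one fitted line per estimator: through
#' the origin for slope-only methods, with a free intercept for Egger.
#'
#' @param harmonized Harmonized-instruments data frame.
#' @param estimates An estimate tibble (e.g. from [mr_all_methods()]).
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(harmonized, estimates) {
  h <- orient_positive(kept_instruments(harmonized))
  est <- as_tibble(estimates)
  est$intercept_line <- if ("intercept" %in% names(est)) {
    ifelse(est$method == "egger", est$intercept, 0)
  } else 0
  ggplot2::ggplot(h, ggplot2::aes(x = .data$beta_exp, y = .data$beta_out)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$beta_out - .data$se_out,
                   ymax = .data$beta_out + .data$se_out),
      width = 0, colour = "grey60"
    ) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$beta_exp - .data$se_exp,
                   xmax = .data$beta_exp + .data$se_exp),
      height = 0, colour = "grey60"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(
      data = est,
      ggplot2::aes(slope = .data$beta, intercept = .data$intercept_line,
                   colour = .data$method)
    ) +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome",
                  colour = "Method") +
    ggplot2::theme_minimal()
}

#' Forest plot of estimator results
#'
#' @param estimates An estimate tibble (optionally with a `cohort` column,
#'   which becomes a facet).
#' @param ... Unused.
#' @return A ggplot object with ORs and 95% CIs on a log scale.
#' @export
plot_mr_forest <- function(estimates, ...) {
  est <- as_tibble(estimates)
  est$label <- if ("cohort" %in% names(est)) {
    paste(est$cohort, est$method, sep = ": ")
  } else {
    est$method
  }
  ggplot2::ggplot(est, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_mr_forest
#' @param object An `mr_estimate` tibble.
#' @export
autoplot.mr_estimate <- function(object, ...) {
  plot_mr_forest(object, ...)
}

#' Forest plot of a full pipeline run
#'
#' Per-cohort primary estimates plus the combined meta-analysis row.
#'
#' @param object An `mr_pipeline` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_pipeline <- function(object, ...) {
  rows <- dplyr::bind_rows(
    object$primary %>%
      mutate(label = paste0(.data$cohort, " (", .data$method, ")")) %>%
      select("label", "or", "ci_low", "ci_high"),
    as_tibble(object$meta) %>%
      mutate(label = paste0("Combined (", .data$model, ")")) %>%
      select("label", "or", "ci_low", "ci_high")
  )
  rows$label <- factor(rows$label, levels = rev(rows$label))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Odds ratio (95% CI)", y = NULL,
      title = sprintf("%s → %s", object$exposure_name,
                      object$outcome_name)
    ) +
    ggplot2::theme_minimal()
}
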