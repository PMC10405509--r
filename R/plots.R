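#' Plot a REML fit
#'
#' Point-range plot of the (co)variance estimates with +-1 SE, plus the
#' convergence trace of `-2 logL`.
#'
#' @param object A [reml()] fit.
#' @param what `"estimates"` (default) or `"trace"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reml_fit <- function(object, what = c("estimates", "trace"), ...) {
  what <- match.arg(what)
  if (what == "trace") {
    return(
      ggplot2::ggplot(
        object$trace,
        ggplot2::aes(x = .data$iter, y = .data$minus2logL)
      ) +
        ggplot2::geom_line() +
        ggplot2::geom_point(size = 1) +
        ggplot2::labs(
          x = "iteration", y = "-2 log L",
          title = paste("REML convergence,", object$config$model)
        ) +
        ggplot2::theme_minimal()
    )
  }
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - .data$std.error,
      ymax = .data$estimate + .data$std.error
    )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "estimate (g²)",
      title = paste("Variance components,", object$config$model)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation report
#'
#' Accuracies (or inflation slopes) per model and test.
#'
#' @param object A [crossvalidate()] report.
#' @param what `"accuracy"` (default) or `"inflation"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crossval_report <- function(object, what = c("accuracy", "inflation"), ...) {
  what <- match.arg(what)
  st <- object$stats
  st <- if (what == "accuracy") {
    st[grepl("^cor|^Halfsibs", st$statistic), ]
  } else {
    st[grepl("^slope", st$statistic), ]
  }
  st$model <- factor(st$model, levels = unique(st$model))
  p <- ggplot2::ggplot(st, ggplot2::aes(
    x = .data$model, y = .data$value, group = .data$statistic
  )) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(
      x = NULL,
      y = if (what == "accuracy") "correlation" else "regression slope"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  if (what == "inflation") {
    p <- p + ggplot2::geom_hline(yintercept = 1, linetype = 3)
  }
  p
}

#' Genetic trend of a simulated population
#'
#' Mean true breeding value per selection round.
#'
#' @param pop A [run_program()] population.
#' @return A ggplot object.
#' @export
plot_genetic_trend <- function(pop) {
  tr <- pop$truth[pop$truth$born > 0, ]
  d <- dplyr::summarise(dplyr::group_by(tr, sr = .data$born),
    mean_tbv = mean(.data$a), .groups = "drop"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sr, y = .data$mean_tbv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "selection round", y = "mean true breeding value (g)",
      title = "Genetic trend"
    ) +
    ggplot2::theme_minimal()
}
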