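#' Plot per-sample score-versus-cutoff curves
#'
#' One grey line per sample with the cohort-mean curve overlaid in red —
#' the standard display for choosing a CNA-calling cutoff by eye before the
#' elbow method formalises it.
#'
#' @param object A [score_sweep()] result.
#' @param score `"as"` or `"fga"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot cna_score_curve
#' @export
autoplot.cna_score_curve <- function(object, score = c("as", "fga"), ...) {
  score <- match.arg(score)
  col <- if (score == "as") "as_score" else "fga"
  mean_curve <- suppressMessages(cohort_mean_curve(object, score = score))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$cutoff, y = .data[[col]])) +
    ggplot2::geom_line(ggplot2::aes(group = .data$sample_id),
                       colour = "grey60", alpha = 0.4, linewidth = 0.3) +
    ggplot2::geom_line(data = mean_curve,
                       ggplot2::aes(y = .data$value, group = 1),
                       colour = "red", linewidth = 1) +
    ggplot2::labs(x = "CNA calling cutoff |log2 ratio|",
                  y = toupper(score)) +
    ggplot2::theme_minimal()
}

#' Plot a cohort-mean curve with its bootstrap elbow
#'
#' @param object A [bootstrap_elbow()] result.
#' @param curve Optional mean curve (`cutoff`, `value`) to draw behind the
#'   elbow annotation.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot cna_elbow
#' @export
autoplot.cna_elbow <- function(object, curve = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(curve)) {
    p <- p + ggplot2::geom_line(
      data = curve, ggplot2::aes(x = .data$cutoff, y = .data$value),
      colour = "grey30")
  }
  p +
    ggplot2::geom_vline(xintercept = object$elbow_point, colour = "red") +
    ggplot2::annotate("rect", xmin = object$ci_low, xmax = object$ci_high,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red") +
    ggplot2::labs(x = "CNA calling cutoff |log2 ratio|", y = "mean score",
                  title = sprintf("Elbow %.2f [%.2f, %.2f]",
                                  object$elbow_point, object$ci_low,
                                  object$ci_high)) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier step curves per group
#'
#' @param object A [km_compare()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot cna_km
#' @export
autoplot.cna_km <- function(object, ...) {
  # prepend time-0 anchors so every curve starts at survival 1
  anchors <- object$curves |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, surv = 1)
  ggplot2::ggplot(dplyr::bind_rows(anchors, object$curves),
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Overall survival (months)",
                  y = "Survival probability", colour = object$group_col) +
    ggplot2::theme_minimal()
}

#' Plot a binarization-percentile search
#'
#' Hazard ratio (with Wald confidence band) of the score-high indicator at
#' each candidate percentile; the chosen percentile, if any, is marked.
#'
#' @param object A [search_binarization()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot cna_search
#' @export
autoplot.cna_search <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$percentile, y = .data$hr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "Binarization percentile",
                  y = "Multivariable HR (score high)") +
    ggplot2::theme_minimal()
  chosen <- attr(object, "chosen")
  if (!is.na(chosen)) {
    p <- p + ggplot2::geom_vline(xintercept = chosen, colour = "red",
                                 linetype = 3)
  }
  p
}
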