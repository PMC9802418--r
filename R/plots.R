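# ggplot2 visualisations of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an empirical ROC curve
#'
#' @param object A `cdace_roc` object from [roc_cutoff()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cdace_roc <- function(object, ...) {
  d <- object$curve |>
    dplyr::mutate(fpr = 1 - .data$specificity) |>
    dplyr::arrange(.data$fpr, .data$sensitivity)
  sel <- d[d$threshold == object$cutoff, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(data = sel, colour = "red", size = 2) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC curve (AUC = %.3f, cutoff = %.3g)",
                      object$auc, object$cutoff)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot the score distribution of a scored cohort
#'
#' Histogram of the CDACE composite with the per-component distributions of
#' Li, R and S as facets.
#'
#' @param object A `cdace_scores` tibble from [score_cdace()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cdace_scores <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::select("study_id", "li", "r", "s", "cdace") |>
    tidyr::pivot_longer(-"study_id", names_to = "component",
                        values_to = "value") |>
    dplyr::mutate(component = factor(
      .data$component, levels = c("cdace", "li", "r", "s"),
      labels = c("CDACE composite", "Li (0-16)", "R (0-4)", "S (0-3)")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~component, scales = "free") +
    ggplot2::labs(x = NULL, y = "Studies") +
    ggplot2::theme_minimal()
}

#' Heatmap of per-quartile inflammation grades
#'
#' One tile per study and quartile, coloured by the 0--4 inflammation grade;
#' a compact view of where along the small bowel each study is inflamed.
#'
#' @param scores A `cdace_scores` tibble (or any tibble with `study_id` and
#'   `q1`..`q4`).
#' @return A ggplot.
#' @export
plot_quartile_grades <- function(scores) {
  d <- tibble::as_tibble(scores) |>
    dplyr::select("study_id", dplyr::all_of(paste0("q", 1:4))) |>
    tidyr::pivot_longer(-"study_id", names_to = "quartile",
                        values_to = "grade")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$quartile, y = .data$study_id,
                                  fill = factor(.data$grade, levels = 0:4))) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_brewer(palette = "YlOrRd", name = "Grade",
                               drop = FALSE) +
    ggplot2::labs(x = "Small-bowel quartile", y = NULL) +
    ggplot2::theme_minimal()
}
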