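#' Plot the benchmark rate summary
#'
#' Stacked proportions of true-positive, false-negative and not-run
#' scenarios per method (the proportions sum to 1), with the mean
#' false-positive count annotated.
#'
#' @param object A `pa_evaluation`, or a named list of them.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pa_evaluation <- function(object, ...) {
  summaries <- if (inherits(object, "pa_evaluation")) {
    glance(object)
  } else {
    purrr::map_dfr(object, glance)
  }
  long <- summaries %>%
    select("method", TP = "tpr", FN = "fnr", `not run` = "not_run_rate") %>%
    tidyr::pivot_longer(-"method", names_to = "outcome", values_to = "proportion") %>%
    mutate(outcome = factor(.data$outcome, levels = c("not run", "FN", "TP")))
  ggplot(long, aes(x = .data$method, y = .data$proportion, fill = .data$outcome)) +
    geom_col() +
    scale_fill_manual(values = c(TP = "#2c7fb8", FN = "#d7301f", `not run` = "#fa9fb5")) +
    labs(
      x = NULL, y = "proportion of knockout scenarios", fill = NULL,
      title = "Recovery of the knocked-out pathway by enrichment method"
    ) +
    theme_minimal()
}

#' Plot a knockout z-score profile
#'
#' Lollipop plot of the exometabolomic z-scores of one scenario, optionally
#' highlighting the knocked-out pathway's own metabolites.
#'
#' @param profiles Tibble of profiles (`scenario`, `metabolite`, `z`).
#' @param scenario Scenario (pathway id) to plot.
#' @param highlight Optional character vector of metabolites to colour.
#' @return A ggplot object.
#' @export
plot_zscore_profile <- function(profiles, scenario, highlight = NULL) {
  pr <- filter(profiles, .data$scenario == !!scenario) %>%
    mutate(
      metabolite = stats::reorder(.data$metabolite, .data$z),
      own = .data$metabolite %in% (highlight %||% character())
    )
  if (!nrow(pr)) abort(paste0("no profile for scenario: ", scenario))
  ggplot(pr, aes(x = .data$metabolite, y = .data$z, colour = .data$own)) +
    geom_segment(aes(xend = .data$metabolite, yend = 0), show.legend = !is.null(highlight)) +
    geom_point(show.legend = !is.null(highlight)) +
    scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "#d7301f")) +
    coord_flip() +
    labs(
      x = NULL, y = "z-score (positive = more in the medium)",
      colour = "in KO'd pathway", title = paste0("Knockout profile: ", scenario)
    ) +
    theme_minimal()
}

#' Plot a pathway-property PCA
#'
#' Scatter of the first two principal components, optionally coloured by
#' TP/FN labels for one method.
#'
#' @param object A `pathway_pca`.
#' @param labels Optional tibble with `pathway_id` and `label`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pathway_pca <- function(object, labels = NULL, ...) {
  dat <- object$scores
  if (!is.null(labels)) {
    dat <- left_join(dat, distinct(labels, .data$pathway_id, .data$label),
      by = "pathway_id"
    )
  } else {
    dat$label <- "pathway"
  }
  pct <- round(100 * object$explained_proportion[1:2], 1)
  ggplot(dat, aes(x = .data$PC1, y = .data$PC2, colour = .data$label)) +
    geom_point(size = 2) +
    labs(
      x = paste0("PC1 (", pct[1], "%)"), y = paste0("PC2 (", pct[2], "%)"),
      colour = NULL, title = "Pathways in intrinsic-property space"
    ) +
    theme_minimal()
}
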