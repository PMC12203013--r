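#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a detection-probability curve
#'
#' Detection probability against pellet effort, with dashed guides at each
#' confidence level and its minimum effort n*.
#'
#' @param object A [detection_curve()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot detection_curve
#' @export
autoplot.detection_curve <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$prob)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = object$n_star$confidence,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = "Pellets examined (n)",
      y = "P(at least one detection)",
      title = paste0(object$taxon, " at ", object$site_id),
      subtitle = sprintf("per-pellet presence p = %.3f", object$p_hat)
    ) +
    ggplot2::theme_minimal()
  ns <- object$n_star[!is.na(object$n_star$n_star), , drop = FALSE]
  if (nrow(ns) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = ns$n_star,
                                 linetype = "dotted", colour = "grey40")
  }
  p
}

#' Plot a rarefaction/extrapolation curve
#'
#' Interpolated range solid, extrapolated range dashed, with the Chao
#' asymptote as a horizontal guide.
#'
#' @param object A [rarefaction_curve()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rarefaction_curve
#' @export
autoplot.rarefaction_curve <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$estimate,
                                   linetype = .data$is_extrapolated)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#31a354") +
    ggplot2::geom_hline(yintercept = object$asymptote, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                              `TRUE` = "dashed"),
                                   guide = "none") +
    ggplot2::labs(
      x = if (object$mode == "incidence") "Pellets" else "Individuals",
      y = "Expected species richness",
      title = paste0("Rarefaction (", object$mode, "), ", object$site_id)
    ) +
    ggplot2::theme_minimal()
}

#' Stacked IRI composition bars per site
#'
#' @param iri An IRI tibble from [iri_table()] (one or many sites
#'   row-bound).
#' @param top_n Label only the `top_n` taxa per site; the rest are pooled
#'   as "other" for display.
#' @return A ggplot.
#' @export
plot_iri <- function(iri, top_n = 5) {
  df <- iri %>%
    dplyr::mutate(
      shown = ifelse(.data$rank <= top_n, .data$taxon, "other"),
      .by = "site_id"
    ) %>%
    dplyr::summarise(iri_pct = sum(.data$iri_pct),
                     .by = c("site_id", "shown"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site_id, y = .data$iri_pct,
                                   fill = .data$shown)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "IRI share (%)", fill = "Taxon") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Stacked habitat-composition bars per site
#'
#' @param props Output of [habitat_proportions()].
#' @return A ggplot.
#' @export
plot_habitat <- function(props) {
  ggplot2::ggplot(props, ggplot2::aes(x = .data$site_id,
                                      y = .data$proportion,
                                      fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "Proportion of hunting range",
                  fill = "Habitat") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
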