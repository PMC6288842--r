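#' Plot a genetic map as linkage-group bars with marker ticks
#'
#' One vertical bar per linkage group with a horizontal tick at every marker
#' position, the usual linkage-map figure.
#'
#' @param object A `genetic_map`.
#' @param sex Which positions to draw: `"averaged"` (default), `"female"` or
#'   `"male"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot genetic_map
#' @export
autoplot.genetic_map <- function(object, sex = c("averaged", "female", "male"),
                                 ...) {
  sex <- match.arg(sex)
  col <- switch(sex, averaged = "avg_cM", female = "female_cM", male = "male_cM")
  df <- as_tibble(object)
  lens <- df %>% group_by(.data$group) %>%
    summarise(len = max(.data[[col]]), .groups = "drop")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = lens,
      ggplot2::aes(x = .data$group, xend = .data$group, y = 0, yend = .data$len),
      linewidth = 2.5, colour = "grey80", lineend = "round") +
    ggplot2::geom_point(
      data = df,
      ggplot2::aes(x = .data$group, y = .data[[col]]),
      shape = 95, size = 4) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "position (cM)",
                  title = sprintf("%s linkage map", sex)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Compare female and male map lengths per linkage group
#'
#' @param map A `genetic_map` or `map_summary`.
#' @return A ggplot object (paired bars of female and male group lengths).
#' @export
plot_sex_lengths <- function(map) {
  s <- if (inherits(map, "map_summary")) map else map_summary(map)
  df <- s$by_group %>%
    select("linkage_group", "female_length_cM", "male_length_cM") %>%
    tidyr::pivot_longer(-"linkage_group", names_to = "map",
                        values_to = "length_cM") %>%
    mutate(map = sub("_length_cM", "", .data$map))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$linkage_group,
                                   y = .data$length_cM, fill = .data$map)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "map length (cM)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot per-arm expected/observed mapping ratios by rediploidization class
#'
#' @param object An `arm_ratio_test`.
#' @param ... Unused.
#' @return A ggplot object (boxplot + points of ratios for AORe vs LORe).
#' @method autoplot arm_ratio_test
#' @export
autoplot.arm_ratio_test <- function(object, ...) {
  df <- object$arms %>% filter(!is.na(.data$ratio))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$ratio)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.7) +
    ggplot2::labs(x = "rediploidization class",
                  y = "expected / observed mappings") +
    ggplot2::theme_minimal()
}
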