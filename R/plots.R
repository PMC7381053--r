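#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_hline
#'   labs coord_flip facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot a circadian slot histogram
#'
#' @param x a posts tibble or POSIXct vector.
#' @return a ggplot.
#' @export
plot_slot_histogram <- function(x) {
  h <- slot_histogram(x)
  h$label <- sprintf("%02d-%02d", h$slot * 3, h$slot * 3 + 3)
  ggplot(h, aes(x = .data$label, y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = "UTC 3-hour slot", y = "posts",
         title = "Posting activity by time of day") +
    theme_minimal()
}

#' @rdname mannwhitney_screen
#' @param object an `spv_screen`.
#' @param top_n features shown.
#' @param ... unused.
#' @export
autoplot.spv_screen <- function(object, top_n = 25, ...) {
  d <- object %>%
    arrange(.data$p_value) %>%
    dplyr::slice_head(n = top_n) %>%
    mutate(feature = factor(.data$feature, levels = rev(.data$feature)))
  ggplot(d, aes(x = .data$feature, y = -log10(pmax(.data$p_value, 1e-300)),
                colour = .data$selected)) +
    geom_point() +
    geom_hline(yintercept = -log10(attr(object, "alpha")), linetype = 2) +
    coord_flip() +
    labs(y = "-log10 P (Mann-Whitney)", x = NULL,
         title = "Feature screening") +
    theme_minimal()
}

#' @rdname fit_select_evaluate
#' @param object an `spv_eval`.
#' @export
autoplot.spv_eval <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$metric, y = .data$value)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = NULL,
         title = paste("Held-out metrics:", object$classifier)) +
    theme_minimal()
}

#' Plot a feature ranking
#'
#' @param ranking a [rank_features()] tibble.
#' @param top_n features shown.
#' @return a ggplot.
#' @export
plot_feature_ranking <- function(ranking, top_n = 10) {
  d <- ranking %>%
    dplyr::slice_head(n = top_n) %>%
    mutate(feature = factor(.data$feature, levels = rev(.data$feature)))
  ggplot(d, aes(x = .data$feature, y = .data$score)) +
    geom_col(fill = "darkorange") +
    coord_flip() +
    labs(x = NULL, y = "importance", title = "Most predictive features") +
    theme_minimal()
}
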