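# ggplot2 visualisations of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_histogram
#'   geom_vline geom_col labs theme_minimal scale_x_log10 coord_equal
#'   facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Ordination scatter plot
#'
#' @param object A `paleo_nmds` object.
#' @param groups Optional group labels (e.g. interval) aligned with the
#'   ordinated samples, used for colour.
#' @param size Optional numeric (e.g. sample size) mapped to point size.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.paleo_nmds <- function(object, groups = NULL, size = NULL, ...) {
  df <- object$points
  if (!is.null(groups)) df$group <- groups
  if (!is.null(size)) df$size <- size
  p <- ggplot(df, aes(x = .data$NMDS1, y = .data$NMDS2)) +
    theme_minimal() +
    labs(subtitle = sprintf("stress-1 = %.3f", object$stress))
  if (!is.null(groups) && !is.null(size)) {
    p + geom_point(aes(colour = .data$group, size = .data$size), alpha = 0.7)
  } else if (!is.null(groups)) {
    p + geom_point(aes(colour = .data$group), alpha = 0.7)
  } else {
    p + geom_point(alpha = 0.7)
  }
}

#' Null-distribution histogram for a permutation test
#'
#' Histogram of the randomized mean between-interval dissimilarities with
#' the observed value marked by a vertical line.
#'
#' @param object A `paleo_nulltest`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.paleo_nulltest <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$mean_bc)) +
    geom_histogram(bins = 40, fill = "darkseagreen", colour = "grey30") +
    geom_vline(xintercept = object$observed, colour = "red", linewidth = 1) +
    theme_minimal() +
    labs(x = "mean between-interval Bray-Curtis",
         y = "iterations",
         title = paste(object$intervals, collapse = " vs "),
         subtitle = sprintf("observed = %.3f, p = %.4g", object$observed,
                            object$p_value))
}

#' Pooled-abundance envelope scatter
#'
#' Simulated per-species abundance pairs (null cloud) under the pooled
#' homogeneous system, with observed pairs overplotted; both axes on a
#' log10(x + 1) scale so species absent from one interval remain visible.
#'
#' @param object A `paleo_envelope`.
#' @param max_cloud Subsample of simulated points to draw (default 20000).
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.paleo_envelope <- function(object, max_cloud = 20000, ...) {
  cloud <- tidy(object)
  if (nrow(cloud) > max_cloud) {
    cloud <- cloud[seq(1, nrow(cloud), length.out = max_cloud), ]
  }
  ggplot(cloud, aes(x = log10(.data$x + 1), y = log10(.data$y + 1))) +
    geom_point(colour = "grey70", alpha = 0.2, size = 0.5) +
    geom_point(data = object$observed,
               aes(x = log10(.data$count_a + 1), y = log10(.data$count_b + 1)),
               colour = "black", size = 1.5) +
    coord_equal() +
    theme_minimal() +
    labs(x = paste0("log10 total abundance + 1, ", object$intervals[1]),
         y = paste0("log10 total abundance + 1, ", object$intervals[2]),
         subtitle = sprintf("rho = %.2f, p = %.3g", object$rho_observed,
                            object$p_rho))
}

#' Stacked biogeographic-affinity bars per interval
#'
#' @param profiles A tibble from [biogeo_profile()] (rows for several
#'   intervals may be bound together).
#' @return A ggplot.
#' @export
plot_biogeo_profiles <- function(profiles) {
  profiles$interval <- factor(profiles$interval,
                              levels = intersect(INTERVAL_LEVELS,
                                                 unique(profiles$interval)))
  ggplot(profiles, aes(x = .data$interval, y = .data$proportion,
                       fill = .data$biogeo_class)) +
    geom_col() +
    theme_minimal() +
    labs(x = NULL, y = "relative abundance of specimens",
         fill = "biogeographic\naffinity")
}
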