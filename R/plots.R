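# ggplot2 views of the result types. All plots are built from the tabular
# results; nothing is computed here that the tables do not already contain.

#' @method autoplot rcf_tbl
#' @export
autoplot.rcf_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$amplitude,
                                       y = .data$frequency,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "amplitude (log2)",
                  y = "fraction with amplitude > x",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Rose plot of a phase histogram
#'
#' @param object A `phase_hist_tbl` from [phase_histogram()].
#' @param ... Unused.
#' @return A ggplot: circular (ZT) bar chart of phase counts.
#' @method autoplot phase_hist_tbl
#' @export
autoplot.phase_hist_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_start + 0.5,
                                       y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "steelblue", colour = "grey30") +
    ggplot2::coord_polar(start = 0) +
    ggplot2::scale_x_continuous(limits = c(0, 24),
                                breaks = seq(0, 21, by = 3),
                                labels = sprintf("ZT%02d", seq(0, 21, 3))) +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal()
}

#' MVA (difference vs. average) plot of a moderated comparison
#'
#' @param object A `moderated_test` tibble.
#' @param ... Unused.
#' @return A ggplot: per-locus M (group difference) against A (group
#'   average), significant loci emphasised.
#' @method autoplot moderated_test
#' @export
autoplot.moderated_test <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$A, y = .data$M)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$significant,
                                     colour = .data$significant),
                        alpha = 0.6) +
    ggplot2::scale_size_manual(values = c(`FALSE` = 1, `TRUE` = 2),
                               guide = "none") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "black")) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(x = "A (mean of group means)",
                  y = "M (difference of group means)",
                  colour = sprintf("p < %.2g", attr(object, "alpha") %||% 0.05)) +
    ggplot2::theme_minimal()
}

#' Silhouette-vs-k curve of a cluster model
#'
#' @param object A `diurnal_pam` from [select_k()].
#' @param ... Unused.
#' @return A ggplot of mean silhouette width against k, the selected k
#'   marked.
#' @method autoplot diurnal_pam
#' @export
autoplot.diurnal_pam <- function(object, ...) {
  if (is.null(object$silhouette_by_k)) {
    abort("No silhouette-by-k table; run select_k() to scan k.")
  }
  ggplot2::ggplot(object$silhouette_by_k,
                  ggplot2::aes(x = .data$k, y = .data$mean_silhouette)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2,
                        colour = "red") +
    ggplot2::scale_x_continuous(breaks = object$silhouette_by_k$k) +
    ggplot2::labs(x = "number of clusters k",
                  y = "mean silhouette width") +
    ggplot2::theme_minimal()
}

#' Heatmap of row-normalised temporal profiles ordered by cluster
#'
#' @param profiles Output of [normalize_rows()] (feature_id + timepoint
#'   columns in \[0, 1\]).
#' @param order_by Optional tibble (`feature_id`, `cluster`) from
#'   [tidy()] of a cluster model; rows are grouped by cluster.
#' @return A ggplot tile heatmap (white = row minimum, red = row maximum).
#' @export
plot_profile_heatmap <- function(profiles, order_by = NULL) {
  long <- tidyr::pivot_longer(
    dplyr::select(profiles, -dplyr::any_of("constant")),
    -"feature_id", names_to = "timepoint", values_to = "value")
  long$timepoint <- factor(long$timepoint,
                           levels = unique(long$timepoint))
  if (!is.null(order_by)) {
    ord <- order_by[order(order_by$cluster), ]
    long$feature_id <- factor(long$feature_id, levels = rev(ord$feature_id))
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint,
                                     y = .data$feature_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "relative\nexpression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
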