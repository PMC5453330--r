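# broom-style tidiers for the package's fitted objects.

#' Tidy a PAM cluster model
#'
#' @param x A `diurnal_pam` object.
#' @param ... Unused.
#' @return A tibble with one row per clustered feature: `feature_id`,
#'   `cluster`, `silhouette`, `is_medoid`.
#' @method tidy diurnal_pam
#' @export
tidy.diurnal_pam <- function(x, ...) {
  tibble::tibble(
    feature_id = x$ids,
    cluster = x$assignment,
    silhouette = x$silhouette,
    is_medoid = seq_along(x$ids) %in% x$medoids)
}

#' One-row summary of a PAM cluster model
#'
#' @param x A `diurnal_pam` object.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `n`, `mean_silhouette`, `objective`,
#'   `iterations`.
#' @method glance diurnal_pam
#' @export
glance.diurnal_pam <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$assignment),
                 mean_silhouette = x$mean_silhouette,
                 objective = x$objective, iterations = x$iterations)
}

#' One-row summary of a moderated two-group comparison
#'
#' @param x A `moderated_test` tibble.
#' @param ... Unused.
#' @return A one-row tibble: group sizes, fitted prior df `d0` and prior
#'   variance `s02`, the number of significant loci and the significance
#'   threshold.
#' @method glance moderated_test
#' @export
glance.moderated_test <- function(x, ...) {
  tibble::tibble(
    n_loci = nrow(x),
    n_a = attr(x, "n_a"), n_b = attr(x, "n_b"),
    d0 = attr(x, "d0"), s02 = attr(x, "s02"),
    alpha = attr(x, "alpha"),
    n_significant = sum(x$significant),
    n_up = sum(x$significant & x$M > 0),
    n_down = sum(x$significant & x$M < 0))
}
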