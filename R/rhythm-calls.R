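#' Call rhythmic features from a cosinor result
#'
#' A feature is called rhythmic when its F-test p-value is strictly below
#' `p_threshold` (default 1e-4, the conventional stringent cutoff for
#' genome-wide rhythm screens; a p-value exactly equal to the threshold is
#' not called).
#'
#' @param fit Cosinor result tibble from [cosinor_fit()] (or any data frame
#'   with `feature_id` and `p_value`).
#' @param p_threshold Strict p-value cutoff (default 1e-4).
#'
#' @return The input with a logical `rhythmic` column appended; the
#'   threshold is recorded in the `p_threshold` attribute.
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(50, seed = 1))
#' sim$data |> cosinor_fit() |> call_rhythmic()
call_rhythmic <- function(fit, p_threshold = 1e-4) {
  if (!is.data.frame(fit) || !"p_value" %in% names(fit)) {
    abort("`fit` must be a data frame with a `p_value` column.")
  }
  check_number(p_threshold, "p_threshold", min = 0, allow_zero = FALSE)
  out <- dplyr::mutate(
    fit, rhythmic = !is.na(.data$p_value) & .data$p_value < p_threshold)
  attr(out, "p_threshold") <- p_threshold
  out
}

#' Feature ids called rhythmic
#'
#' @param calls Output of [call_rhythmic()].
#' @return Character vector of rhythmic feature ids.
#' @export
rhythmic_ids <- function(calls) {
  if (!all(c("feature_id", "rhythmic") %in% names(calls))) {
    abort("`calls` must have feature_id and rhythmic columns.")
  }
  calls$feature_id[calls$rhythmic]
}

#' Estimate the false discovery rate of rhythm calls by permutation
#'
#' The sample-to-time assignment is destroyed by permuting the time labels
#' of the samples (columns), jointly for all features so that the gene-gene
#' correlation structure is preserved; each permutation refits every feature
#' and counts rhythm calls at `p_threshold`. The FDR estimate is the mean
#' permuted count divided by the observed count, clipped to \[0, 1\]. It is
#' undefined (NA, with a note) when no feature is called on the observed
#' data.
#'
#' @param data Long time-course tibble for a single condition.
#' @param p_threshold Strict p-value cutoff (default 1e-4).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param period Period in hours (default 24).
#'
#' @return A one-row tibble: `condition`, `n_observed`, `mean_permuted`,
#'   `fdr`, `p_threshold`, `n_perm`, `seed`, `note`.
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(40, seed = 3))
#' estimate_fdr(sim$data, n_perm = 20, seed = 1)
estimate_fdr <- function(data, p_threshold = 1e-4, n_perm = 1000, seed = 1L,
                         period = 24) {
  check_timecourse(data)
  check_count(n_perm, "n_perm", min = 1L)
  check_count(seed, "seed")
  if (length(unique(data$condition)) > 1L) {
    abort("`data` must contain a single condition; split and call per condition.")
  }
  mats <- tc_to_matrix(data)
  Y <- mats$values
  keep <- rowSums(!is.finite(Y)) == 0L
  Y <- Y[keep, , drop = FALSE]
  if (nrow(Y) == 0L) abort("No complete features to fit.")
  times <- mats$samples$zt

  observed <- sum(cosinor_fit_matrix(Y, times, period)$p_value < p_threshold)
  perm_counts <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      t_perm <- sample(times)
      sum(cosinor_fit_matrix(Y, t_perm, period)$p_value < p_threshold)
    }, numeric(1))
  })
  mean_perm <- mean(perm_counts)
  if (observed == 0L) {
    fdr <- NA_real_
    note <- "No rhythmic features observed; FDR undefined."
  } else {
    fdr <- min(max(mean_perm / observed, 0), 1)
    note <- NA_character_
  }
  tibble::tibble(
    condition = unique(mats$samples$condition), n_observed = observed,
    mean_permuted = mean_perm, fdr = fdr, p_threshold = p_threshold,
    n_perm = as.integer(n_perm), seed = as.integer(seed), note = note)
}
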