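# Set-level summaries of rhythmic features across conditions.

#' Convert a log2 amplitude to a peak-to-trough fold change (and back)
#'
#' A cosine of log2 amplitude A spans 2A log2 units peak to trough, i.e. a
#' fold change of `2^(2*A)`; the conventional 0.25 log2 amplitude cutoff
#' corresponds to a 1.4-fold change.
#'
#' @param amplitude Log2 amplitude(s) (half peak-to-trough).
#' @return Fold change(s).
#' @export
#' @examples
#' amplitude_to_foldchange(0.25) # ~1.41
amplitude_to_foldchange <- function(amplitude) {
  2^(2 * amplitude)
}

#' @rdname amplitude_to_foldchange
#' @param foldchange Peak-to-trough fold change(s).
#' @export
foldchange_to_amplitude <- function(foldchange) {
  log2(foldchange) / 2
}

#' Filter a cosinor result by amplitude
#'
#' Eliminates features whose fitted amplitude is lower than `min_amplitude`
#' (default 0.25 log2 units, i.e. < 1.4-fold peak to trough); a feature at
#' exactly the cutoff is retained.
#'
#' @param fit Cosinor result tibble (needs `amplitude`).
#' @param min_amplitude Log2 amplitude cutoff (default 0.25).
#' @return The filtered tibble.
#' @export
amplitude_filter <- function(fit, min_amplitude = 0.25) {
  if (!is.data.frame(fit) || !"amplitude" %in% names(fit)) {
    abort("`fit` must be a data frame with an `amplitude` column.")
  }
  check_number(min_amplitude, "min_amplitude", min = 0)
  dplyr::filter(fit, !is.na(.data$amplitude),
                .data$amplitude >= min_amplitude)
}

#' Partition 2-3 named feature sets into their disjoint intersection regions
#'
#' The Venn-diagram decomposition: every feature of the union is assigned to
#' exactly one membership pattern, so the region counts sum to the union
#' size.
#'
#' @param sets Named list of 2 or 3 character vectors of feature ids.
#' @return A tibble with one logical membership column per set, the region
#'   `n`, and a `members` list-column.
#' @export
#' @examples
#' partition_sets(list(A = c("g1", "g2", "g3"), B = c("g2", "g3"), C = "g3"))
partition_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L) {
    abort("`sets` must be a named list of 2 or 3 feature-id vectors.")
  }
  nms <- names(sets)
  if (is.null(nms) || any(!nzchar(nms))) abort("All sets must be named.")
  if (anyDuplicated(nms)) abort("Set (condition) names must be unique.")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, ncol = length(sets),
                       dimnames = list(NULL, nms))
  patterns <- do.call(tidyr::expand_grid,
                      setNames(rep(list(c(TRUE, FALSE)), length(sets)), nms))
  patterns <- patterns[rowSums(as.matrix(patterns)) > 0L, , drop = FALSE]
  pattern_key <- apply(as.matrix(patterns), 1L, paste, collapse = "|")
  member_key <- apply(membership, 1L, paste, collapse = "|")
  members <- lapply(pattern_key, function(k) universe[member_key == k])
  dplyr::mutate(patterns,
                n = lengths(members),
                members = members)
}

#' Reverse cumulative frequency of amplitudes
#'
#' For each grid value `a`, the fraction of input values strictly greater
#' than `a`. Curves from different gene groups can be overlaid to compare
#' their amplitude distributions.
#'
#' @param amplitudes Non-empty numeric vector.
#' @param grid Evaluation grid; default 200 points from 0 to the maximum.
#' @param group Optional label stored alongside the curve.
#' @return A tibble of class `rcf_tbl` with columns `amplitude`,
#'   `frequency`, `group`, `n`.
#' @export
#' @examples
#' rcf(c(0.1, 0.2, 0.3))
rcf <- function(amplitudes, grid = NULL, group = "all") {
  amplitudes <- amplitudes[is.finite(amplitudes)]
  if (length(amplitudes) == 0L) abort("`amplitudes` must be non-empty.")
  if (is.null(grid)) grid <- seq(0, max(amplitudes), length.out = 200L)
  freq <- vapply(grid, function(a) mean(amplitudes > a), numeric(1))
  out <- tibble::tibble(amplitude = grid, frequency = freq, group = group,
                        n = length(amplitudes))
  class(out) <- c("rcf_tbl", class(out))
  out
}

#' Histogram of peak phases in hourly ZT bins
#'
#' Bins are half-open intervals \[k, k + width) covering \[0, 24); phase
#' 24.0 must be normalised to 0 upstream. Counts sum to the number of
#' phases.
#'
#' @param phases Peak times in \[0, 24) (NA dropped with a count).
#' @param bin_width Bin width in hours; must divide 24 (default 1).
#' @return A tibble of class `phase_hist_tbl`: `bin_start`, `bin_end`,
#'   `count`; the number of NA phases is in attribute `n_undefined`.
#' @export
#' @examples
#' phase_histogram(c(22.5, 22.9, 0.2))
phase_histogram <- function(phases, bin_width = 1) {
  check_number(bin_width, "bin_width", min = 0, allow_zero = FALSE)
  if (24 %% bin_width != 0) abort("`bin_width` must divide 24.")
  n_na <- sum(is.na(phases))
  phases <- phases[!is.na(phases)]
  if (any(phases < 0 | phases >= 24)) {
    abort("Phases must lie in [0, 24); normalise (e.g. 24 -> 0) upstream.")
  }
  starts <- seq(0, 24 - bin_width, by = bin_width)
  idx <- floor(phases / bin_width) + 1L
  counts <- tabulate(idx, nbins = length(starts))
  out <- tibble::tibble(bin_start = starts, bin_end = starts + bin_width,
                        count = counts)
  attr(out, "n_undefined") <- n_na
  class(out) <- c("phase_hist_tbl", class(out))
  out
}

#' Per-feature phase and amplitude shifts between two conditions
#'
#' For features fitted in both a reference and an alternative condition,
#' computes the wrapped phase difference (alternative minus reference) in
#' (-12, 12\] hours and pairs the two amplitudes. The group-level mean shift
#' is the circular mean of the differences, which remains meaningful when
#' shifts straddle the midnight wrap. Features with an undefined phase (zero
#' amplitude) in either condition are excluded and counted.
#'
#' @param fit_ref,fit_alt Cosinor result tibbles (single condition each).
#' @param features Optional feature ids to restrict to.
#' @return A tibble of class `phase_shift_tbl`: `feature_id`, `phase_ref`,
#'   `phase_alt`, `phase_shift`, `amplitude_ref`, `amplitude_alt`;
#'   attributes `mean_shift` (circular mean, hours) and `n_excluded`.
#' @export
phase_shift <- function(fit_ref, fit_alt, features = NULL) {
  for (nm in c("feature_id", "phase", "amplitude")) {
    if (!nm %in% names(fit_ref) || !nm %in% names(fit_alt)) {
      abort(sprintf("Both fits must carry a `%s` column.", nm))
    }
  }
  joined <- dplyr::inner_join(
    dplyr::select(fit_ref, "feature_id", phase_ref = "phase",
                  amplitude_ref = "amplitude"),
    dplyr::select(fit_alt, "feature_id", phase_alt = "phase",
                  amplitude_alt = "amplitude"),
    by = "feature_id")
  if (!is.null(features)) {
    joined <- dplyr::filter(joined, .data$feature_id %in% features)
  }
  defined <- !is.na(joined$phase_ref) & !is.na(joined$phase_alt)
  out <- joined[defined, ]
  out$phase_shift <- wrap_half_period(out$phase_alt - out$phase_ref)
  attr(out, "mean_shift") <- circular_mean_hours(out$phase_shift)
  attr(out, "n_excluded") <- sum(!defined)
  class(out) <- c("phase_shift_tbl", class(out))
  out
}

#' Min-max normalise profile rows across conditions
#'
#' Rescales each feature's profile (e.g. the concatenated per-timepoint
#' means of all conditions) linearly to \[0, 1\], so that the lowest value
#' of the row maps to 0 (white in a heatmap) and the highest to 1 (red).
#' Constant rows cannot be scaled; they map to 0.5 and are flagged.
#'
#' @param profiles Data frame with `feature_id` and numeric profile columns.
#' @return The same tibble with numeric columns rescaled and a logical
#'   `constant` column appended.
#' @export
#' @examples
#' normalize_rows(tibble::tibble(feature_id = "g1", a = 1, b = 3, c = 5))
normalize_rows <- function(profiles) {
  if (!is.data.frame(profiles) || !"feature_id" %in% names(profiles)) {
    abort("`profiles` must be a data frame with a `feature_id` column.")
  }
  num_cols <- names(profiles)[vapply(profiles, is.numeric, logical(1))]
  if (length(num_cols) == 0L) abort("No numeric profile columns found.")
  m <- as.matrix(profiles[, num_cols, drop = FALSE])
  lo <- apply(m, 1L, min)
  hi <- apply(m, 1L, max)
  constant <- hi - lo <= 0
  scaled <- (m - lo) / ifelse(constant, 1, hi - lo)
  scaled[constant, ] <- 0.5
  out <- profiles
  out[, num_cols] <- tibble::as_tibble(scaled)
  out$constant <- constant
  tibble::as_tibble(out)
}
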