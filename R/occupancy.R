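# Day/night and timepoint-pair comparisons of locus occupancy scores
# (log2 IP/Input), with an empirical-Bayes moderated t-statistic: per-locus
# pooled variances are shrunk toward a common prior whose degrees of
# freedom d0 and scale s0^2 are estimated by method of moments on the
# log variances (digamma/trigamma moment equations), and the posterior
# variance (d0*s0^2 + d*s^2) / (d0 + d) enters a t-statistic with d + d0
# degrees of freedom.

#' Per-locus mean occupancy by condition
#'
#' Arithmetic mean of all samples of each condition (all timepoints and
#' replicates), the condition-level summary used to compare overall
#' occupancy between genotypes or feeding regimens.
#'
#' @param data Long occupancy tibble (time-course columns).
#' @return Tibble: `feature_id`, `condition`, `mean_score`, `n_samples`.
#' @export
condition_means <- function(data) {
  check_timecourse(data)
  data |>
    dplyr::group_by(.data$feature_id, .data$condition) |>
    dplyr::summarise(mean_score = mean(.data$value),
                     n_samples = dplyr::n(), .groups = "drop")
}

#' Per-locus mean occupancy by timepoint
#'
#' Mean of the replicates (both days pooled by ZT) at every timepoint.
#' Timepoints with fewer replicates than the design maximum are averaged
#' over what is available and flagged `incomplete`.
#'
#' @param data Long occupancy tibble.
#' @return Tibble: `feature_id`, `condition`, `zt`, `mean_score`, `n_reps`,
#'   `incomplete`.
#' @export
timepoint_means <- function(data) {
  check_timecourse(data)
  out <- data |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(.data$feature_id, .data$condition, .data$zt) |>
    dplyr::summarise(mean_score = mean(.data$value),
                     n_reps = dplyr::n(), .groups = "drop")
  out |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(incomplete = .data$n_reps < max(.data$n_reps)) |>
    dplyr::ungroup()
}

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used to solve trigamma(d0/2) = excess variance of log s^2.
trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

# Method-of-moments fit of the scaled inverse-chi-square variance prior:
# log s^2 has marginal mean log s0^2 + digamma(d/2) - log(d/2)
#   - digamma(d0/2) + log(d0/2)  and variance trigamma(d/2) + trigamma(d0/2).
fit_variance_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2L) return(list(d0 = 0, s02 = NA_real_))
  z <- log(s2)
  excess <- var(z) - trigamma(df / 2)
  if (excess <= 0) {
    d0 <- Inf
    log_s02 <- mean(z) - digamma(df / 2) + log(df / 2)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    log_s02 <- mean(z) - digamma(df / 2) + log(df / 2) +
      digamma(d0 / 2) - log(d0 / 2)
  }
  list(d0 = d0, s02 = exp(log_s02))
}

#' Moderated two-group comparison of occupancy scores
#'
#' For every locus, compares the mean score of two sample groups with a
#' pooled-variance t-statistic whose variance is moderated by empirical
#' Bayes: the per-locus pooled variances `s^2` (d = n_a + n_b - 2 df) are
#' shrunk toward a prior `s0^2` with `d0` prior degrees of freedom,
#' posterior variance `(d0 * s0^2 + d * s^2) / (d0 + d)`, and the t
#' statistic is referred to a t distribution with `d + d0` degrees of
#' freedom. `d0` and `s0^2` are fitted across loci by method of moments on
#' the log variances. With `prior_df = 0` the statistic reduces to the
#' classical pooled two-sample t.
#'
#' @param data Long occupancy tibble.
#' @param samples_a,samples_b Character vectors of sample ids for the two
#'   groups (>= 2 each). The difference M is group B minus group A.
#' @param prior_df Optional override of the fitted prior degrees of freedom
#'   (`0` disables moderation; `NULL`, the default, fits it).
#' @param alpha Significance threshold on the two-sided p (default 0.05,
#'   unadjusted; multiplicity handling is left to the caller).
#'
#' @return A tibble of class `moderated_test`: `feature_id`, `mean_a`,
#'   `mean_b`, `M` (B - A), `A` ((A + B) / 2), `s2` (pooled), `s2_post`
#'   (moderated), `t`, `df_total`, `p_value`, `significant`. Attributes:
#'   `d0`, `s02`, `n_a`, `n_b`, `alpha`.
#' @export
moderated_group_test <- function(data, samples_a, samples_b,
                                 prior_df = NULL, alpha = 0.05) {
  check_timecourse(data)
  samples_a <- unique(samples_a); samples_b <- unique(samples_b)
  if (length(intersect(samples_a, samples_b)) > 0L) {
    abort("The two groups must not share samples.")
  }
  missing_ids <- setdiff(c(samples_a, samples_b), data$sample_id)
  if (length(missing_ids) > 0L) {
    abort(sprintf("Sample id(s) not in `data`: %s.",
                  paste(head(missing_ids, 5L), collapse = ", ")))
  }
  if (length(samples_a) < 2L || length(samples_b) < 2L) {
    abort("Each group needs >= 2 samples.")
  }
  mats <- tc_to_matrix(data)
  Ya <- mats$values[, samples_a, drop = FALSE]
  Yb <- mats$values[, samples_b, drop = FALSE]
  na <- length(samples_a); nb <- length(samples_b)
  mean_a <- rowMeans(Ya); mean_b <- rowMeans(Yb)
  ss_a <- rowSums((Ya - mean_a)^2)
  ss_b <- rowSums((Yb - mean_b)^2)
  d <- na + nb - 2
  s2 <- (ss_a + ss_b) / d

  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2, d)
  } else {
    check_number(prior_df, "prior_df", min = 0)
    prior <- list(d0 = prior_df,
                  s02 = if (prior_df > 0) fit_variance_prior(s2, d)$s02
                        else NA_real_)
  }
  d0 <- prior$d0; s02 <- prior$s02
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else if (d0 == 0) s2
             else (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  M <- mean_b - mean_a
  t_stat <- ifelse(se > 0, M / se, ifelse(M == 0, 0, sign(M) * Inf))
  df_total <- d + d0
  p <- 2 * pt(-abs(t_stat), df = df_total)
  p[se == 0 & M == 0] <- 1
  out <- tibble::tibble(
    feature_id = rownames(mats$values),
    mean_a = unname(mean_a), mean_b = unname(mean_b),
    M = unname(M), A = unname((mean_a + mean_b) / 2),
    s2 = unname(s2), s2_post = unname(s2_post), t = unname(t_stat),
    df_total = df_total, p_value = unname(p),
    significant = unname(p < alpha))
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  attr(out, "n_a") <- na
  attr(out, "n_b") <- nb
  attr(out, "alpha") <- alpha
  class(out) <- c("moderated_test", class(out))
  out
}

#' Moderated day-versus-night comparison
#'
#' Groups the samples of one condition into day (ZT in \[0, 12)) and night
#' (ZT in \[12, 24)) and runs [moderated_group_test()] with
#' M = night - day. The reported `mean_day` / `mean_night` (and hence M and
#' A, the MVA-plot coordinates) are means of the per-timepoint averages --
#' in the canonical design, the three day timepoint averages and the three
#' night ones -- while the test statistic uses all individual samples.
#'
#' @param data Long occupancy tibble (single condition).
#' @param alpha Significance threshold (default 0.05, unadjusted).
#' @return A `moderated_test` tibble with `mean_day`, `mean_night` columns
#'   (M = night - day, A their midpoint).
#' @export
#' @examples
#' cfg <- sim_config(0, replicates_per_timepoint = 1)
#' occ <- simulate_occupancy(occupancy_spec(30, night_effect = 0.6,
#'   affected_fraction = 0.5, seed = 2), cfg)
#' day_night_compare(occ$data)
day_night_compare <- function(data, alpha = 0.05) {
  check_timecourse(data)
  if (length(unique(data$condition)) > 1L) {
    abort("`data` must contain a single condition.")
  }
  night <- is_night(data$zt)
  day_samples <- unique(data$sample_id[!night])
  night_samples <- unique(data$sample_id[night])
  if (length(day_samples) == 0L || length(night_samples) == 0L) {
    abort("Both day (ZT < 12) and night (ZT >= 12) samples are required.")
  }
  res <- moderated_group_test(data, day_samples, night_samples, alpha = alpha)
  # MVA coordinates from the per-timepoint averages.
  tp <- timepoint_means(data)
  tp_avg <- tp |>
    dplyr::mutate(night = is_night(.data$zt)) |>
    dplyr::group_by(.data$feature_id, .data$night) |>
    dplyr::summarise(m = mean(.data$mean_score), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "night", values_from = "m") |>
    dplyr::rename(mean_day = "FALSE", mean_night = "TRUE")
  attrs <- attributes(res)[c("d0", "s02", "n_a", "n_b", "alpha")]
  res <- dplyr::left_join(tibble::as_tibble(res), tp_avg, by = "feature_id") |>
    dplyr::mutate(M = .data$mean_night - .data$mean_day,
                  A = (.data$mean_day + .data$mean_night) / 2) |>
    dplyr::relocate("feature_id", "mean_day", "mean_night", "M", "A")
  attributes(res) <- c(attributes(res), attrs,
                       list(comparison = "night - day"))
  class(res) <- c("moderated_test", class(tibble::tibble()))
  res
}

#' Moderated comparison of two timepoints
#'
#' Compares the samples at `zt_b` against those at `zt_a` (replicates and
#' days pooled per ZT); M = `zt_b` - `zt_a`. The default ZT02 vs ZT10
#' contrasts the start against the end of the light period, isolating a
#' clock-driven anticipatory rise in occupancy before the feeding period
#' from the feeding response itself.
#'
#' @param data Long occupancy tibble (single condition).
#' @param zt_a,zt_b The two zeitgeber times (defaults 2 and 10).
#' @param alpha Significance threshold (default 0.05).
#' @return A `moderated_test` tibble (M = mean at `zt_b` minus `zt_a`).
#' @export
timepoint_pair_compare <- function(data, zt_a = 2, zt_b = 10, alpha = 0.05) {
  check_timecourse(data)
  a_samples <- unique(data$sample_id[data$zt == zt_a])
  b_samples <- unique(data$sample_id[data$zt == zt_b])
  if (length(a_samples) < 2L || length(b_samples) < 2L) {
    abort(sprintf("Need >= 2 samples at both ZT%02d and ZT%02d.", zt_a, zt_b))
  }
  res <- moderated_group_test(data, a_samples, b_samples, alpha = alpha)
  attr(res, "comparison") <- sprintf("ZT%02d - ZT%02d", zt_b, zt_a)
  res
}

#' Fraction of loci whose occupancy follows a cosine curve
#'
#' Fits the 24-h cosinor to every locus and reports the fraction with
#' F-test p below `p_threshold` (default 0.05, the conventional cutoff for
#' this looser, locus-level question).
#'
#' @param data Long occupancy tibble (single condition).
#' @param p_threshold P-value cutoff (default 0.05).
#' @param period Period in hours (default 24).
#' @return One-row tibble: `condition`, `n_loci`, `n_rhythmic`, `fraction`,
#'   plus a `rhythmic_ids` list-column.
#' @export
cosine_fit_fraction <- function(data, p_threshold = 0.05, period = 24) {
  check_timecourse(data)
  if (nrow(data) == 0L) abort("Empty occupancy table: fraction undefined.")
  fit <- cosinor_fit(data, period = period)
  calls <- call_rhythmic(fit, p_threshold = p_threshold)
  calls |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_loci = dplyr::n(),
      n_rhythmic = sum(.data$rhythmic),
      fraction = mean(.data$rhythmic),
      rhythmic_ids = list(.data$feature_id[.data$rhythmic]),
      .groups = "drop")
}
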