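# Harmonic (cosinor) regression with a fixed period.
#
# Model per feature: y = b0 + b1*cos(2*pi*t/P) + b2*sin(2*pi*t/P) + e.
# Amplitude = sqrt(b1^2 + b2^2) (half peak-to-trough, log2 units); phase =
# time of the fitted maximum, atan2(b2, b1) * P / (2*pi) mapped into [0, P);
# F = (SS_model / 2) / (SS_resid / (n - 3)) against F(2, n - 3).

cosinor_design <- function(times, period) {
  cbind(intercept = 1,
        b_cos = cos(2 * pi * times / period),
        b_sin = sin(2 * pi * times / period))
}

# Amplitude below which the phase is reported as undefined.
AMP_TOL <- 1e-9

# Fit every row of Y (features x samples) against a shared time vector.
# Returns a data frame of per-feature statistics. The workhorse behind
# cosinor_fit() and the permutation FDR: one matrix product fits all
# features at once.
cosinor_fit_matrix <- function(Y, times, period = 24) {
  n <- length(times)
  X <- cosinor_design(times, period)
  XtX <- crossprod(X)
  if (n < 4L || qr(XtX)$rank < 3L) {
    abort(paste0(
      "Degenerate cosinor design: need >= 4 samples and >= 3 distinct ",
      "times mod the period."))
  }
  B <- Y %*% X %*% solve(XtX)                     # features x 3 coefficients
  fitted <- B %*% t(X)
  resid <- Y - fitted
  ss_resid <- rowSums(resid^2)
  ss_total <- rowSums((Y - rowMeans(Y))^2)
  ss_model <- pmax(ss_total - ss_resid, 0)
  df_resid <- n - 3L
  f_stat <- ifelse(ss_model <= AMP_TOL^2, 0,
                   (ss_model / 2) / (ss_resid / df_resid))
  p_value <- ifelse(ss_model <= AMP_TOL^2, 1,
                    pf(f_stat, 2, df_resid, lower.tail = FALSE))
  amplitude <- sqrt(B[, 2L]^2 + B[, 3L]^2)
  phase <- ifelse(amplitude <= AMP_TOL, NA_real_,
                  wrap_phase(atan2(B[, 3L], B[, 2L]) * period / (2 * pi),
                             period))
  phase[!is.na(phase) & period - phase < 1e-9] <- 0  # snap 24-eps to 0
  data.frame(
    feature_id = rownames(Y) %||% as.character(seq_len(nrow(Y))),
    n = n, mesor = B[, 1L], b_cos = B[, 2L], b_sin = B[, 3L],
    amplitude = amplitude, phase = phase, f_stat = f_stat,
    p_value = p_value, residual_var = ss_resid / df_resid,
    row.names = NULL
  )
}

#' Fit a 24-h cosinor regression to one feature
#'
#' Ordinary least squares of `values` on `cos(2*pi*t/period)` and
#' `sin(2*pi*t/period)` with intercept. The amplitude is half the fitted
#' peak-to-trough range; the phase is the time of the fitted maximum in
#' \[0, period), computed with the full-quadrant arctangent so that every
#' quadrant of the (cosine, sine) coefficient plane maps to the correct time
#' of day. Rhythmicity is tested with the nested-model F statistic
#' (intercept-only vs. full) on (2, n - 3) degrees of freedom.
#'
#' @param times Sampling times in hours (any real; used modulo `period`).
#' @param values Numeric measurements, one per time (log2 scale).
#' @param period Rhythm period in hours (default 24).
#'
#' @return A one-row tibble: `n`, `mesor`, `b_cos`, `b_sin`, `amplitude`,
#'   `phase` (NA when the amplitude is zero), `f_stat`, `p_value`,
#'   `residual_var`.
#' @export
#' @examples
#' t <- c(0, 4, 8, 12, 16, 20)
#' fit_cosinor(t, 2 + cos(2 * pi * t / 24))
fit_cosinor <- function(times, values, period = 24) {
  if (length(times) != length(values)) {
    abort("`times` and `values` must have the same length.")
  }
  keep <- is.finite(times) & is.finite(values)
  times <- times[keep]; values <- values[keep]
  if (length(values) < 4L) {
    abort("Insufficient data: cosinor fitting needs >= 4 samples.")
  }
  if (length(unique(round(times %% period, 10))) < 3L) {
    abort("Degenerate design: need >= 3 distinct times modulo the period.")
  }
  res <- cosinor_fit_matrix(matrix(values, nrow = 1L), times, period)
  tibble::as_tibble(res[, -1L])
}

#' Predict the fitted cosinor curve
#'
#' @param fit A one-row data frame with `mesor`, `b_cos`, `b_sin` (as
#'   returned by [fit_cosinor()] or one row of [cosinor_fit()]).
#' @param times Times (hours) at which to evaluate the curve.
#' @param period Period in hours (default 24).
#' @return Numeric vector of fitted values.
#' @export
cosinor_predict <- function(fit, times, period = 24) {
  fit$mesor + fit$b_cos * cos(2 * pi * times / period) +
    fit$b_sin * sin(2 * pi * times / period)
}

#' Fit cosinor regressions to every feature of a time course
#'
#' Takes a long time-course tibble (columns `feature_id`, `sample_id`,
#' `value`, `condition`, `zt`, `day`, `replicate`) and fits the fixed-period
#' harmonic regression to each feature, using every individual sample (the
#' two days collapse onto one 24-h cycle via ZT; replicates and days enter
#' as independent observations). If several conditions are present each is
#' fitted separately.
#'
#' Features that cannot be fitted (missing values leaving fewer than 4
#' samples, or a rank-deficient design) are flagged in the `status` column
#' with NA statistics rather than dropped.
#'
#' @param data Long time-course tibble (e.g. `simulate_expression()$data`).
#' @param period Period in hours (default 24).
#'
#' @return A tibble with one row per feature (and condition), columns
#'   `feature_id`, `condition`, `n`, `mesor`, `b_cos`, `b_sin`, `amplitude`,
#'   `phase`, `f_stat`, `p_value`, `residual_var`, `status`.
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(10, seed = 1))
#' cosinor_fit(sim$data)
cosinor_fit <- function(data, period = 24) {
  check_timecourse(data)
  if (nrow(data) == 0L) {
    warn("Empty time course: returning an empty cosinor result.")
    return(tibble::tibble(
      feature_id = character(), condition = character(), n = integer(),
      mesor = double(), b_cos = double(), b_sin = double(),
      amplitude = double(), phase = double(), f_stat = double(),
      p_value = double(), residual_var = double(), status = character()))
  }
  out <- data |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(d, key) {
      d$condition <- key$condition
      cosinor_fit_one_condition(d, period)
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("feature_id", "condition")
  attr(out, "period") <- period
  out
}

cosinor_fit_one_condition <- function(data, period) {
  mats <- tc_to_matrix(data)
  Y <- mats$values
  times <- mats$samples$zt
  complete <- rowSums(!is.finite(Y)) == 0L
  res_ok <- NULL
  if (any(complete)) {
    res_ok <- cosinor_fit_matrix(Y[complete, , drop = FALSE], times, period)
    res_ok$status <- "ok"
  }
  res_bad <- NULL
  if (any(!complete)) {
    # Refit feature-wise on the finite samples; flag unfittable features.
    res_bad <- purrr::map_dfr(rownames(Y)[!complete], function(fid) {
      y <- Y[fid, ]
      fit <- tryCatch(fit_cosinor(times, y, period), error = function(e) NULL)
      if (is.null(fit)) {
        tibble::tibble(
          feature_id = fid, n = sum(is.finite(y)), mesor = NA_real_,
          b_cos = NA_real_, b_sin = NA_real_, amplitude = NA_real_,
          phase = NA_real_, f_stat = NA_real_, p_value = NA_real_,
          residual_var = NA_real_, status = "unfittable")
      } else {
        dplyr::bind_cols(tibble::tibble(feature_id = fid), fit,
                         tibble::tibble(status = "incomplete"))
      }
    })
  }
  res <- dplyr::bind_rows(tibble::as_tibble(res_ok), res_bad)
  res[match(rownames(Y), res$feature_id), ]
}
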