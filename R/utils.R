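# Internal helpers shared across modules.

# Wrap a phase difference (hours) into (-12, 12].
wrap_half_period <- function(x, period = 24) {
  half <- period / 2
  out <- ((x + half) %% period) - half
  out[out == -half] <- half
  out
}

# Wrap an absolute phase into [0, period).
wrap_phase <- function(x, period = 24) {
  x %% period
}

# Circular mean of phase differences (hours on a `period`-hour circle),
# mapped back into (-period/2, period/2].
circular_mean_hours <- function(x, period = 24) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  theta <- x * 2 * pi / period
  m <- atan2(mean(sin(theta)), mean(cos(theta))) * period / (2 * pi)
  wrap_half_period(m, period)
}

# Day/night classification: lights on at ZT0, off at ZT12.
is_night <- function(zt) {
  zt %% 24 >= 12
}

check_number <- function(x, name, min = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min || (!allow_zero && x == min)) {
    abort(sprintf("`%s` must be %s %s.", name,
                  if (allow_zero) ">=" else ">", format(min)))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Columns every time-course tibble must carry.
TC_COLS <- c("feature_id", "sample_id", "value", "condition", "zt", "day", "replicate")

check_timecourse <- function(data, arg = "data") {
  if (!is.data.frame(data)) abort(sprintf("`%s` must be a data frame.", arg))
  missing_cols <- setdiff(TC_COLS, names(data))
  if (length(missing_cols) > 0L) {
    abort(sprintf("`%s` is missing time-course column(s): %s.",
                  arg, paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(data$zt)) || any(data$zt < 0) || any(data$zt >= 24)) {
    abort(sprintf("`%s$zt` must contain zeitgeber times in [0, 24).", arg))
  }
  invisible(data)
}

# Long time course -> features x samples matrix plus per-sample metadata.
tc_to_matrix <- function(data) {
  check_timecourse(data)
  samples <- dplyr::distinct(data, .data$sample_id, .data$condition,
                             .data$zt, .data$day, .data$replicate)
  if (anyDuplicated(samples$sample_id)) {
    dups <- unique(samples$sample_id[duplicated(samples$sample_id)])
    abort(sprintf("Sample id(s) with conflicting metadata: %s.",
                  paste(head(dups, 5L), collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(data, "feature_id", "sample_id", "value"),
    names_from = "sample_id", values_from = "value"
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$feature_id
  samples <- samples[match(colnames(m), samples$sample_id), ]
  list(values = m, samples = samples)
}
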