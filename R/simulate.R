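#' Describe one experimental condition for the expression simulator
#'
#' A condition is characterised by the fraction of features that cycle, the
#' log2 amplitudes and peak phases of the cycling features, and -- for
#' conditions derived from a reference (the first condition of a
#' [sim_config()]) -- a multiplicative amplitude damping and an additive
#' phase shift applied to the rhythms shared with the reference. This is how
#' scenarios such as "constant feeding damps amplitudes" or "clock knockout
#' abolishes most rhythms" are encoded.
#'
#' @param name Condition label.
#' @param rhythmic_fraction Fraction of features cycling in this condition,
#'   in \[0, 1\].
#' @param amplitude_range Length-2 numeric, min/max log2 amplitude for newly
#'   drawn rhythmic features (amplitude = half peak-to-trough).
#' @param phase_dist Data frame with columns `phase_h` (peak time, hours),
#'   `weight` (mixture weights, summing to 1) and optionally `sd` (wrapped
#'   Gaussian jitter, hours; default 1.5). `NULL` means phases uniform on
#'   \[0, 24).
#' @param mesor_range Length-2 numeric, min/max baseline (log2 units).
#' @param amplitude_damping Multiplier applied to amplitudes of features
#'   shared with the reference condition (>= 0; 1 = unchanged, 0 = rhythm
#'   lost).
#' @param phase_shift_h Hours added to the phases of features shared with
#'   the reference condition.
#'
#' @return A `condition_spec` list.
#' @export
#' @examples
#' condition_spec("control", rhythmic_fraction = 0.1)
condition_spec <- function(name,
                           rhythmic_fraction = 0.1,
                           amplitude_range = c(0.25, 1.5),
                           phase_dist = default_phase_dist(),
                           mesor_range = c(4, 10),
                           amplitude_damping = 1,
                           phase_shift_h = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string.")
  }
  check_number(rhythmic_fraction, "rhythmic_fraction", min = 0)
  if (rhythmic_fraction > 1) abort("`rhythmic_fraction` must be in [0, 1].")
  if (length(amplitude_range) != 2L || amplitude_range[1] > amplitude_range[2] ||
      any(amplitude_range < 0)) {
    abort("`amplitude_range` must be c(min, max) with 0 <= min <= max.")
  }
  if (length(mesor_range) != 2L || mesor_range[1] > mesor_range[2]) {
    abort("`mesor_range` must be c(min, max) with min <= max.")
  }
  check_number(amplitude_damping, "amplitude_damping", min = 0)
  check_number(phase_shift_h, "phase_shift_h")
  if (!is.null(phase_dist)) {
    if (!is.data.frame(phase_dist) ||
        !all(c("phase_h", "weight") %in% names(phase_dist))) {
      abort("`phase_dist` must have columns phase_h and weight (or be NULL).")
    }
    if (abs(sum(phase_dist$weight) - 1) > 1e-8) {
      abort("`phase_dist$weight` must sum to 1.")
    }
    if (is.null(phase_dist$sd)) phase_dist$sd <- 1.5
  }
  structure(
    list(name = name, rhythmic_fraction = rhythmic_fraction,
         amplitude_range = as.numeric(amplitude_range),
         phase_dist = phase_dist, mesor_range = as.numeric(mesor_range),
         amplitude_damping = amplitude_damping, phase_shift_h = phase_shift_h),
    class = "condition_spec"
  )
}

#' Default bimodal phase distribution
#'
#' Liver diurnal transcriptomes typically show two dominant phase groups, at
#' the beginning and at the end of the night; the default mixture places
#' equal weight at ZT14 and ZT22 with 1.5 h of wrapped Gaussian jitter.
#'
#' @return A tibble with columns `phase_h`, `weight`, `sd`.
#' @export
default_phase_dist <- function() {
  tibble::tibble(phase_h = c(14, 22), weight = c(0.5, 0.5), sd = 1.5)
}

#' Configure a synthetic diurnal expression experiment
#'
#' The design mirrors a light/dark entrained time course: samples taken at a
#' fixed set of zeitgeber times over consecutive days, with replicate animals
#' per timepoint per day, under one or more feeding/genotype conditions. The
#' first condition is the reference: other conditions keep its rhythmic
#' features (subject to their own `rhythmic_fraction`) with amplitudes scaled
#' by `amplitude_damping` and phases shifted by `phase_shift_h`.
#'
#' @param n_features Number of features (genes).
#' @param conditions List of [condition_spec()] objects (first = reference).
#' @param timepoints_h Zeitgeber times sampled, strictly increasing, in
#'   \[0, 24). Default `c(2, 6, 10, 14, 18, 22)`.
#' @param n_days Number of consecutive sampling days (default 2). Samples at
#'   the same ZT on different days are replicates of that ZT.
#' @param replicates_per_timepoint Replicates per timepoint per day
#'   (default 3).
#' @param noise_sd Gaussian noise standard deviation, log2 units
#'   (default 0.2).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_features,
                       conditions = list(condition_spec("control")),
                       timepoints_h = c(2, 6, 10, 14, 18, 22),
                       n_days = 2,
                       replicates_per_timepoint = 3,
                       noise_sd = 0.2,
                       seed = 1L) {
  check_count(n_features, "n_features")
  if (!is.list(conditions) || length(conditions) < 1L ||
      !all(vapply(conditions, inherits, logical(1), "condition_spec"))) {
    abort("`conditions` must be a non-empty list of condition_spec objects.")
  }
  cond_names <- vapply(conditions, `[[`, character(1), "name")
  if (anyDuplicated(cond_names)) abort("Condition names must be unique.")
  if (length(timepoints_h) < 1L || any(!is.finite(timepoints_h)) ||
      any(timepoints_h < 0) || any(timepoints_h >= 24) ||
      any(diff(timepoints_h) <= 0)) {
    abort("`timepoints_h` must be strictly increasing and in [0, 24).")
  }
  check_count(n_days, "n_days", min = 1L)
  check_count(replicates_per_timepoint, "replicates_per_timepoint", min = 1L)
  check_number(noise_sd, "noise_sd", min = 0)
  check_count(seed, "seed")
  structure(
    list(n_features = as.integer(n_features), conditions = conditions,
         timepoints_h = as.numeric(timepoints_h), n_days = as.integer(n_days),
         replicates_per_timepoint = as.integer(replicates_per_timepoint),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Sample sheet for one condition of a design.
build_sample_sheet <- function(config, condition) {
  grid <- tidyr::expand_grid(
    zt = config$timepoints_h,
    day = seq_len(config$n_days),
    replicate = seq_len(config$replicates_per_timepoint)
  )
  tibble::tibble(
    sample_id = sprintf("%s_ZT%02d_d%d_r%d", condition, round(grid$zt),
                        grid$day, grid$replicate),
    condition = condition,
    zt = grid$zt, day = grid$day, replicate = grid$replicate
  )
}

# Draw phases from a mixture of wrapped normals (or uniform when NULL).
draw_phases <- function(n, phase_dist) {
  if (n == 0L) return(numeric(0))
  if (is.null(phase_dist)) return(stats::runif(n, 0, 24))
  comp <- sample.int(nrow(phase_dist), n, replace = TRUE,
                     prob = phase_dist$weight)
  wrap_phase(phase_dist$phase_h[comp] +
               stats::rnorm(n, 0, phase_dist$sd[comp]))
}

#' Simulate a diurnal expression time course with known ground truth
#'
#' Each feature's expected value at time `t` is
#' `mesor + A * cos(2 * pi * (t - phase) / 24)` with `A = 0` for arrhythmic
#' features, plus iid Gaussian noise on the log2 scale. The per-feature truth
#' (rhythmic flag, amplitude, phase, mesor, per condition) is returned
#' alongside the data so downstream stages can be validated by parameter
#' recovery.
#'
#' @param config A [sim_config()].
#'
#' @return An object of class `diurnal_sim`: a list with `data` (long tibble
#'   with columns feature_id, sample_id, value, condition, zt, day,
#'   replicate), `truth` (per feature and condition: rhythmic, amplitude,
#'   phase, mesor), `samples` (the sample sheet) and `config`.
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(20, seed = 42))
#' head(sim$data)
#' head(sim$truth)
simulate_expression <- function(config) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, config)
  }
  n <- config$n_features
  feature_ids <- sprintf("gene_%04d", seq_len(max(n, 0L)))

  withr::with_seed(config$seed, {
    ref <- config$conditions[[1L]]
    truth_list <- vector("list", length(config$conditions))
    # Reference condition: draw everything fresh.
    n_rhythmic_ref <- round(ref$rhythmic_fraction * n)
    rhythmic_ref <- seq_len(n) <= n_rhythmic_ref  # first features cycle
    mesor <- stats::runif(n, ref$mesor_range[1], ref$mesor_range[2])
    amp_ref <- numeric(n)
    amp_ref[rhythmic_ref] <- stats::runif(
      n_rhythmic_ref, ref$amplitude_range[1], ref$amplitude_range[2])
    phase_ref <- rep(NA_real_, n)
    phase_ref[rhythmic_ref] <- draw_phases(n_rhythmic_ref, ref$phase_dist)
    truth_list[[1L]] <- tibble::tibble(
      feature_id = feature_ids, condition = ref$name,
      rhythmic = rhythmic_ref, amplitude = amp_ref, phase = phase_ref,
      mesor = mesor
    )
    for (ci in seq_along(config$conditions)[-1L]) {
      cs <- config$conditions[[ci]]
      n_rhythmic <- round(cs$rhythmic_fraction * n)
      # Shared rhythms first (reference order), then newly cycling features.
      ord <- order(!rhythmic_ref, seq_len(n))
      rhythmic <- logical(n)
      rhythmic[ord[seq_len(n_rhythmic)]] <- TRUE
      shared <- rhythmic & rhythmic_ref
      fresh <- rhythmic & !rhythmic_ref
      amp <- numeric(n)
      amp[shared] <- amp_ref[shared] * cs$amplitude_damping
      amp[fresh] <- stats::runif(sum(fresh), cs$amplitude_range[1],
                                 cs$amplitude_range[2])
      phase <- rep(NA_real_, n)
      phase[shared] <- wrap_phase(phase_ref[shared] + cs$phase_shift_h)
      phase[fresh] <- draw_phases(sum(fresh), cs$phase_dist)
      rhythmic <- rhythmic & amp > 0  # full damping silences the rhythm
      phase[!rhythmic] <- NA_real_
      truth_list[[ci]] <- tibble::tibble(
        feature_id = feature_ids, condition = cs$name,
        rhythmic = rhythmic, amplitude = amp, phase = phase, mesor = mesor
      )
    }
    truth <- dplyr::bind_rows(truth_list)

    data_list <- vector("list", length(config$conditions))
    for (ci in seq_along(config$conditions)) {
      cs <- config$conditions[[ci]]
      sheet <- build_sample_sheet(config, cs$name)
      tr <- truth_list[[ci]]
      amp <- tr$amplitude
      ph <- ifelse(is.na(tr$phase), 0, tr$phase)
      # features x samples expected signal
      signal <- outer(tr$mesor, rep(1, nrow(sheet))) +
        (amp * cos(2 * pi * ph / 24)) %o% cos(2 * pi * sheet$zt / 24) +
        (amp * sin(2 * pi * ph / 24)) %o% sin(2 * pi * sheet$zt / 24)
      noise <- matrix(stats::rnorm(length(signal), 0, config$noise_sd),
                      nrow = nrow(signal), ncol = ncol(signal))
      values <- signal + noise
      data_list[[ci]] <- tibble::tibble(
        feature_id = rep(feature_ids, times = nrow(sheet)),
        sample_id = rep(sheet$sample_id, each = max(n, 0L)),
        value = as.vector(values)
      ) |>
        dplyr::left_join(sheet, by = "sample_id")
    }
    data <- dplyr::bind_rows(data_list)
    samples <- dplyr::bind_rows(
      lapply(config$conditions, function(cs) build_sample_sheet(config, cs$name)))
  })

  structure(list(data = data, truth = truth, samples = samples,
                 config = config),
            class = "diurnal_sim")
}

#' @export
print.diurnal_sim <- function(x, ...) {
  cat(sprintf(
    "<diurnal_sim> %d feature(s) x %d sample(s), %d condition(s), seed %d\n",
    x$config$n_features %||% length(unique(x$truth$feature_id)),
    nrow(x$samples), length(unique(x$samples$condition)),
    x$config$seed))
  invisible(x)
}

#' Configure a synthetic occupancy (log2 IP/Input) experiment
#'
#' Encodes the two planted mechanisms of nighttime feeding biology: a
#' `night_effect` added to all night samples (ZT >= 12) of an affected locus
#' (occupancy rises while food is available), and an `anticipation_effect`
#' added at the last daytime timepoint when `clock_on` is `TRUE` (a
#' functional circadian clock raises occupancy before the feeding period
#' begins). A global `condition_offset` models conditions with elevated
#' baseline occupancy, such as loss of a repressor.
#'
#' @param n_loci Number of loci.
#' @param base_mean Baseline score, log2(IP/Input) units (default 1).
#' @param night_effect Score added to night samples of affected loci.
#' @param anticipation_effect Score added at the last daytime timepoint for
#'   affected loci when `clock_on`.
#' @param clock_on Is the circadian clock functional? (default `TRUE`)
#' @param condition_offset Global score shift (default 0).
#' @param affected_fraction Fraction of loci carrying the planted effects.
#' @param noise_sd Gaussian noise sd, score units (default 0.2).
#' @param seed Integer seed.
#'
#' @return An `occupancy_spec` list.
#' @export
occupancy_spec <- function(n_loci,
                           base_mean = 1,
                           night_effect = 0,
                           anticipation_effect = 0,
                           clock_on = TRUE,
                           condition_offset = 0,
                           affected_fraction = 0.1,
                           noise_sd = 0.2,
                           seed = 1L) {
  check_count(n_loci, "n_loci")
  check_number(base_mean, "base_mean")
  check_number(night_effect, "night_effect")
  check_number(anticipation_effect, "anticipation_effect")
  if (!is.logical(clock_on) || length(clock_on) != 1L || is.na(clock_on)) {
    abort("`clock_on` must be TRUE or FALSE.")
  }
  check_number(condition_offset, "condition_offset")
  check_number(affected_fraction, "affected_fraction", min = 0)
  if (affected_fraction > 1) abort("`affected_fraction` must be in [0, 1].")
  check_number(noise_sd, "noise_sd", min = 0)
  check_count(seed, "seed")
  structure(
    list(n_loci = as.integer(n_loci), base_mean = base_mean,
         night_effect = night_effect,
         anticipation_effect = anticipation_effect, clock_on = clock_on,
         condition_offset = condition_offset,
         affected_fraction = affected_fraction, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "occupancy_spec"
  )
}

#' Simulate locus occupancy scores with planted day/night structure
#'
#' Generates one condition's loci-by-samples table under the design of
#' `config` (timepoints, days, replicates). The score of locus `l` in sample
#' `s` is `base_mean + condition_offset + night_effect * [night & affected]
#' + anticipation_effect * [zt == last daytime ZT & clock_on & affected]
#' + noise`. Day is ZT in \[0, 12), night ZT in \[12, 24).
#'
#' @param spec An [occupancy_spec()].
#' @param config A [sim_config()] describing the sampling design (its
#'   feature/noise fields are ignored); `condition` names the condition.
#' @param condition Condition label (default "control").
#'
#' @return A `diurnal_sim` object whose `truth` has per-locus columns
#'   `affected`, `night_effect`, `anticipation_effect`.
#' @export
#' @examples
#' cfg <- sim_config(0, replicates_per_timepoint = 1)
#' occ <- simulate_occupancy(occupancy_spec(50, night_effect = 0.5), cfg)
simulate_occupancy <- function(spec, config, condition = "control") {
  if (!inherits(spec, "occupancy_spec")) spec <- do.call(occupancy_spec, spec)
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  day_zts <- config$timepoints_h[!is_night(config$timepoints_h)]
  if (length(day_zts) == 0L || all(is_night(config$timepoints_h))) {
    abort("Design must contain at least one daytime timepoint (ZT < 12).")
  }
  last_day_zt <- max(day_zts)
  locus_ids <- sprintf("locus_%04d", seq_len(max(spec$n_loci, 0L)))
  sheet <- build_sample_sheet(config, condition)

  withr::with_seed(spec$seed, {
    n_aff <- round(spec$affected_fraction * spec$n_loci)
    affected <- seq_len(spec$n_loci) <= n_aff
    night <- is_night(sheet$zt)
    anticip <- spec$clock_on & sheet$zt == last_day_zt
    signal <- matrix(spec$base_mean + spec$condition_offset,
                     nrow = spec$n_loci, ncol = nrow(sheet))
    signal <- signal +
      (affected * spec$night_effect) %o% as.numeric(night) +
      (affected * spec$anticipation_effect) %o% as.numeric(anticip)
    values <- signal +
      matrix(stats::rnorm(length(signal), 0, spec$noise_sd),
             nrow = nrow(signal), ncol = ncol(signal))
    data <- tibble::tibble(
      feature_id = rep(locus_ids, times = nrow(sheet)),
      sample_id = rep(sheet$sample_id, each = max(spec$n_loci, 0L)),
      value = as.vector(values)
    ) |>
      dplyr::left_join(sheet, by = "sample_id")
  })

  truth <- tibble::tibble(
    feature_id = locus_ids, condition = condition, affected = affected,
    night_effect = ifelse(affected, spec$night_effect, 0),
    anticipation_effect = ifelse(
      affected & spec$clock_on, spec$anticipation_effect, 0)
  )
  structure(list(data = data, truth = truth, samples = sheet,
                 config = config, spec = spec),
            class = "diurnal_sim")
}
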