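#' Configure an end-to-end rhythm analysis run
#'
#' Collects the tunable parameters of the pipeline with their conventional
#' defaults: 24-h period, rhythm p-value cutoff 1e-4 for expression and
#' 0.05 for occupancy, amplitude cutoff 0.25 log2 units, 1000 permutations
#' for the FDR, k scanned over 2-10 for clustering.
#'
#' @param matrix_path,samples_path Input TSVs (see [read_timecourse()]);
#'   may be `NULL` when `data` is passed to [run_pipeline()] directly.
#' @param mode `"expression"` or `"occupancy"`.
#' @param period Period in hours.
#' @param p_threshold Rhythm-call cutoff (default 1e-4 for expression,
#'   0.05 for occupancy).
#' @param min_amplitude Amplitude cutoff, log2 units (default 0.25).
#' @param n_permutations Permutations for the FDR (default 1000; 0 skips).
#' @param k_range Candidate cluster numbers (default 2:10).
#' @param metric Clustering distance metric (default "euclidean").
#' @param zt_pair The two ZTs of the timepoint-pair comparison
#'   (default c(2, 10)).
#' @param seed Integer seed for all randomised stages.
#' @param out_dir Output directory for TSVs (`NULL` = return only).
#' @return A `run_config` list.
#' @export
run_config <- function(matrix_path = NULL, samples_path = NULL,
                       mode = c("expression", "occupancy"),
                       period = 24,
                       p_threshold = NULL,
                       min_amplitude = 0.25,
                       n_permutations = 1000,
                       k_range = 2:10,
                       metric = "euclidean",
                       zt_pair = c(2, 10),
                       seed = 1L,
                       out_dir = NULL) {
  mode <- match.arg(mode)
  p_threshold <- p_threshold %||% if (mode == "expression") 1e-4 else 0.05
  check_number(period, "period", min = 0, allow_zero = FALSE)
  check_number(p_threshold, "p_threshold", min = 0, allow_zero = FALSE)
  check_number(min_amplitude, "min_amplitude", min = 0)
  check_count(n_permutations, "n_permutations", min = 0L)
  check_count(seed, "seed")
  structure(
    list(matrix_path = matrix_path, samples_path = samples_path, mode = mode,
         period = period, p_threshold = p_threshold,
         min_amplitude = min_amplitude,
         n_permutations = as.integer(n_permutations),
         k_range = as.integer(k_range), metric = metric,
         zt_pair = as.numeric(zt_pair), seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config")
}

#' Load a run configuration from a YAML or JSON file
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys are the
#'   arguments of [run_config()].
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  fields <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    abort("Config file must be .yaml/.yml or .json.")
  }
  unknown <- setdiff(names(fields), names(formals(run_config)))
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown config field(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  do.call(run_config, fields)
}

pipeline_meta <- function(config) {
  list(package = "diurnal",
       version = as.character(utils::packageVersion("diurnal")),
       mode = config$mode, period = config$period,
       p_threshold = config$p_threshold,
       min_amplitude = config$min_amplitude,
       n_permutations = config$n_permutations, seed = config$seed)
}

#' Run the full rhythm-analysis workflow
#'
#' Expression mode: per-condition cosinor fits, rhythm calls, permutation
#' FDR, amplitude filtering, reverse-cumulative-frequency curves, phase
#' histograms, a 2-3 condition rhythmic-set partition, and PAM clustering of
#' the first (reference) condition's filtered profiles with
#' silhouette-selected k. Occupancy mode: cosinor-fit fraction, condition
#' and timepoint means, and moderated day-vs-night and timepoint-pair
#' comparisons per condition. Per-stage feature counts are logged via
#' `message()`; when `out_dir` is set every table is written as TSV with a
#' metadata header (version, seed, thresholds), and reruns with the same
#' config and seed are byte-identical.
#'
#' @param config A [run_config()].
#' @param data Optional long time-course tibble (otherwise read from
#'   `config$matrix_path` / `config$samples_path`).
#' @return A named list of result tibbles (invisible components depend on
#'   the mode).
#' @export
run_pipeline <- function(config, data = NULL) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config.")
  if (is.null(data)) {
    if (is.null(config$matrix_path) || is.null(config$samples_path)) {
      abort("Provide `data` or set matrix_path/samples_path in the config.")
    }
    data <- read_timecourse(config$matrix_path, config$samples_path)
  }
  check_timecourse(data)
  n_missing <- data |>
    dplyr::group_by(.data$condition, .data$feature_id) |>
    dplyr::summarise(any_na = any(!is.finite(.data$value)),
                     .groups = "drop") |>
    dplyr::summarise(n = sum(.data$any_na)) |>
    dplyr::pull(.data$n)
  message(sprintf("[input] %d features x %d samples; %d condition(s); %d feature-condition pairs with missing values",
                  length(unique(data$feature_id)),
                  length(unique(data$sample_id)),
                  length(unique(data$condition)), n_missing))
  if (config$mode == "expression") {
    res <- run_expression_pipeline(config, data)
  } else {
    res <- run_occupancy_pipeline(config, data)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    meta <- pipeline_meta(config)
    for (nm in names(res)) {
      if (is.data.frame(res[[nm]])) {
        write_tsv_meta(res[[nm]],
                       file.path(config$out_dir, paste0(nm, ".tsv")), meta)
      }
    }
    message(sprintf("[output] wrote %d table(s) to %s",
                    sum(vapply(res, is.data.frame, logical(1))),
                    config$out_dir))
  }
  invisible(res)
}

run_expression_pipeline <- function(config, data) {
  conditions <- unique(data$condition)
  fit <- cosinor_fit(data, period = config$period)
  calls <- call_rhythmic(fit, p_threshold = config$p_threshold)
  message(sprintf("[fit] rhythmic features per condition: %s",
                  paste(sprintf("%s=%d", conditions,
                                vapply(conditions, function(cc)
                                  sum(calls$rhythmic[calls$condition == cc]),
                                  integer(1))), collapse = ", ")))
  fdr <- NULL
  if (config$n_permutations > 0L) {
    fdr <- purrr::map_dfr(conditions, function(cc) {
      estimate_fdr(dplyr::filter(data, .data$condition == cc),
                   p_threshold = config$p_threshold,
                   n_perm = config$n_permutations, seed = config$seed,
                   period = config$period)
    })
    message(sprintf("[fdr] %s",
                    paste(sprintf("%s=%.3g", fdr$condition, fdr$fdr),
                          collapse = ", ")))
  }
  # Reference-condition rhythmic set, amplitude-filtered.
  ref <- conditions[[1L]]
  ref_calls <- dplyr::filter(calls, .data$condition == ref, .data$rhythmic)
  filtered <- amplitude_filter(ref_calls, config$min_amplitude)
  message(sprintf("[filter] %s: %d rhythmic, %d pass amplitude >= %.3g",
                  ref, nrow(ref_calls), nrow(filtered), config$min_amplitude))
  rcf_curves <- dplyr::bind_rows(lapply(conditions, function(cc) {
    amps <- calls$amplitude[calls$condition == cc & calls$rhythmic]
    if (length(amps) == 0L) return(NULL)
    rcf(amps, group = cc)
  }))
  phase_hist <- dplyr::bind_rows(lapply(conditions, function(cc) {
    ph <- filtered_phases <- calls |>
      dplyr::filter(.data$condition == cc, .data$rhythmic,
                    !is.na(.data$phase),
                    .data$amplitude >= config$min_amplitude)
    if (nrow(ph) == 0L) return(NULL)
    dplyr::mutate(phase_histogram(ph$phase), condition = cc)
  }))
  partition <- NULL
  if (length(conditions) >= 2L && length(conditions) <= 3L) {
    sets <- lapply(conditions, function(cc)
      rhythmic_ids(dplyr::filter(calls, .data$condition == cc)))
    names(sets) <- conditions
    partition <- partition_sets(sets)
  }
  cluster_assign <- sil_by_k <- NULL
  if (nrow(filtered) >= 3L) {
    prof <- profile_matrix(dplyr::filter(data, .data$condition == ref),
                           features = filtered$feature_id)
    model <- tryCatch(
      select_k(prof, k_range = config$k_range, metric = config$metric),
      error = function(e) NULL)
    if (!is.null(model)) {
      message(sprintf("[cluster] selected k = %d (mean silhouette %.3f)",
                      model$k, model$mean_silhouette))
      cluster_assign <- tidy(model)
      sil_by_k <- model$silhouette_by_k
    }
  }
  list(cosinor = calls, fdr = fdr, filtered = filtered,
       rcf = rcf_curves, phase_histogram = phase_hist,
       partition = partition, clusters = cluster_assign,
       silhouette_by_k = sil_by_k)
}

run_occupancy_pipeline <- function(config, data) {
  conditions <- unique(data$condition)
  cosfrac <- cosine_fit_fraction(data, p_threshold = config$p_threshold,
                                 period = config$period)
  message(sprintf("[cosfrac] %s",
                  paste(sprintf("%s=%.1f%%", cosfrac$condition,
                                100 * cosfrac$fraction), collapse = ", ")))
  cmeans <- condition_means(data)
  tmeans <- timepoint_means(data)
  daynight <- purrr::map_dfr(conditions, function(cc) {
    r <- day_night_compare(dplyr::filter(data, .data$condition == cc))
    dplyr::mutate(tibble::as_tibble(r), condition = cc)
  })
  ztpair <- purrr::map_dfr(conditions, function(cc) {
    r <- timepoint_pair_compare(dplyr::filter(data, .data$condition == cc),
                                zt_a = config$zt_pair[1L],
                                zt_b = config$zt_pair[2L])
    dplyr::mutate(tibble::as_tibble(r), condition = cc)
  })
  message(sprintf("[daynight] significant loci per condition: %s",
                  paste(sprintf("%s=%d", conditions,
                                vapply(conditions, function(cc)
                                  sum(daynight$significant[daynight$condition == cc]),
                                  integer(1))), collapse = ", ")))
  list(cosine_fraction = cosfrac, condition_means = cmeans,
       timepoint_means = tmeans, day_night = daynight,
       zt_pair = ztpair)
}
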