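test_that("empty designs give empty matrices and truth tables", {
  sim <- simulate_expression(sim_config(0, seed = 1))
  expect_equal(nrow(sim$data), 0)
  expect_equal(nrow(sim$truth), 0)
})

test_that("the same config and seed reproduce bit-identical output", {
  cfg <- sim_config(25, seed = 11,
                    conditions = list(condition_spec("control"),
                                      condition_spec("cf", amplitude_damping = 0.5)))
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth, s2$truth)
  o1 <- simulate_occupancy(occupancy_spec(30, night_effect = 0.4, seed = 4), cfg)
  o2 <- simulate_occupancy(occupancy_spec(30, night_effect = 0.4, seed = 4), cfg)
  expect_identical(o1$data, o2$data)
})

test_that("sample counts follow timepoints x days x replicates per condition", {
  cfg <- sim_config(3, timepoints_h = c(2, 6, 10, 14, 18, 22), n_days = 2,
                    replicates_per_timepoint = 3, seed = 2,
                    conditions = list(condition_spec("a"), condition_spec("b")))
  sim <- simulate_expression(cfg)
  counts <- dplyr::count(sim$samples, condition)
  expect_equal(counts$n, c(36, 36))
  expect_equal(nrow(sim$data), 3 * 72)
})

test_that("noiseless planted cosines are recovered exactly by the cosinor fit", {
  cfg <- sim_config(
    5, noise_sd = 0, seed = 7,
    conditions = list(condition_spec("control", rhythmic_fraction = 1,
                                     amplitude_range = c(0.5, 1.5))))
  sim <- simulate_expression(cfg)
  fit <- cosinor_fit(sim$data)
  truth <- sim$truth
  expect_equal(fit$amplitude, truth$amplitude, tolerance = 1e-10)
  expect_equal(fit$mesor, truth$mesor, tolerance = 1e-10)
  expect_true(all(phase_abs_diff(fit$phase, truth$phase) < 1e-8))
})

test_that("planted amplitudes follow the configured range (generator-vs-spec)", {
  cfg <- sim_config(
    2000, noise_sd = 0.2, seed = 13,
    conditions = list(condition_spec("control", rhythmic_fraction = 0.05,
                                     amplitude_range = c(0.5, 1))))
  sim <- simulate_expression(cfg)
  amp <- sim$truth$amplitude[sim$truth$rhythmic]
  expect_equal(length(amp), 100)
  expect_true(all(amp >= 0.5 & amp <= 1))
  # draws should be uniform over the configured range
  ks <- suppressWarnings(stats::ks.test(amp, "punif", 0.5, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("derived conditions damp amplitudes and shift phases of shared rhythms", {
  cfg <- sim_config(
    100, noise_sd = 0, seed = 3,
    conditions = list(
      condition_spec("control", rhythmic_fraction = 0.5),
      condition_spec("cf", rhythmic_fraction = 0.5,
                     amplitude_damping = 0.6, phase_shift_h = -1.5)))
  sim <- simulate_expression(cfg)
  tr <- tidyr::pivot_wider(sim$truth, id_cols = "feature_id",
                           names_from = "condition",
                           values_from = c("rhythmic", "amplitude", "phase"))
  shared <- tr$rhythmic_control & tr$rhythmic_cf
  expect_true(any(shared))
  expect_equal(tr$amplitude_cf[shared], 0.6 * tr$amplitude_control[shared])
  d <- phase_abs_diff(tr$phase_cf[shared],
                      (tr$phase_control[shared] - 1.5) %% 24)
  expect_true(all(d < 1e-12))
})

test_that("occupancy generator plants exact effects when noiseless", {
  cfg <- sim_config(0, replicates_per_timepoint = 2, n_days = 1)
  # noiseless night effect: night mean - day mean = 0.5 for every locus
  occ <- simulate_occupancy(
    occupancy_spec(20, night_effect = 0.5, affected_fraction = 1,
                   noise_sd = 0, seed = 5), cfg)
  dn <- occ$data |>
    dplyr::group_by(feature_id, night = zt >= 12) |>
    dplyr::summarise(m = mean(value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "night", values_from = "m")
  expect_equal(dn$`TRUE` - dn$`FALSE`, rep(0.5, 20))
  # anticipation lands only at ZT10, only for affected loci, only with clock
  occ2 <- simulate_occupancy(
    occupancy_spec(20, anticipation_effect = 0.4, clock_on = TRUE,
                   affected_fraction = 0.5, noise_sd = 0, seed = 6), cfg)
  zt <- occ2$data |>
    dplyr::filter(zt %in% c(2, 10)) |>
    dplyr::group_by(feature_id, zt) |>
    dplyr::summarise(m = mean(value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "zt", values_from = "m",
                       names_prefix = "zt")
  truth <- occ2$truth[match(zt$feature_id, occ2$truth$feature_id), ]
  expect_equal(zt$zt10 - zt$zt2, ifelse(truth$affected, 0.4, 0))
  occ3 <- simulate_occupancy(
    occupancy_spec(20, anticipation_effect = 0.4, clock_on = FALSE,
                   affected_fraction = 0.5, noise_sd = 0, seed = 6), cfg)
  expect_true(all(abs(occ3$data$value - occ3$spec$base_mean) < 1e-12))
})

test_that("a planted-null dataset yields uniform cosinor p-values", {
  data <- make_null_timecourse(10000, seed = 42)
  fit <- cosinor_fit(data)
  ks <- stats::ks.test(fit$p_value, "punif")
  # KS statistic below the 1% critical value (~1.63 / sqrt(n))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(10000))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(-1), "n_features")
  expect_error(sim_config(5, noise_sd = -0.1), "noise_sd")
  expect_error(sim_config(5, timepoints_h = c(4, 2)), "timepoints_h")
  expect_error(sim_config(5, timepoints_h = c(2, 26)), "timepoints_h")
  expect_error(condition_spec("x", rhythmic_fraction = 1.2), "rhythmic_fraction")
  expect_error(condition_spec("x", amplitude_damping = -1), "amplitude_damping")
  expect_error(occupancy_spec(10, affected_fraction = 2), "affected_fraction")
  expect_error(occupancy_spec(10, noise_sd = -1), "noise_sd")
})
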