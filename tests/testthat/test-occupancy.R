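occ_design <- sim_config(0, replicates_per_timepoint = 1, n_days = 2)

test_that("condition and timepoint means reduce correctly", {
  occ <- simulate_occupancy(
    occupancy_spec(10, base_mean = 1, condition_offset = 0.3, noise_sd = 0,
                   affected_fraction = 0, seed = 1), occ_design)
  cm <- condition_means(occ$data)
  expect_equal(cm$mean_score, rep(1.3, 10))
  expect_equal(cm$n_samples, rep(12L, 10))
  tm <- timepoint_means(occ$data)
  expect_equal(tm$mean_score, rep(1.3, 60))
  expect_equal(tm$n_reps, rep(2L, 60))  # two days pooled per ZT
  expect_false(any(tm$incomplete))
  # mean of timepoint means equals the grand mean in a balanced design
  grand <- tm |>
    dplyr::group_by(feature_id) |>
    dplyr::summarise(m = mean(mean_score))
  expect_equal(grand$m, cm$mean_score)
})

test_that("missing replicates are averaged over what remains and flagged", {
  occ <- simulate_occupancy(
    occupancy_spec(3, noise_sd = 0, affected_fraction = 0, seed = 1),
    occ_design)
  drop_one <- dplyr::filter(occ$data, !(zt == 2 & day == 2))
  tm <- timepoint_means(drop_one)
  at2 <- dplyr::filter(tm, zt == 2)
  expect_equal(at2$n_reps, rep(1L, 3))
  expect_true(all(at2$incomplete))
  expect_false(any(tm$incomplete[tm$zt != 2]))
})

test_that("with zero prior df the moderated t is the classical pooled t", {
  occ <- simulate_occupancy(
    occupancy_spec(10, night_effect = 0.5, affected_fraction = 0.5,
                   noise_sd = 0.3, seed = 7), occ_design)
  night <- is_night_samples <- unique(
    occ$data$sample_id[occ$data$zt >= 12])
  day <- setdiff(unique(occ$data$sample_id), night)
  res <- moderated_group_test(occ$data, day, night, prior_df = 0)
  mats <- tidyr::pivot_wider(
    dplyr::select(occ$data, feature_id, sample_id, value),
    names_from = sample_id, values_from = value)
  for (i in seq_len(nrow(res))) {
    ya <- as.numeric(mats[i, day]); yb <- as.numeric(mats[i, night])
    expect_equal(res$t[i], oracle_pooled_t(ya, yb), tolerance = 1e-10)
  }
  expect_equal(attr(res, "d0"), 0)
})

test_that("moderated statistics agree with limma's empirical Bayes", {
  skip_if_not_installed("limma")
  occ <- simulate_occupancy(
    occupancy_spec(200, night_effect = 0.4, affected_fraction = 0.2,
                   noise_sd = 0.25, seed = 3), occ_design)
  night <- unique(occ$data$sample_id[occ$data$zt >= 12])
  day <- setdiff(unique(occ$data$sample_id), night)
  res <- moderated_group_test(occ$data, day, night)
  mats <- tidyr::pivot_wider(
    dplyr::select(occ$data, feature_id, sample_id, value),
    names_from = sample_id, values_from = value)
  Y <- as.matrix(mats[, -1]); rownames(Y) <- mats$feature_id
  design <- cbind(1, as.numeric(colnames(Y) %in% night))
  eb <- limma::eBayes(limma::lmFit(Y, design))
  # limma estimates the same prior by a slightly different fit; statistics
  # should agree closely but not to machine precision
  expect_equal(res$t, unname(eb$t[, 2]), tolerance = 1e-6)
  expect_equal(res$p_value, unname(eb$p.value[, 2]), tolerance = 1e-5)
  expect_equal(attr(res, "d0"), eb$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s02"), eb$s2.prior, tolerance = 1e-6)
})

test_that("shrinkage keeps the posterior variance between sample and prior", {
  occ <- simulate_occupancy(
    occupancy_spec(300, noise_sd = 0.3, affected_fraction = 0, seed = 9),
    occ_design)
  night <- unique(occ$data$sample_id[occ$data$zt >= 12])
  day <- setdiff(unique(occ$data$sample_id), night)
  res <- moderated_group_test(occ$data, day, night)
  s02 <- attr(res, "s02")
  lo <- pmin(res$s2, s02); hi <- pmax(res$s2, s02)
  expect_true(all(res$s2_post >= lo - 1e-12 & res$s2_post <= hi + 1e-12))
})

test_that("identical groups give M = 0, t = 0, p = 1", {
  data <- tidyr::expand_grid(feature_id = c("l1", "l2"),
                             sample_id = sprintf("s%d", 1:4)) |>
    dplyr::mutate(value = rep(c(1.2, 3.4), each = 4),
                  condition = "c", zt = rep(c(2, 6, 14, 18), 2),
                  day = 1L, replicate = 1L)
  res <- moderated_group_test(data, c("s1", "s2"), c("s3", "s4"),
                              prior_df = 0)
  expect_equal(res$M, c(0, 0))
  expect_equal(res$t, c(0, 0))
  expect_equal(res$p_value, c(1, 1))
})

test_that("day/night comparison computes MVA coordinates and antisymmetry", {
  # day scores 1, night scores 2 for every locus
  occ <- simulate_occupancy(
    occupancy_spec(5, base_mean = 1, night_effect = 1, affected_fraction = 1,
                   noise_sd = 0, seed = 2), occ_design)
  res <- day_night_compare(occ$data)
  expect_equal(res$mean_day, rep(1, 5))
  expect_equal(res$mean_night, rep(2, 5))
  expect_equal(res$M, rep(1, 5))
  expect_equal(res$A, rep(1.5, 5))
  # M and A invert exactly to the two means
  expect_equal(res$A + res$M / 2, res$mean_night)
  expect_equal(res$A - res$M / 2, res$mean_day)
  # swapping the labels negates M and leaves A unchanged
  swapped <- dplyr::mutate(occ$data, zt = (zt + 12) %% 24)
  res2 <- day_night_compare(swapped)
  expect_equal(res2$M, -res$M)
  expect_equal(res2$A, res$A)
})

test_that("day/night test is calibrated under the null", {
  occ <- simulate_occupancy(
    occupancy_spec(2000, noise_sd = 0.2, affected_fraction = 0, seed = 23),
    occ_design)
  res <- day_night_compare(occ$data)
  fp <- mean(res$p_value < 0.05)
  band <- 2.58 * sqrt(0.05 * 0.95 / 2000)
  expect_gt(fp, 0.05 - band)
  expect_lt(fp, 0.05 + band)
})

test_that("planted night effects are detected with high sensitivity", {
  cfg <- sim_config(0, replicates_per_timepoint = 1, n_days = 2)
  occ <- simulate_occupancy(
    occupancy_spec(500, night_effect = 0.5, affected_fraction = 0.1,
                   noise_sd = 0.2, seed = 11), cfg)
  res <- day_night_compare(occ$data)
  truth <- occ$truth$affected[match(res$feature_id, occ$truth$feature_id)]
  sens <- mean(res$significant[truth])
  fpr <- mean(res$significant[!truth])
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.07)
})

test_that("timepoint-pair comparison recovers a noiseless anticipation effect", {
  occ <- simulate_occupancy(
    occupancy_spec(50, anticipation_effect = 0.4, clock_on = TRUE,
                   affected_fraction = 0.3, noise_sd = 0, seed = 3),
    occ_design)
  res <- timepoint_pair_compare(occ$data, 2, 10)
  truth <- occ$truth$affected[match(res$feature_id, occ$truth$feature_id)]
  expect_equal(res$M, ifelse(truth, 0.4, 0))
  # identical scores at both ZTs -> M = 0
  expect_equal(res$M[!truth], rep(0, sum(!truth)))
})

test_that("without a clock there is no ZT10 - ZT02 excess", {
  occ <- simulate_occupancy(
    occupancy_spec(400, anticipation_effect = 0.4, clock_on = FALSE,
                   night_effect = 0.5, affected_fraction = 0.2,
                   noise_sd = 0.2, seed = 8), occ_design)
  res <- timepoint_pair_compare(occ$data, 2, 10)
  pos_rate <- mean(res$significant & res$M > 0)
  expect_lte(pos_rate, 0.05)  # no excess over the null rate
})

test_that("group validation rejects undersized or overlapping groups", {
  occ <- simulate_occupancy(occupancy_spec(5, seed = 1), occ_design)
  ids <- unique(occ$data$sample_id)
  expect_error(moderated_group_test(occ$data, ids[1], ids[2:3]), ">= 2")
  expect_error(moderated_group_test(occ$data, ids[1:2], ids[2:3]), "share")
  expect_error(moderated_group_test(occ$data, c("nope", "nah"), ids[1:2]),
               "not in")
})

test_that("cosine-fit fraction saturates for strong rhythms and errors when empty", {
  cfg <- sim_config(
    60, noise_sd = 0.1, seed = 14,
    conditions = list(condition_spec("control", rhythmic_fraction = 1,
                                     amplitude_range = c(1, 1))))
  sim <- simulate_expression(cfg)
  frac <- cosine_fit_fraction(sim$data, p_threshold = 0.05)
  expect_gte(frac$fraction, 0.95)
  null_data <- make_null_timecourse(400, seed = 15, noise_sd = 0.2)
  frac0 <- cosine_fit_fraction(null_data, p_threshold = 0.05)
  expect_lt(abs(frac0$fraction - 0.05), 0.03)
  expect_error(cosine_fit_fraction(dplyr::filter(sim$data, FALSE)), "[Ee]mpty")
})
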