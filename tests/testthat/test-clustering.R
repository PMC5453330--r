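test_that("PAM separates well-separated pairs with member medoids", {
  x <- c(0, 0.1, 10, 10.1)
  m <- pam_kmedoids(dist(x), k = 2)
  expect_equal(m$assignment[1], m$assignment[2])
  expect_equal(m$assignment[3], m$assignment[4])
  expect_false(m$assignment[1] == m$assignment[3])
  # each medoid belongs to the cluster it represents
  expect_equal(m$assignment[m$medoids], c(1L, 2L))
})

test_that("SWAP-converged objective equals exhaustive search on small instances", {
  withr::with_seed(42, {
    for (i in 1:15) {
      n <- sample(5:8, 1)
      k <- sample(2:3, 1)
      pts <- matrix(rnorm(n * 2), ncol = 2)
      D <- as.matrix(dist(pts))
      m <- pam_kmedoids(D, k)
      expect_equal(m$objective, oracle_pam_objective(D, k), tolerance = 1e-12)
    }
  })
})

test_that("duplicated points leave the objective invariant (tie handling)", {
  x <- c(0, 0, 0, 5, 5, 5)
  m <- pam_kmedoids(dist(x), k = 2)
  expect_equal(m$objective, 0)
  expect_equal(sort(unique(m$assignment)), c(1L, 2L))
})

test_that("PAM agrees with an independent implementation on random data", {
  skip_if_not_installed("cluster")
  withr::with_seed(13, {
    for (i in 1:5) {
      pts <- matrix(rnorm(40), ncol = 2)
      D <- as.matrix(dist(pts))
      ours <- pam_kmedoids(D, 3)
      ref <- cluster::pam(as.dist(D), 3)
      # the multistart search is never worse than the single-start reference
      ref_obj <- sum(apply(D[, ref$id.med, drop = FALSE], 1, min))
      expect_lte(ours$objective, ref_obj + 1e-10)
      # and the classic single BUILD start follows the same descent family
      classic <- pam_kmedoids(D, 3, n_starts = 1)
      expect_gte(classic$objective, ours$objective - 1e-10)
    }
  })
})

test_that("PAM validates its inputs", {
  D <- as.matrix(dist(1:5))
  expect_error(pam_kmedoids(D, 5), "k")
  expect_error(pam_kmedoids(D, 1), "k")
  bad <- D; bad[1, 2] <- 99
  expect_error(pam_kmedoids(bad, 2), "symmetric")
  neg <- D; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(pam_kmedoids(neg, 2), "non-negative")
})

test_that("silhouette widths match the per-point definition and cluster::silhouette", {
  withr::with_seed(4, {
    pts <- c(rnorm(3, 0, 0.3), rnorm(3, 4, 0.3))
    D <- as.matrix(dist(pts))
    assign <- c(1L, 1L, 1L, 2L, 2L, 2L)
    s <- silhouette_widths(D, assign)
    expect_equal(s, oracle_silhouette(D, assign), tolerance = 1e-12)
    expect_true(all(s >= -1 & s <= 1))
    if (requireNamespace("cluster", quietly = TRUE)) {
      ref <- cluster::silhouette(assign, dmatrix = D)
      expect_equal(s, as.numeric(ref[, "sil_width"]), tolerance = 1e-12)
    }
  })
})

test_that("profile_matrix averages replicates per ZT and standardises rows", {
  sim <- simulate_expression(sim_config(
    4, noise_sd = 0, seed = 2,
    conditions = list(condition_spec("control", rhythmic_fraction = 0.5))))
  prof <- profile_matrix(sim$data, standardize = FALSE)
  # noiseless replicates agree, so means equal any single replicate value
  one <- dplyr::filter(sim$data, feature_id == "gene_0001", zt == 2,
                       day == 1, replicate == 1)
  expect_equal(prof$zt2[prof$feature_id == "gene_0001"], one$value)
  # z-scored rows have mean 0, sd 1
  profz <- profile_matrix(sim$data)
  m <- as.matrix(profz[, grep("^zt", names(profz))])
  rhythmic_rows <- !profz$constant
  expect_equal(unname(rowMeans(m)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(m[rhythmic_rows, ], 1, sd)),
               rep(1, sum(rhythmic_rows)), tolerance = 1e-12)
  expect_error(profile_matrix(dplyr::filter(sim$data, zt != 2 |
                                              feature_id != "gene_0001")),
               "every timepoint")
})

test_that("silhouette-selected k recovers three planted phase groups", {
  cfg <- sim_config(
    150, noise_sd = 0.1, seed = 6,
    conditions = list(condition_spec(
      "control", rhythmic_fraction = 1, amplitude_range = c(0.8, 1.2),
      phase_dist = tibble::tibble(phase_h = c(2, 10, 18),
                                  weight = rep(1 / 3, 3), sd = 0.5))))
  sim <- simulate_expression(cfg)
  prof <- profile_matrix(sim$data)
  model <- select_k(prof, k_range = 2:6)
  expect_equal(model$k, 3)
  # clusters correspond to the planted phase groups
  truth_group <- sapply(sim$truth$phase, function(p) {
    which.min(phase_abs_diff(p, c(2, 10, 18)))
  })
  tab <- table(model$assignment, truth_group)
  expect_true(all(apply(tab, 1, function(r) max(r) / sum(r)) == 1))
  # cluster mean profiles peak in three distinct ZT bins
  peaks <- tidy(model) |>
    dplyr::left_join(prof, by = "feature_id") |>
    dplyr::group_by(cluster) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("zt"), mean)) |>
    dplyr::rowwise() |>
    dplyr::mutate(peak = which.max(dplyr::c_across(dplyr::starts_with("zt")))) |>
    dplyr::pull(peak)
  expect_equal(length(unique(peaks)), 3)
})

test_that("k selection prefers the smallest k among ties and validates input", {
  # two well-separated blobs: k = 2 wins over 3..5
  withr::with_seed(11, {
    prof <- tibble::tibble(
      feature_id = sprintf("f%02d", 1:20),
      a = c(rnorm(10, 0, 0.1), rnorm(10, 5, 0.1)),
      b = c(rnorm(10, 0, 0.1), rnorm(10, -5, 0.1)))
  })
  model <- select_k(prof, k_range = 2:5)
  expect_equal(model$k, 2)
  same <- tibble::tibble(feature_id = c("a", "b", "c"),
                         v1 = c(1, 1, 1), v2 = c(2, 2, 2))
  expect_error(select_k(same), "identical")
})

test_that("cluster labels are equivariant under feature relabeling", {
  withr::with_seed(8, {
    prof <- tibble::tibble(
      feature_id = sprintf("f%02d", 1:12),
      a = rnorm(12), b = rnorm(12))
  })
  m1 <- pam_kmedoids(dist(as.matrix(prof[, -1])), 3, ids = prof$feature_id)
  perm <- c(5:12, 1:4)
  prof2 <- prof[perm, ]
  m2 <- pam_kmedoids(dist(as.matrix(prof2[, -1])), 3,
                     ids = prof2$feature_id)
  t1 <- tidy(m1); t2 <- tidy(m2)
  joined <- dplyr::inner_join(t1, t2, by = "feature_id")
  # same partition structure: co-membership is preserved
  pairs <- utils::combn(nrow(joined), 2)
  co1 <- joined$cluster.x[pairs[1, ]] == joined$cluster.x[pairs[2, ]]
  co2 <- joined$cluster.y[pairs[1, ]] == joined$cluster.y[pairs[2, ]]
  expect_equal(co1, co2)
})
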