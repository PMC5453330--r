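# Independent oracles used to check the package's implementations.
# These deliberately use different code paths (generic linear solver,
# exhaustive enumeration, closed forms) from the functions they verify.

# Cosinor coefficients via the normal equations and a generic solver.
oracle_cosinor_coef <- function(times, values, period = 24) {
  X <- cbind(1, cos(2 * pi * times / period), sin(2 * pi * times / period))
  as.numeric(solve(t(X) %*% X, t(X) %*% values))
}

# Exhaustive k-medoids objective: minimum over all medoid subsets.
oracle_pam_objective <- function(D, k) {
  D <- as.matrix(D)
  subsets <- utils::combn(nrow(D), k)
  min(apply(subsets, 2L, function(med) {
    sum(apply(D[, med, drop = FALSE], 1L, min))
  }))
}

# Classical pooled-variance two-sample t statistic (b minus a).
oracle_pooled_t <- function(ya, yb) {
  na <- length(ya); nb <- length(yb)
  s2 <- (sum((ya - mean(ya))^2) + sum((yb - mean(yb))^2)) / (na + nb - 2)
  (mean(yb) - mean(ya)) / sqrt(s2 * (1 / na + 1 / nb))
}

# Direct per-point silhouette from the definition (loops, no matrix algebra).
oracle_silhouette <- function(D, assignment) {
  D <- as.matrix(D)
  vapply(seq_len(nrow(D)), function(i) {
    own <- assignment[i]
    mates <- setdiff(which(assignment == own), i)
    if (length(mates) == 0L) return(0)
    a <- mean(D[i, mates])
    b <- min(vapply(setdiff(unique(assignment), own), function(cl) {
      mean(D[i, assignment == cl])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# Adjusted Rand index between two labelings (Hubert & Arabie closed form).
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab)
  exp_idx <- sum_comb(rowSums(tab)) * sum_comb(colSums(tab)) / choose(n, 2)
  max_idx <- (sum_comb(rowSums(tab)) + sum_comb(colSums(tab))) / 2
  (idx - exp_idx) / (max_idx - exp_idx)
}

# Absolute circular difference between two phases on a 24 h clock.
phase_abs_diff <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

# Balanced single-condition design used throughout the tests:
# 6 ZTs x 2 days x 3 replicates = 36 samples.
make_null_timecourse <- function(n_features, seed = 1, noise_sd = 1,
                                 replicates = 3) {
  sim <- simulate_expression(sim_config(
    n_features,
    conditions = list(condition_spec("control", rhythmic_fraction = 0)),
    replicates_per_timepoint = replicates, noise_sd = noise_sd, seed = seed))
  sim$data
}
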