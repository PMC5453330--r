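# Partitioning around medoids (classic BUILD + SWAP) with silhouette-based
# selection of the number of clusters. The implementation is deterministic:
# all ties (initial medoid, best swap, nearest medoid) break toward the
# lowest index, so repeated runs on the same dissimilarity matrix give
# identical models.

as_diss_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    abort("`d` must be a square dissimilarity matrix or a `dist` object.")
  }
  if (any(d < 0) || any(abs(diag(d)) > 1e-12)) {
    abort("Dissimilarities must be non-negative with a zero diagonal.")
  }
  if (max(abs(d - t(d))) > 1e-8) abort("Dissimilarity matrix must be symmetric.")
  d
}

# Distances to nearest and second-nearest medoid for every point.
nearest_two <- function(D, medoids) {
  Dm <- D[, medoids, drop = FALSE]
  n1 <- max.col(-Dm, ties.method = "first")     # nearest medoid (index into medoids)
  d1 <- Dm[cbind(seq_len(nrow(D)), n1)]
  Dm2 <- Dm
  Dm2[cbind(seq_len(nrow(D)), n1)] <- Inf
  d2 <- if (length(medoids) > 1L) {
    Dm2[cbind(seq_len(nrow(D)), max.col(-Dm2, ties.method = "first"))]
  } else rep(Inf, nrow(D))
  list(which = medoids[n1], d1 = d1, d2 = d2)
}

# One SWAP descent from a given medoid set: repeatedly apply the
# (medoid, non-medoid) exchange that most lowers the total dissimilarity
# until no exchange improves it. Returns the converged medoids.
pam_swap <- function(D, medoids) {
  n <- nrow(D)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    nt <- nearest_two(D, medoids)
    best <- list(delta = -1e-12, m = NA, h = NA)  # strict improvement only
    non_medoids <- setdiff(seq_len(n), medoids)
    for (mi in seq_along(medoids)) {
      m <- medoids[mi]
      owned <- nt$which == m
      cand <- D[, non_medoids, drop = FALSE]
      # points losing medoid m: reassigned to min(second nearest, new medoid)
      delta_owned <- if (any(owned)) {
        colSums(pmin(cand[owned, , drop = FALSE], nt$d2[owned]) -
                  nt$d1[owned])
      } else 0
      # other points: may defect to the new medoid if closer
      delta_other <- if (any(!owned)) {
        colSums(pmin(cand[!owned, , drop = FALSE] - nt$d1[!owned], 0))
      } else 0
      delta <- delta_owned + delta_other
      j <- which.min(delta)
      if (delta[j] < best$delta) {
        best <- list(delta = delta[j], m = mi, h = non_medoids[j])
      }
    }
    if (is.na(best$m)) break
    medoids[best$m] <- best$h
    if (iterations > n * length(medoids) + 100L) break  # safety net
  }
  list(medoids = sort(medoids), iterations = iterations,
       objective = sum(nearest_two(D, sort(medoids))$d1))
}

#' Cluster a dissimilarity matrix around k medoids (PAM)
#'
#' Two-phase partitioning around medoids: BUILD greedily selects k initial
#' medoids (first the point with the smallest total dissimilarity, then the
#' point giving the largest reduction); SWAP repeatedly replaces the
#' (medoid, non-medoid) pair whose exchange most lowers the total
#' dissimilarity, until no swap improves it. The objective never increases
#' across SWAP steps, and all ties break toward the lowest point index.
#'
#' Because SWAP is a local search it can converge to a non-global optimum
#' from an unlucky start; `n_starts > 1` adds seeded random initial medoid
#' sets alongside the deterministic BUILD start, runs SWAP from each, and
#' keeps the best converged solution. The result is deterministic given
#' `seed` (and fully deterministic for `n_starts = 1`, the classic
#' algorithm).
#'
#' @param d Symmetric non-negative dissimilarity matrix (or `dist`).
#' @param k Number of clusters, `2 <= k < n`.
#' @param ids Optional point labels (defaults to rownames or indices).
#' @param n_starts Number of SWAP descents: 1 BUILD start plus
#'   `n_starts - 1` random starts (default 5).
#' @param seed Seed for the random starts (default 1; irrelevant when
#'   `n_starts = 1`).
#'
#' @return An object of class `diurnal_pam`: list with `k`, `medoids`
#'   (indices), `medoid_ids`, `assignment` (cluster index per point),
#'   `silhouette` (per-point width), `mean_silhouette`, `objective` (total
#'   dissimilarity to assigned medoids), `iterations`.
#' @export
#' @examples
#' x <- c(0, 0.1, 10, 10.1)
#' pam_kmedoids(dist(x), k = 2)
pam_kmedoids <- function(d, k, ids = NULL, n_starts = 5, seed = 1L) {
  D <- as_diss_matrix(d)
  n <- nrow(D)
  check_count(k, "k", min = 2L)
  check_count(n_starts, "n_starts", min = 1L)
  if (k >= n) abort(sprintf("`k` must satisfy k < n (k = %d, n = %d).", k, n))
  ids <- ids %||% rownames(D) %||% as.character(seq_len(n))

  # BUILD
  medoids <- which.min(colSums(D))  # lowest index wins ties (which.min)
  while (length(medoids) < k) {
    d1 <- apply(D[, medoids, drop = FALSE], 1L, min)
    # gain of adding candidate c: sum_i max(0, d1_i - D[i, c])
    gain <- colSums(pmax(d1 - D, 0))
    gain[medoids] <- -Inf
    medoids <- c(medoids, which.max(gain))
  }
  starts <- list(medoids)
  if (n_starts > 1L) {
    starts <- c(starts, withr::with_seed(seed, {
      lapply(seq_len(n_starts - 1L), function(i) sort(sample.int(n, k)))
    }))
  }
  runs <- lapply(starts, function(s) pam_swap(D, s))
  objectives <- vapply(runs, `[[`, numeric(1), "objective")
  best_run <- runs[[which.min(objectives)]]
  medoids <- best_run$medoids
  iterations <- best_run$iterations
  nt <- nearest_two(D, medoids)
  assignment <- match(nt$which, medoids)
  sil <- silhouette_widths(D, assignment)
  structure(list(
    k = as.integer(k), medoids = medoids, medoid_ids = ids[medoids],
    assignment = assignment, ids = ids, silhouette = sil,
    mean_silhouette = mean(sil), objective = sum(nt$d1),
    iterations = iterations), class = "diurnal_pam")
}

#' Per-point silhouette widths
#'
#' `s_i = (b_i - a_i) / max(a_i, b_i)` where `a_i` is the mean
#' dissimilarity of point i to the other members of its own cluster and
#' `b_i` the smallest mean dissimilarity to any other cluster. Points in
#' singleton clusters get width 0 by convention.
#'
#' @param d Dissimilarity matrix (or `dist`).
#' @param assignment Integer cluster labels, one per point.
#' @return Numeric vector of widths in \[-1, 1\].
#' @export
silhouette_widths <- function(d, assignment) {
  D <- as_diss_matrix(d)
  n <- nrow(D)
  if (length(assignment) != n) abort("One cluster label per point required.")
  clusters <- sort(unique(assignment))
  if (length(clusters) < 2L) {
    abort("Silhouette requires at least two clusters.")
  }
  sizes <- table(factor(assignment, levels = clusters))
  # n x n_clusters matrix of summed dissimilarity to each cluster
  member <- vapply(clusters, function(cl) as.numeric(assignment == cl),
                   numeric(n))
  sums <- D %*% member
  vapply(seq_len(n), function(i) {
    own <- match(assignment[i], clusters)
    if (sizes[own] == 1L) return(0)
    a <- sums[i, own] / (sizes[own] - 1L)
    b <- min(sums[i, -own] / sizes[-own])
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

#' Temporal profile matrix of a time course
#'
#' Per-feature mean value at each zeitgeber time (replicates and days at the
#' same ZT averaged), optionally z-scored per row. Z-scoring makes the
#' dissimilarity between profiles phase-driven rather than amplitude-driven,
#' which is usually what temporal clustering should interpret. Constant
#' features cannot be standardised; they are set to 0 and flagged.
#'
#' @param data Long time-course tibble (one condition).
#' @param features Optional feature ids to restrict to.
#' @param standardize Z-score each row? (default `TRUE`)
#' @return A tibble: `feature_id`, one column `zt<k>` per timepoint
#'   (ZT-ordered), and `constant`.
#' @export
profile_matrix <- function(data, features = NULL, standardize = TRUE) {
  check_timecourse(data)
  if (!is.null(features)) {
    data <- dplyr::filter(data, .data$feature_id %in% features)
  }
  if (nrow(data) == 0L) abort("No data for the requested features.")
  zts <- sort(unique(data$zt))
  prof <- data |>
    dplyr::group_by(.data$feature_id, .data$zt) |>
    dplyr::summarise(mean_value = mean(.data$value), .groups = "drop")
  n_zt_per_feature <- dplyr::count(prof, .data$feature_id)
  if (any(n_zt_per_feature$n != length(zts))) {
    abort("Every feature must be observed at every timepoint.")
  }
  wide <- tidyr::pivot_wider(prof, names_from = "zt",
                             values_from = "mean_value",
                             names_prefix = "zt", names_sort = TRUE)
  m <- as.matrix(wide[, -1, drop = FALSE])
  constant <- apply(m, 1L, function(r) max(r) - min(r) <= 0)
  if (standardize) {
    mu <- rowMeans(m)
    s <- apply(m, 1L, sd)
    m <- (m - mu) / ifelse(constant, 1, s)
    m[constant, ] <- 0
  }
  out <- dplyr::bind_cols(wide[, 1L], tibble::as_tibble(m))
  out$constant <- constant
  out
}

#' PAM clustering with the number of clusters chosen by silhouette
#'
#' Runs [pam_kmedoids()] for every k in `k_range` on the dissimilarities of
#' the feature profiles and keeps the model with the best mean silhouette
#' width (ties go to the smallest k).
#'
#' @param profiles Profile tibble from [profile_matrix()] (or any data frame
#'   with `feature_id` plus numeric columns).
#' @param k_range Candidate cluster numbers (default 2:10).
#' @param metric Distance metric passed to [stats::dist()]
#'   (default "euclidean").
#' @param n_starts,seed Passed to [pam_kmedoids()].
#' @return The selected `diurnal_pam` model, with a `silhouette_by_k` tibble
#'   (k, mean_silhouette, objective) attached.
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(30, seed = 5,
#'   conditions = list(condition_spec("control", rhythmic_fraction = 1))))
#' prof <- profile_matrix(sim$data)
#' select_k(prof, k_range = 2:4)
select_k <- function(profiles, k_range = 2:10, metric = "euclidean",
                     n_starts = 5, seed = 1L) {
  if (!is.data.frame(profiles) || !"feature_id" %in% names(profiles)) {
    abort("`profiles` must be a data frame with a `feature_id` column.")
  }
  num_cols <- setdiff(
    names(profiles)[vapply(profiles, is.numeric, logical(1))], "constant")
  m <- as.matrix(profiles[, num_cols, drop = FALSE])
  rownames(m) <- profiles$feature_id
  if (nrow(m) < 3L) abort("Need at least 3 features to cluster.")
  if (all(stats::dist(m) == 0)) {
    abort("All profiles identical: silhouette is undefined.")
  }
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2L & k_range < nrow(m)]
  if (length(k_range) == 0L) abort("No valid k in `k_range`.")
  D <- as.matrix(stats::dist(m, method = metric))
  models <- lapply(k_range, function(k) {
    pam_kmedoids(D, k, ids = rownames(m), n_starts = n_starts, seed = seed)
  })
  sil_by_k <- tibble::tibble(
    k = k_range,
    mean_silhouette = vapply(models, `[[`, numeric(1), "mean_silhouette"),
    objective = vapply(models, `[[`, numeric(1), "objective"))
  best <- models[[which.max(sil_by_k$mean_silhouette)]]  # first max = smallest k
  best$silhouette_by_k <- sil_by_k
  best$metric <- metric
  best
}

#' @export
print.diurnal_pam <- function(x, ...) {
  cat(sprintf("<diurnal_pam> k = %d, n = %d, mean silhouette %.3f, objective %.3f\n",
              x$k, length(x$assignment), x$mean_silhouette, x$objective))
  cat("cluster sizes:", paste(tabulate(x$assignment, x$k), collapse = ", "), "\n")
  invisible(x)
}
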