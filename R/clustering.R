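#' Standardize scenario deltas to z-scores
#'
#' Column-wise standardization (mean 0, sample SD 1) of the delta variables.
#' Standardization is required before clustering so that unit differences
#' between variables (degrees C vs percent) do not weight the distance.
#'
#' @param table a [scenario_table()] with >= 2 scenarios, or a numeric matrix.
#' @return numeric matrix of z-scores with scenario keys as row names and
#'   attributes `scaled:center` / `scaled:scale` holding the per-column mean
#'   and sample SD for back-transformation.
#' @export
standardize <- function(table) {
  if (inherits(table, "scenario_table")) {
    X <- as.matrix(as.data.frame(table)[delta_vars(table)])
    rownames(X) <- scenario_keys(table)
  } else {
    X <- as.matrix(table)
  }
  if (nrow(X) < 2L) fail("need >= 2 scenarios to standardize")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    fail("constant variable(s): %s (zero SD, cannot standardize)",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  scale(X)
}

#' Euclidean distance matrix between standardized scenarios
#'
#' @param Z matrix of standardized deltas, one row per scenario.
#' @return symmetric n x n matrix of Euclidean distances with zero diagonal.
#' @export
euclidean_distance_matrix <- function(Z) {
  as.matrix(dist(Z, method = "euclidean"))
}

#' Ward minimum-variance agglomeration tree
#'
#' Hierarchical clustering with Ward's minimum variance criterion: at every
#' step the two groups whose merge least increases the total within-group sum
#' of squares are fused. Operates on plain Euclidean distances (the
#' "ward.D2" form of the Lance-Williams update), so merge heights are
#' non-decreasing.
#'
#' @param D an n x n Euclidean distance matrix or a [stats::dist] object,
#'   n >= 2.
#' @return an [stats::hclust] tree (merge order, heights, labels).
#' @export
ward_tree <- function(D) {
  d <- if (inherits(D, "dist")) D else {
    D <- as.matrix(D)
    if (!isSymmetric(unname(D))) fail("distance matrix must be symmetric")
    as.dist(D)
  }
  if (attr(d, "Size") < 2L) fail("need >= 2 objects to build a merge tree")
  hclust(d, method = "ward.D2")
}

#' Initial k-means seeds from a Ward tree cut
#'
#' Cuts the agglomeration tree into `k` groups and returns the group
#' centroids in standardized space; these are the recommended deterministic
#' initial seeds for the k-means refinement.
#'
#' @param tree an [stats::hclust] tree over the rows of `Z`.
#' @param Z standardized delta matrix.
#' @param k number of groups, in `1..nrow(Z)`.
#' @return k x p matrix of seed centroids.
#' @export
seeds_from_tree <- function(tree, Z, k) {
  n <- nrow(Z)
  if (k < 1L || k > n) fail("k must be in 1..%d, got %s", n, k)
  groups <- cutree(tree, k = k)
  centroids_of(Z, groups, k)
}

centroids_of <- function(Z, assign, k) {
  # all k labels must be occupied (callers guarantee this)
  C <- rowsum(Z, assign, reorder = TRUE) / tabulate(assign, nbins = k)
  rownames(C) <- NULL
  C
}

# squared point-to-centroid distances, n x k
dist2_to_centroids <- function(Z, C, zz = rowSums(Z^2)) {
  outer(zz, rowSums(C^2), "+") - 2 * Z %*% t(C)
}

# One Lloyd descent from centroid matrix C (compiled inner loop). Empty
# clusters are repaired by reassigning the point currently farthest from its
# own centroid (ties -> lowest index; sole cluster members are never moved).
lloyd_run <- function(Z, C, max_iter = 100L) {
  .lloyd_cpp(Z, C, as.integer(max_iter))
}

# relabel clusters by order of first appearance so solutions are canonical
canonical_labels <- function(a, C) {
  new <- match(seq_len(nrow(C)), unique(a))
  list(assignment = new[a], centroids = C[unique(a), , drop = FALSE])
}

#' Restarted k-means refinement from hierarchical seeds
#'
#' Runs Lloyd's algorithm to convergence from the supplied (typically
#' Ward-derived) seeds and from `restarts` additional random initializations
#' (k distinct data rows each), returning the partition with the smallest
#' within-group sum of squares. Empty clusters arising during iteration are
#' repaired so that exactly `k` clusters are always occupied. Randomness is
#' derived from `rng_seed` by counter-based splitting, so the result is
#' reproducible and independent of the caller's RNG state.
#'
#' @param Z standardized delta matrix (n x p).
#' @param seeds k x p matrix of initial centroids.
#' @param restarts number of extra random initializations (default 999).
#' @param rng_seed integer master seed for the random restarts.
#' @param max_iter Lloyd iteration cap per start.
#' @param extra_seeds optional list of additional k x p seed matrices to try
#'   deterministically (used by [rsq_profile()] to warm-start from the
#'   previous k).
#' @return object of class `cluster_solution`: list with `k`, `assignment`
#'   (named integer vector of labels in `1..k`, every label occupied),
#'   `centroids`, `within_ss`, `between_ss`, `total_ss`,
#'   `rsq = between_ss / total_ss` and `restarts_used`.
#' @export
kmeans_refine <- function(Z, seeds, restarts = 999L, rng_seed = 1L,
                          max_iter = 100L, extra_seeds = NULL) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  seeds <- matrix(as.numeric(seeds), ncol = ncol(Z))
  k <- nrow(seeds)
  if (k > n) fail("k (%d) exceeds number of scenarios (%d)", k, n)
  if (restarts < 0L) fail("restarts must be >= 0")

  starts <- c(list(seeds), extra_seeds)
  best <- NULL
  for (S in starts) {
    sol <- lloyd_run(Z, S, max_iter)
    if (is.null(best) || sol$within_ss < best$within_ss) best <- sol
  }
  if (restarts > 0L && k > 1L && k < n) {
    # one RNG save/restore around the whole loop; each restart still gets
    # its own counter-derived seed so results are order-independent
    with_seed(split_seed(rng_seed, 0L), {
      for (r in seq_len(restarts)) {
        set.seed(split_seed(rng_seed, r))
        init <- Z[sample.int(n, k), , drop = FALSE]
        sol <- lloyd_run(Z, init, max_iter)
        if (sol$within_ss < best$within_ss) best <- sol
      }
    })
  }

  cl <- canonical_labels(best$assignment, best$centroids)
  grand <- colMeans(Z)
  total <- sum(sweep(Z, 2, grand)^2)
  within <- best$within_ss
  between <- total - within
  rsq <- if (total > 0) min(max(between / total, 0), 1) else 1
  assignment <- cl$assignment
  names(assignment) <- rownames(Z)
  structure(list(k = k, assignment = assignment, centroids = cl$centroids,
                 within_ss = within, between_ss = between, total_ss = total,
                 rsq = rsq, restarts_used = restarts),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf(
    "k-means solution: k = %d, Rsq = %.4f (within %.3f / total %.3f)\n",
    x$k, x$rsq, x$within_ss, x$total_ss))
  cat("cluster sizes:", paste(tabulate(x$assignment, x$k), collapse = ", "),
      "\n")
  invisible(x)
}

#' Rsq profile over the number of clusters
#'
#' Repeats the Ward-seeded restarted k-means for k = 1..`k_max` and records
#' the Rsq statistic (between-group over total sum of squares, the variance
#' captured by the partition). Each k's starts include the Ward cut seeds,
#' the random restarts and a warm start obtained by splitting the widest
#' cluster of the (k-1) solution, which enforces monotone non-decrease in
#' practice; any residual decrease (a finite-restart artifact) is rectified
#' to the running maximum with a warning.
#'
#' @inheritParams kmeans_refine
#' @param k_max largest k to profile (default n).
#' @param tree optional precomputed [ward_tree()]; built from `Z` otherwise.
#' @return data.frame of class `rsq_profile` with columns `k` and `rsq`;
#'   attribute `solutions` holds the per-k `cluster_solution` objects.
#' @export
rsq_profile <- function(Z, k_max = nrow(Z), restarts = 999L, rng_seed = 1L,
                        tree = NULL) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (k_max > n) fail("k_max (%d) exceeds number of scenarios (%d)", k_max, n)
  if (is.null(tree)) tree <- ward_tree(dist(Z))
  solutions <- vector("list", k_max)
  rsq <- numeric(k_max)
  prev <- NULL
  for (k in seq_len(k_max)) {
    extra <- if (!is.null(prev) && k > 1L) list(split_widest(Z, prev))
    sol <- kmeans_refine(Z, seeds_from_tree(tree, Z, k), restarts = restarts,
                         rng_seed = split_seed(rng_seed, 100000L + k),
                         extra_seeds = extra)
    solutions[[k]] <- sol
    rsq[k] <- sol$rsq
    prev <- sol
  }
  if (any(diff(rsq) < 0)) {
    warning("Rsq profile not monotone despite warm starts; ",
            "rectified to the running maximum", call. = FALSE)
    rsq <- cummax(rsq)
  }
  structure(data.frame(k = seq_len(k_max), rsq = rsq),
            solutions = solutions,
            class = c("rsq_profile", "data.frame"))
}

# seed matrix for k+1 groups: previous centroids plus the point farthest
# from its centroid inside the cluster with the largest within-SS
split_widest <- function(Z, solution) {
  a <- solution$assignment
  C <- solution$centroids
  d2 <- dist2_to_centroids(Z, C)
  own <- d2[cbind(seq_along(a), a)]
  wss_j <- rowsum(own, a)
  widest <- which.max(wss_j)
  cand <- which(a == widest)
  p <- cand[which.max(own[cand])]
  unname(rbind(C, Z[p, ]))
}

#' Choose the number of clusters from an Rsq profile
#'
#' Cost-benefit rule: the chosen k maximizes the net benefit
#' `B(k) = rsq(k) - cost_weight * (k - 1) / (k_max - 1)`, i.e. explained
#' variance minus a linear cost per added cluster; ties go to the smallest
#' k. With the default `cost_weight = 1` both terms run from 0 to 1 over the
#' profile, and the rule stops adding clusters once the marginal variance
#' gained by one more cluster drops below the average per-cluster cost
#' `1 / (k_max - 1)`.
#'
#' @param profile an [rsq_profile()] (or data.frame with `k`, `rsq`).
#' @param cost_weight non-negative cost of moving from k = 1 to k = k_max.
#' @return the selected k (integer).
#' @export
select_k <- function(profile, cost_weight = 1) {
  k <- profile$k
  if (length(k) < 2L) return(k[1L])
  benefit <- profile$rsq - cost_weight * (k - 1) / (max(k) - 1)
  k[which.max(benefit)]
}

#' Representative scenario of each cluster
#'
#' For every cluster, selects the member scenario closest (Euclidean, in
#' standardized space) to the cluster centroid; ties go to the scenario
#' earliest in table order. Cluster sizes `nk_j` and the normalized weights
#' `nk_j / sum(nk)` used by the double-weighted consensus are recorded.
#'
#' @param solution a `cluster_solution` over the rows of `Z`.
#' @param Z standardized delta matrix.
#' @param table the [scenario_table()] the solution was computed from.
#' @return data.frame of class `representative_set` with one row per cluster:
#'   `cluster`, `center`, `model`, `sres`, `key`, `size`, `weight`,
#'   `dist_to_centroid`.
#' @export
select_representatives <- function(solution, Z, table) {
  Z <- as.matrix(Z)
  a <- solution$assignment
  if (length(a) != nrow(Z) || nrow(Z) != nrow(table)) {
    fail("solution, Z and table must describe the same scenarios")
  }
  d2 <- dist2_to_centroids(Z, solution$centroids)
  keys <- scenario_keys(table)
  rows <- lapply(seq_len(solution$k), function(j) {
    members <- which(a == j)
    rep_i <- members[which.min(d2[members, j])]
    data.frame(cluster = j,
               center = table$center[rep_i], model = table$model[rep_i],
               sres = table$sres[rep_i], key = keys[rep_i],
               size = length(members),
               dist_to_centroid = sqrt(max(d2[rep_i, j], 0)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$weight <- out$size / sum(out$size)
  structure(out[c("cluster", "center", "model", "sres", "key", "size",
                  "weight", "dist_to_centroid")],
            class = c("representative_set", "data.frame"))
}

#' Full scenario-selection procedure
#'
#' The complete selection algorithm: standardize the delta table, build the
#' Euclidean distance matrix, grow a Ward minimum-variance tree, refine each
#' tree cut with restarted k-means, profile the Rsq statistic over k, choose
#' k by the cost-benefit rule (or use a fixed k), and pick the scenario
#' nearest each cluster centroid as its representative.
#'
#' @param table a [scenario_table()] with >= 2 scenarios.
#' @param k `"auto"` (cost-benefit selection) or a fixed integer.
#' @param restarts random k-means restarts per k (default 999).
#' @param rng_seed integer master seed.
#' @param k_max largest k profiled under `k = "auto"` (default n).
#' @param cost_weight see [select_k()].
#' @return object of class `scenario_clustering`: list with `table`, `Z`,
#'   `tree`, `profile`, `k`, `solution`, `representatives`.
#' @export
#' @examples
#' sel <- cluster_scenarios(cmip3_deltas_fixture(), restarts = 25, rng_seed = 1)
#' sel$k
#' sel$representatives
cluster_scenarios <- function(table, k = "auto", restarts = 999L,
                              rng_seed = 1L, k_max = nrow(table),
                              cost_weight = 1) {
  table <- scenario_table(table)
  Z <- standardize(table)
  D <- euclidean_distance_matrix(Z)
  tree <- ward_tree(D)
  profile <- rsq_profile(Z, k_max = k_max, restarts = restarts,
                         rng_seed = rng_seed, tree = tree)
  k_sel <- if (identical(k, "auto")) {
    select_k(profile, cost_weight)
  } else {
    k <- as.integer(k)
    if (is.na(k) || k < 1L || k > nrow(Z)) {
      fail("k must be 'auto' or an integer in 1..%d", nrow(Z))
    }
    k
  }
  solution <- if (k_sel <= nrow(profile)) {
    attr(profile, "solutions")[[k_sel]]
  } else {
    kmeans_refine(Z, seeds_from_tree(tree, Z, k_sel), restarts = restarts,
                  rng_seed = split_seed(rng_seed, 100000L + k_sel))
  }
  reps <- select_representatives(solution, Z, table)
  structure(list(table = table, Z = Z, tree = tree, profile = profile,
                 k = k_sel, solution = solution, representatives = reps,
                 restarts = restarts, rng_seed = rng_seed,
                 cost_weight = cost_weight),
            class = "scenario_clustering")
}

#' @export
print.scenario_clustering <- function(x, ...) {
  cat(sprintf("Scenario selection: %d scenarios -> %d representatives\n",
              nrow(x$table), x$k))
  cat(sprintf("Rsq(k = %d) = %.4f (%.0f%% of variance)\n",
              x$k, x$solution$rsq, 100 * x$solution$rsq))
  print(as.data.frame(x$representatives), row.names = FALSE, ...)
  invisible(x)
}
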