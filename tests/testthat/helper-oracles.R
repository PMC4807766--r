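# Brute-force oracles, independent of the implementation paths they check.

# all partitions of 1..n into exactly k non-empty groups, as label vectors
# (restricted growth strings)
all_partitions_k <- function(n, k) {
  res <- list()
  rec <- function(labels, used) {
    i <- length(labels) + 1L
    if (i > n) {
      if (used == k) res[[length(res) + 1L]] <<- labels
      return(invisible())
    }
    if (used + (n - i + 1L) < k) return(invisible())  # cannot reach k groups
    for (j in seq_len(min(used + 1L, k))) rec(c(labels, j), max(used, j))
  }
  rec(integer(0), 0L)
  res
}

partition_within_ss <- function(Z, labels) {
  sum(vapply(unique(labels), function(j) {
    sub <- Z[labels == j, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, numeric(1)))
}

# optimal within-SS over every k-partition (exhaustive; n <= 8)
best_partition_within_ss <- function(Z, k) {
  min(vapply(all_partitions_k(nrow(Z), k), function(lab) {
    partition_within_ss(Z, lab)
  }, numeric(1)))
}

# Ward agglomeration by recomputing the SS increase of every candidate merge
# at every step; returns the merged member sets in order
ward_oracle <- function(Z) {
  wss <- function(idx) {
    sub <- Z[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  clusters <- as.list(seq_len(nrow(Z)))
  merges <- list()
  deltas <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL
    best_d <- Inf
    for (a in seq_len(length(clusters) - 1L)) {
      for (b in (a + 1L):length(clusters)) {
        d <- wss(c(clusters[[a]], clusters[[b]])) -
          wss(clusters[[a]]) - wss(clusters[[b]])
        if (d < best_d - 1e-12) {
          best_d <- d
          best <- c(a, b)
        }
      }
    }
    merged <- sort(c(clusters[[best[1L]]], clusters[[best[2L]]]))
    merges[[length(merges) + 1L]] <- merged
    deltas <- c(deltas, best_d)
    clusters[[best[1L]]] <- merged
    clusters <- clusters[-best[2L]]
  }
  list(merges = merges, delta_ss = deltas)
}

# member sets merged at each step of an hclust tree
hclust_merge_sets <- function(tree) {
  n <- length(tree$order)
  sets <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    members <- function(x) if (x < 0) -x else sets[[x]]
    sets[[s]] <- sort(c(members(tree$merge[s, 1L]),
                        members(tree$merge[s, 2L])))
  }
  sets
}

# O(n^2) pair-counting AUC, ties counted one half
auc_oracle <- function(scores, truth) {
  s1 <- scores[truth == 1]
  s0 <- scores[truth == 0]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# exhaustive maxSSS sweep with explicit loops (p >= t convention,
# smallest maximizer; integer pair-count scoring avoids float ties)
max_sss_oracle <- function(p, y) {
  cand <- sort(unique(p))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  best_t <- NA_real_
  best_sss <- -Inf
  for (t in cand) {
    # sens + spec on a common integer scale: sens*n1*n0 + spec*n0*n1
    score <- sum(p >= t & y == 1) * n0 + sum(p < t & y == 0) * n1
    if (score > best_sss) {
      best_sss <- score
      best_t <- t
    }
  }
  best_t
}

# direct summation of the double-weighted consensus for one cell
double_weight_oracle <- function(x_ij, auc_i, nk_j) {
  total <- 0
  for (i in seq_along(auc_i)) {
    for (j in seq_along(nk_j)) {
      total <- total + x_ij[i, j] * (auc_i[i] / sum(auc_i)) *
        (nk_j[j] / sum(nk_j))
    }
  }
  total
}

# random probability stack for consensus tests
random_stack <- function(n_cells, n_models, n_scen, seed,
                         cluster_size = NULL, scenario_model = NULL,
                         scenario_sres = NULL) {
  set.seed(seed)
  prob <- array(runif(n_cells * n_models * n_scen),
                dim = c(n_cells, n_models, n_scen),
                dimnames = list(paste0("c", seq_len(n_cells)),
                                paste0("m", seq_len(n_models)),
                                paste0("s", seq_len(n_scen))))
  probability_stack(prob, model_auc = runif(n_models, 0.6, 1),
                    cluster_size = cluster_size,
                    scenario_model = scenario_model,
                    scenario_sres = scenario_sres)
}
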