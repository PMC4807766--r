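test_that("standardize produces exact z-scores with stored parameters", {
  tab <- cmip3_deltas_fixture()
  Z <- standardize(tab)
  expect_true(all(abs(colMeans(Z)) < 1e-10))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-10))

  # direct-summation oracle for the first dTavg z-score
  x <- tab$dTavg
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  expect_equal(Z[1, "dTavg"], (5.0 - m) / s, ignore_attr = TRUE)

  # idempotence on already-standardized input
  expect_equal(unclass(standardize(Z)), unclass(Z), tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(standardize(scenario_table(
    data.frame(center = "X", model = c("a", "b"), sres = "A2",
               dTavg = c(1, 2), dPrec = c(3, 3)))),
    "constant.*dPrec")
  expect_error(standardize(tab[1, , drop = FALSE]), ">= 2 scenarios")
})

test_that("euclidean_distance_matrix matches a per-pair loop oracle", {
  expect_equal(euclidean_distance_matrix(rbind(c(0, 0), c(3, 4)))[1, 2], 5)
  expect_equal(euclidean_distance_matrix(rbind(c(1, 2), c(1, 2)))[1, 2], 0)

  set.seed(11)
  Z <- matrix(rnorm(15), 5, 3)
  D <- euclidean_distance_matrix(Z)
  for (a in 1:5) for (b in 1:5) {
    expect_equal(D[a, b], sqrt(sum((Z[a, ] - Z[b, ])^2)))
  }
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 5))
})

test_that("ward_tree reproduces the recompute-SS agglomeration oracle", {
  # forced cases
  Z2 <- matrix(c(0, 1), ncol = 1)
  t2 <- ward_tree(euclidean_distance_matrix(Z2))
  expect_equal(nrow(t2$merge), 1L)

  Z4 <- matrix(c(0, 1, 10, 11), ncol = 1)
  t4 <- ward_tree(euclidean_distance_matrix(Z4))
  first_two <- hclust_merge_sets(t4)[1:2]
  expect_setequal(lapply(first_two, paste, collapse = ","), c("1,2", "3,4"))

  # random cases vs brute force; ward.D2 heights^2 / 2 = SS increase
  for (seed in 1:5) {
    set.seed(seed)
    Z <- matrix(rnorm(12), 6, 2)
    tree <- ward_tree(euclidean_distance_matrix(Z))
    oracle <- ward_oracle(Z)
    expect_equal(hclust_merge_sets(tree), oracle$merges)
    expect_equal(tree$height^2 / 2, oracle$delta_ss, tolerance = 1e-8)
    expect_true(all(diff(tree$height) >= -1e-10))
  }
  expect_error(ward_tree(matrix(0, 1, 1)), ">= 2 objects")
})

test_that("seeds_from_tree returns tree-cut centroids", {
  set.seed(3)
  Z <- matrix(rnorm(20), 10, 2)
  tree <- ward_tree(euclidean_distance_matrix(Z))
  expect_equal(sort(seeds_from_tree(tree, Z, 10)[, 1]), sort(Z[, 1]))
  expect_equal(as.vector(seeds_from_tree(tree, Z, 1)), colMeans(Z))

  Z4 <- matrix(c(0, 1, 10, 11), ncol = 1)
  t4 <- ward_tree(euclidean_distance_matrix(Z4))
  expect_equal(sort(as.vector(seeds_from_tree(t4, Z4, 2))), c(0.5, 10.5))
  expect_error(seeds_from_tree(tree, Z, 11), "k must be in")
})

test_that("kmeans_refine finds the exhaustive-partition optimum (n <= 8)", {
  for (case in list(c(n = 5, k = 2, seed = 1), c(n = 6, k = 3, seed = 2),
                    c(n = 7, k = 3, seed = 3), c(n = 8, k = 4, seed = 4))) {
    set.seed(case[["seed"]])
    Z <- matrix(rnorm(case[["n"]] * 2), case[["n"]], 2)
    tree <- ward_tree(euclidean_distance_matrix(Z))
    sol <- kmeans_refine(Z, seeds_from_tree(tree, Z, case[["k"]]),
                         restarts = 200, rng_seed = 9)
    expect_equal(sol$within_ss, best_partition_within_ss(Z, case[["k"]]),
                 tolerance = 1e-8)
  }
})

test_that("kmeans solutions satisfy their structural invariants", {
  set.seed(21)
  Z <- matrix(rnorm(40), 20, 2)
  tree <- ward_tree(euclidean_distance_matrix(Z))
  for (k in c(1, 3, 7, 20)) {
    sol <- kmeans_refine(Z, seeds_from_tree(tree, Z, k), restarts = 30,
                         rng_seed = 5)
    expect_setequal(unique(sol$assignment), seq_len(k))  # every label occupied
    expect_lt(abs(sol$within_ss + sol$between_ss - sol$total_ss) /
                sol$total_ss, 1e-8)
    expect_gte(sol$rsq, 0)
    expect_lte(sol$rsq, 1)
    # Lloyd fixed point: each object nearest its own centroid
    d2 <- outer(rowSums(Z^2), rowSums(sol$centroids^2), "+") -
      2 * Z %*% t(sol$centroids)
    expect_equal(max.col(-d2, ties.method = "first"),
                 unname(sol$assignment))
    # restarts never hurt the hierarchical-seed solution
    seed_only <- kmeans_refine(Z, seeds_from_tree(tree, Z, k), restarts = 0)
    expect_lte(sol$within_ss, seed_only$within_ss + 1e-12)
  }
})

test_that("kmeans_refine is deterministic, honours fixed points, repairs empties", {
  set.seed(2)
  Z <- matrix(rnorm(30), 15, 2)
  s1 <- kmeans_refine(Z, Z[1:4, ], restarts = 50, rng_seed = 42)
  s2 <- kmeans_refine(Z, Z[1:4, ], restarts = 50, rng_seed = 42)
  expect_identical(s1, s2)

  # a Lloyd fixed point with restarts = 0 is returned unchanged
  fixed <- kmeans_refine(Z, s1$centroids, restarts = 0)
  expect_equal(fixed$assignment, s1$assignment)
  expect_equal(fixed$within_ss, s1$within_ss)

  # seeds engineered to leave clusters empty still yield k occupied labels
  Zsep <- rbind(matrix(rnorm(10, 0), 5, 2), matrix(rnorm(10, 50), 5, 2))
  bad_seeds <- rbind(c(0, 0), c(0.1, 0.1), c(0.2, 0.2))
  sol <- kmeans_refine(Zsep, bad_seeds, restarts = 0)
  expect_setequal(unique(sol$assignment), 1:3)
  expect_error(kmeans_refine(Z, matrix(0, 16, 2)), "exceeds")
})

test_that("rsq_profile hits definitional limits and exhaustive optima", {
  set.seed(8)
  Z <- matrix(rnorm(10), 5, 2)
  prof <- rsq_profile(Z, restarts = 100, rng_seed = 3)
  expect_equal(prof$rsq[1], 0)
  expect_equal(prof$rsq[5], 1)
  expect_true(all(diff(prof$rsq) >= 0))
  total <- sum(sweep(Z, 2, colMeans(Z))^2)
  for (k in 2:4) {
    expect_equal(prof$rsq[k], 1 - best_partition_within_ss(Z, k) / total,
                 tolerance = 1e-8)
  }
})

test_that("select_k implements the net-benefit knee rule", {
  # rising-then-flat profile: knee at the start of the flat segment
  prof <- data.frame(k = 1:10,
                     rsq = c(0, .5, .8, .95, .95, .95, .95, .95, .95, .95))
  expect_equal(select_k(prof, cost_weight = 1), 4)
  # perfectly linear profile: k = 1 iff cost_weight >= slope (ties smallest)
  lin <- data.frame(k = 1:10, rsq = (0:9) / 9)
  expect_equal(select_k(lin, cost_weight = 1), 1)
  expect_equal(select_k(lin, cost_weight = 1.5), 1)
  expect_equal(select_k(lin, cost_weight = 0.5), 10)
})

test_that("select_representatives picks nearest members with table-order ties", {
  tab <- scenario_table(data.frame(
    center = "X", model = paste0("m", 1:4), sres = "A2",
    dTavg = c(-1, 1, -1, 1), dPrec = c(0, 0, 0, 0), dPrat = c(1, 1, -1, -1)))
  Z <- as.matrix(as.data.frame(tab)[delta_vars(tab)])
  rownames(Z) <- paste0("m", 1:4, ":A2")
  # centroid at origin: all four equidistant -> earliest row wins
  sol <- structure(list(k = 1L, assignment = stats::setNames(rep(1L, 4),
                                                             rownames(Z)),
                        centroids = matrix(0, 1, 3)),
                   class = "cluster_solution")
  reps <- select_representatives(sol, Z, tab)
  expect_equal(reps$key, "m1:A2")
  expect_equal(reps$size, 4L)
  expect_equal(reps$weight, 1)

  # random table, k = 3: per-cluster linear scan oracle; singletons forced
  set.seed(13)
  tab10 <- scenario_table(data.frame(
    center = "X", model = paste0("m", 1:10), sres = "A2",
    dTavg = rnorm(10), dPrec = rnorm(10), dPrat = rnorm(10)))
  Z10 <- standardize(tab10)
  sol10 <- kmeans_refine(Z10, seeds_from_tree(
    ward_tree(euclidean_distance_matrix(Z10)), Z10, 3), restarts = 50,
    rng_seed = 2)
  reps10 <- select_representatives(sol10, Z10, tab10)
  expect_equal(sum(reps10$size), 10L)
  expect_equal(sum(reps10$weight), 1)
  for (j in 1:3) {
    members <- which(sol10$assignment == j)
    d <- apply(Z10[members, , drop = FALSE], 1, function(z) {
      sqrt(sum((z - sol10$centroids[j, ])^2))
    })
    expect_equal(reps10$key[j], names(which.min(d)))
    expect_true(reps10$key[j] %in% rownames(Z10)[members])
  }
})

test_that("cluster_scenarios is reproducible bit-for-bit given its seed", {
  tab <- cmip3_deltas_fixture()
  a <- cluster_scenarios(tab, restarts = 40, rng_seed = 77)
  b <- cluster_scenarios(tab, restarts = 40, rng_seed = 77)
  expect_identical(a$solution, b$solution)
  expect_identical(a$representatives, b$representatives)
  expect_identical(a$profile$rsq, b$profile$rsq)

  fixed <- cluster_scenarios(tab, k = 4, restarts = 20, rng_seed = 1)
  expect_equal(fixed$k, 4L)
  expect_error(cluster_scenarios(tab, k = 99, restarts = 5), "k must be")
})
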