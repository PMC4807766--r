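test_that("AUC-weighted consensus matches direct summation", {
  # 3 models with AUCs 0.6/0.8/1.0 and probabilities 0/0.5/1 in one cell
  prob <- array(c(0, 0.5, 1), dim = c(1, 3, 1))
  stack <- probability_stack(prob, model_auc = c(0.6, 0.8, 1.0))
  expect_equal(consensus_auc_weighted(stack)$prob,
               (0 * 0.6 + 0.5 * 0.8 + 1 * 1.0) / 2.4)

  # equal AUCs cancel to the plain mean; single model/scenario is identity
  s <- random_stack(20, 4, 3, seed = 1)
  s$model_auc <- rep(0.9, 4)
  expect_equal(consensus_auc_weighted(s)$prob,
               unname(apply(s$prob, 1, mean)))
  one <- probability_stack(array(runif(7), c(7, 1, 1)), model_auc = 0.8)
  expect_equal(consensus_auc_weighted(one)$prob, as.vector(one$prob))

  bad <- random_stack(3, 2, 2, seed = 2)
  bad$model_auc <- c(0.8, 0)
  expect_error(consensus_auc_weighted(bad), "AUC weights must be > 0")
})

test_that("double-weighted consensus matches the explicit summation oracle", {
  # 2 models (AUC 0.8, 0.9) x 2 clusters (nk 2, 4): 4-term hand summation
  x <- matrix(c(0.2, 0.7, 0.4, 0.9), 2, 2)  # x[i, j]
  prob <- array(x, dim = c(1, 2, 2),
                dimnames = list("c1", c("m1", "m2"), c("s1", "s2")))
  stack <- probability_stack(prob, model_auc = c(0.8, 0.9),
                             cluster_size = c(2, 4))
  expect_equal(consensus_double_weighted(stack)$prob,
               double_weight_oracle(x, c(0.8, 0.9), c(2, 4)))

  # uniform weights collapse to the arithmetic mean
  s <- random_stack(15, 3, 4, seed = 3, cluster_size = rep(2, 4))
  s$model_auc <- rep(0.85, 3)
  expect_equal(consensus_double_weighted(s)$prob, unname(apply(s$prob, 1, mean)))

  # all weight on one scenario with one model reproduces that scenario's map
  s1 <- random_stack(10, 1, 1, seed = 4, cluster_size = 27)
  expect_equal(consensus_double_weighted(s1)$prob, as.vector(s1$prob))

  # scenario without an nk_j is an error
  expect_error(consensus_double_weighted(random_stack(5, 2, 3, seed = 5)),
               "cluster size nk_j")
})

test_that("double-weighted consensus is permutation-invariant in both indices and convex", {
  s <- random_stack(25, 4, 5, seed = 6, cluster_size = c(1, 3, 2, 5, 4))
  base <- consensus_double_weighted(s)$prob
  pi_m <- sample(4)
  pi_s <- sample(5)
  perm <- probability_stack(s$prob[, pi_m, pi_s],
                            model_auc = s$model_auc[pi_m],
                            cluster_size = s$cluster_size[pi_s])
  expect_equal(consensus_double_weighted(perm)$prob, base)
  # consensual probability stays inside the per-cell envelope
  expect_true(all(base >= apply(s$prob, 1, min) - 1e-12))
  expect_true(all(base <= apply(s$prob, 1, max) + 1e-12))
})

test_that("degenerate-homogeneity: double-weighted over representatives equals full AUC consensus", {
  # 27 scenarios in 6 clusters; every member's map equals its representative's
  set.seed(7)
  sizes <- c(2, 3, 3, 5, 6, 8)
  n_cells <- 30
  n_models <- 4
  rep_maps <- array(runif(n_cells * n_models * 6),
                    dim = c(n_cells, n_models, 6),
                    dimnames = list(NULL, NULL, paste0("r", 1:6)))
  full <- rep_maps[, , rep(1:6, times = sizes)]
  aucs <- runif(n_models, 0.7, 1)
  stack_full <- probability_stack(full, model_auc = aucs)
  stack_reps <- probability_stack(rep_maps, model_auc = aucs,
                                  cluster_size = sizes)
  expect_equal(consensus_double_weighted(stack_reps)$prob,
               consensus_auc_weighted(stack_full)$prob,
               tolerance = 1e-14)
})

test_that("maxSSS threshold equals the brute-force sweep", {
  # perfect separation: smallest maximizer = lowest presence probability
  p <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_equal(max_sss_threshold(p, y), 0.7)
  expect_equal(max_sss_threshold(p, y), max_sss_oracle(p, y))

  set.seed(8)
  for (i in 1:200) {
    n <- sample(5:25, 1)
    p <- round(runif(n), 2)  # duplicates make candidate ties likely
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(max_sss_threshold(p, y), max_sss_oracle(p, y))
  }
  expect_error(max_sss_threshold(p, rep(1, length(p))), "both classes")
})

test_that("binarize uses the presence-inclusive convention and is idempotent", {
  cons <- structure(data.frame(cell_id = paste0("c", 1:4),
                               prob = c(0, 0.4, 0.5, 1)),
                    class = c("consensus_map", "data.frame"))
  b0 <- binarize(cons, 0)
  expect_equal(b0$binary, rep(1L, 4))
  b_hi <- binarize(cons, 1)
  expect_equal(b_hi$binary, c(0L, 0L, 0L, 1L))  # p >= t inclusive at the top
  b <- binarize(cons, 0.5)
  expect_equal(b$binary, c(0L, 0L, 1L, 1L))
  expect_equal(binarize(b, 0.5)$binary, b$binary)
  expect_equal(attr(b, "threshold"), 0.5)
  expect_error(binarize(cons, 1.5), "\\[0, 1\\]")
})

test_that("range_change computes gains/losses over the reference presences", {
  expect_equal(range_change(c(1, 1, 0, 0), c(1, 1, 0, 0))$gains_pct, 0)
  expect_equal(range_change(c(1, 1, 0, 0), c(1, 1, 0, 0))$losses_pct, 0)

  # ref {A,B}, future {C,D,E}: gains 150%, losses 100%
  rc <- range_change(c(1, 1, 0, 0, 0), c(0, 0, 1, 1, 1))
  expect_equal(rc$gains_pct, 150)
  expect_equal(rc$losses_pct, 100)

  set.seed(9)
  r <- rbinom(50, 1, 0.4)
  r[1] <- 1
  f <- rbinom(50, 1, 0.4)
  rc2 <- range_change(r, f)
  expect_equal(rc2$gains_pct, 100 * length(intersect(which(r == 0),
                                                     which(f == 1))) / sum(r))
  expect_equal(rc2$losses_pct, 100 * length(intersect(which(r == 1),
                                                      which(f == 0))) / sum(r))
  expect_error(range_change(rep(0, 5), rep(1, 5)), "no reference-period")
})

test_that("difference_map categories partition the cell set", {
  a <- c(1, 1, 0, 0)
  expect_equal(as.character(difference_map(a, a)$category),
               c("agree_presence", "agree_presence",
                 "agree_absence", "agree_absence"))
  d <- difference_map(a, 1 - a)
  expect_setequal(as.character(d$category), c("only_in_a", "only_in_b"))
  set.seed(10)
  x <- rbinom(40, 1, 0.5)
  y <- rbinom(40, 1, 0.5)
  expect_equal(sum(table(difference_map(x, y)$category)), 40)
})
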