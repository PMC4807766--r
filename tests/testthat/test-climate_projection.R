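baseline_toy <- function(n = 5) {
  data.frame(cell_id = paste0("c", seq_len(n)),
             tavg = seq(5, 9, length.out = n),
             prec = seq(1000, 1200, length.out = n),
             prat = seq(0.3, 0.4, length.out = n),
             stringsAsFactors = FALSE)
}

test_that("apply_change_field follows the delta arithmetic per variable", {
  b <- baseline_toy()
  zero <- apply_change_field(b, list(dTavg = 0, dPrec = 0, dPrat = 0))
  expect_equal(zero$tavg, b$tavg)
  expect_equal(zero$prec, b$prec)
  expect_equal(zero$prat, b$prat)

  # the warmest printed scenario row: +5.0 degrees, +18.2% precipitation
  tab <- cmip3_deltas_fixture()
  row <- tab[tab$model == "CGCM3.1 (T47)" & tab$sres == "A2", ]
  out <- apply_change_field(
    data.frame(cell_id = "c1", tavg = 5.0, prec = 1000, prat = 0.35), row)
  expect_equal(out$tavg, 10.0)
  expect_equal(out$prec, 1182)
  expect_equal(out$prat, 0.35 * (1 - 4.2 / 100))
  expect_equal(attr(out, "period"), "CGCM3.1 (T47):A2")
})

test_that("ratio clipping is applied, counted and warned about", {
  b <- data.frame(cell_id = c("c1", "c2"), tavg = 5, prec = 100,
                  prat = c(0.99, 0.5))
  expect_warning(out <- apply_change_field(
    b, list(dTavg = 0, dPrec = 0, dPrat = 3)), "clipped 1")
  expect_equal(out$prat, c(1.0, 0.5 * 1.03))
  expect_equal(attr(out, "n_clipped"), 1L)

  expect_error(apply_change_field(
    b, list(dTavg = 0, dPrec = -150, dPrat = 0)), "negative projected")
  expect_error(apply_change_field(b, list(dTavg = 1)), "missing: dPrec, dPrat")
})

test_that("change field accepts per-cell delta grids and commutes with subsetting", {
  b <- baseline_toy(6)
  dT <- seq(1, 2, length.out = 6)
  out <- apply_change_field(b, list(dTavg = dT, dPrec = 10, dPrat = 0))
  expect_equal(out$tavg, b$tavg + dT)

  sub <- c(2, 4, 5)
  whole_then_sub <- out[sub, ]
  sub_then_whole <- apply_change_field(
    b[sub, ], list(dTavg = dT[sub], dPrec = 10, dPrat = 0))
  expect_equal(whole_then_sub$tavg, sub_then_whole$tavg)
  expect_equal(whole_then_sub$prec, sub_then_whole$prec)

  expect_error(apply_change_field(
    b, list(dTavg = c(1, 2), dPrec = 0, dPrat = 0)), "scalar or length 6")
})

test_that("weighted_quantile is the left-continuous inverse weighted CDF", {
  expect_equal(weighted_quantile(c(1, 2, 3), 1, c(0, 0.5, 1)), c(1, 2, 3))
  # weight concentrated on one value pulls every quantile there
  expect_equal(weighted_quantile(c(1, 2, 3), c(0.01, 50, 0.01), 0.5), 2)
  # smallest x with F(x) >= p
  expect_equal(weighted_quantile(c(10, 20), c(1, 3), 0.25), 10)
  expect_equal(weighted_quantile(c(10, 20), c(1, 3), 0.26), 20)
  expect_error(weighted_quantile(1:3, c(1, 1), 0.5), "equal length")
})

test_that("percentile_fields summarises ensembles per cell", {
  b <- baseline_toy()
  single <- percentile_fields(list(b))
  expect_equal(single$tavg.p10, b$tavg)
  expect_equal(single$tavg.mean, b$tavg)
  expect_equal(single$tavg.p90, b$tavg)

  g0 <- b; g0$tavg <- rep(0, 5)
  g10 <- b; g10$tavg <- rep(10, 5)
  two <- percentile_fields(list(g0, g10))
  expect_equal(two$tavg.mean, rep(5, 5))

  # p10 <= p90 always, on a random weighted ensemble
  set.seed(4)
  grids <- lapply(1:8, function(i) {
    g <- b
    g$tavg <- rnorm(5)
    g$prec <- runif(5, 500, 1500)
    g
  })
  pf <- percentile_fields(grids, weights = runif(8, 0.5, 2))
  expect_true(all(pf$tavg.p10 <= pf$tavg.p90))
  expect_true(all(pf$prec.p10 <= pf$prec.p90))

  bad <- b; bad$cell_id <- rev(b$cell_id)
  expect_error(percentile_fields(list(b, bad)), "same cell set")
})

test_that("cluster-weighted representative means equal full means when clusters are homogeneous", {
  b <- baseline_toy()
  # degenerate ensemble: 3 clusters of sizes 3, 2, 1; members equal their rep
  reps <- lapply(c(1, 4, 9), function(d) {
    apply_change_field(b, list(dTavg = d, dPrec = 0, dPrat = 0))
  })
  sizes <- c(3, 2, 1)
  full <- rep(reps, times = sizes)
  pf_full <- percentile_fields(full)
  pf_reps <- percentile_fields(reps, weights = sizes)
  expect_equal(pf_reps$tavg.mean, pf_full$tavg.mean)
  expect_equal(pf_reps$tavg.p10, pf_full$tavg.p10)
  expect_equal(pf_reps$tavg.p90, pf_full$tavg.p90)
})

test_that("six cluster-weighted representatives track the 27-scenario mean field", {
  # tolerance frozen after one calibration against the full-ensemble oracle
  # on the packaged fixture: weighted-mean delta error below 0.25 degC for
  # temperature and 1.5% of the baseline for precipitation
  sel <- cluster_scenarios(cmip3_deltas_fixture(), restarts = 60, rng_seed = 1)
  b <- make_baseline_grid(nx = 8, ny = 8, rng_seed = 2)
  tab <- cmip3_deltas_fixture()
  grids <- lapply(seq_len(nrow(tab)), function(i) {
    suppressWarnings(apply_change_field(b, tab[i, , drop = FALSE]))
  })
  names(grids) <- scenario_keys(tab)
  pf_full <- percentile_fields(grids)
  reps <- sel$representatives
  pf_reps <- percentile_fields(grids[reps$key], weights = reps$size)
  expect_lt(max(abs(pf_reps$tavg.mean - pf_full$tavg.mean)), 0.25)
  expect_lt(max(abs(pf_reps$prec.mean - pf_full$prec.mean) / b$prec), 0.015)
})
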