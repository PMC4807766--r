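# sensitivity of projections to an arbitrary choice of q AOGCMs

#' Enumerate q-of-m AOGCM combinations
#'
#' All `choose(m, q)` subsets of the model ids, in lexicographic order with
#' respect to the input ordering. If the count exceeds `cap`, a seeded
#' uniform subsample of `cap` combinations is returned instead (so the
#' analysis stays tractable for CMIP5-scale model lists).
#'
#' @param model_ids character vector of m distinct AOGCM identifiers.
#' @param q combination size, `1 <= q <= m`.
#' @param cap maximum number of combinations returned (default 10000).
#' @param rng_seed seed for the subsample when over `cap`.
#' @return list of character vectors, each of length `q`.
#' @export
enumerate_combinations <- function(model_ids, q, cap = 10000L, rng_seed = 1L) {
  model_ids <- as.character(model_ids)
  if (anyDuplicated(model_ids)) fail("model_ids must be distinct")
  m <- length(model_ids)
  if (q < 1L || q > m) fail("q must be in 1..%d, got %s", m, q)
  n_comb <- choose(m, q)
  if (n_comb <= cap) {
    combos <- combn(model_ids, q, simplify = FALSE)
  } else {
    # sample combination ranks without materializing all of them
    picks <- with_seed(split_seed(rng_seed, q),
                       sort(sample(n_comb, cap)))
    combos <- lapply(picks, function(r) unrank_combination(m, q, r))
    combos <- lapply(combos, function(idx) model_ids[idx])
  }
  combos
}

# lexicographic unranking of the r-th q-subset of 1..m (1-based rank)
unrank_combination <- function(m, q, r) {
  out <- integer(q)
  x <- 1L
  for (i in seq_len(q)) {
    repeat {
      block <- choose(m - x, q - i)
      if (r <= block) break
      r <- r - block
      x <- x + 1L
    }
    out[i] <- x
    x <- x + 1L
  }
  out
}

#' Consensus and range change for one AOGCM combination
#'
#' Restricts the probability stack to all scenarios (every available forcing)
#' of the chosen AOGCMs, builds the AUC-weighted consensus, binarizes it with
#' the reference-period threshold and computes gains/losses against the
#' reference binary map.
#'
#' @param stack a [probability_stack()] carrying `scenario_model` metadata.
#' @param combination character vector of AOGCM ids.
#' @param threshold reference-period threshold (see [max_sss_threshold()]).
#' @param reference_binary reference-period binary map or 0/1 vector.
#' @return list of class `combination_run`: `combination`, `q`, `gains_pct`,
#'   `losses_pct`, `n_scenarios`, `n_projections` (models x scenarios
#'   aggregated per cell).
#' @export
run_combination <- function(stack, combination, threshold, reference_binary) {
  if (is.null(stack$scenario_model)) {
    fail("stack carries no scenario_model metadata")
  }
  missing_m <- setdiff(combination, stack$scenario_model)
  if (length(missing_m)) {
    fail("no scenarios in stack for AOGCM(s): %s",
         paste(missing_m, collapse = ", "))
  }
  sel <- which(stack$scenario_model %in% combination)
  sub <- probability_stack(stack$prob[, , sel, drop = FALSE],
                           stack$model_auc,
                           scenario_model = stack$scenario_model[sel],
                           scenario_sres = stack$scenario_sres[sel])
  cons <- binarize(consensus_auc_weighted(sub), threshold)
  rc <- range_change(reference_binary, cons)
  structure(list(combination = as.character(combination),
                 q = length(combination),
                 gains_pct = rc$gains_pct, losses_pct = rc$losses_pct,
                 n_scenarios = length(sel),
                 n_projections = length(sel) * dim(stack$prob)[2L],
                 consensus = cons),
            class = "combination_run")
}

#' Per-q spread of gains and losses across combinations
#'
#' @param runs list of `combination_run` objects (any mix of q values).
#' @return data.frame with one row per q: `q`, `n_combinations`,
#'   `gain_spread` and `loss_spread` (max - min across the q's combinations),
#'   plus min/max columns.
#' @export
spread_summary <- function(runs) {
  if (!length(runs)) fail("need at least one combination run")
  q <- vapply(runs, `[[`, integer(1), "q")
  g <- vapply(runs, `[[`, numeric(1), "gains_pct")
  l <- vapply(runs, `[[`, numeric(1), "losses_pct")
  out <- do.call(rbind, lapply(sort(unique(q)), function(qi) {
    i <- q == qi
    data.frame(q = qi, n_combinations = sum(i),
               gain_min = min(g[i]), gain_max = max(g[i]),
               gain_spread = max(g[i]) - min(g[i]),
               loss_min = min(l[i]), loss_max = max(l[i]),
               loss_spread = max(l[i]) - min(l[i]))
  }))
  rownames(out) <- NULL
  out
}

#' Full arbitrary-selection sensitivity analysis
#'
#' For every q in `q_values`, enumerates the q-of-m AOGCM combinations,
#' computes each combination's AUC-weighted consensus / gains / losses, and
#' summarises the per-q spreads. The spread at q = m is 0 by construction
#' (single combination).
#'
#' @inheritParams run_combination
#' @param q_values combination sizes to evaluate (default 1..m).
#' @param cap,rng_seed forwarded to [enumerate_combinations()].
#' @return list with `runs` (all `combination_run`s) and `spread`
#'   (the [spread_summary()] data.frame).
#' @export
aogcm_sensitivity <- function(stack, threshold, reference_binary,
                              q_values = NULL, cap = 10000L, rng_seed = 1L) {
  models <- unique(stack$scenario_model)
  if (is.null(models)) fail("stack carries no scenario_model metadata")
  if (is.null(q_values)) q_values <- seq_along(models)
  runs <- list()
  for (q in q_values) {
    combos <- enumerate_combinations(models, q, cap = cap,
                                     rng_seed = rng_seed)
    runs <- c(runs, lapply(combos, run_combination, stack = stack,
                           threshold = threshold,
                           reference_binary = reference_binary))
  }
  list(runs = runs, spread = spread_summary(runs))
}
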