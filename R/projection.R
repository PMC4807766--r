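#' Project a baseline climatology under a scenario's change field
#'
#' The change-field (delta) method superimposes a scenario's simulated
#' climate change onto an observed baseline climatology: temperature change
#' is additive (`tavg + dTavg`), precipitation change is relative
#' (`prec * (1 + dPrec/100)`), and the useful-precipitation ratio is scaled
#' relatively as well (`prat * (1 + dPrat/100)`) then clipped to `[0, 1]`,
#' with clip events counted and warned about. Deltas are regional scalars by
#' default; a per-cell numeric vector (a delta grid) of length `nrow(baseline)`
#' is accepted through the same interface for each variable.
#'
#' @param baseline climate grid: data.frame with `cell_id` and numeric
#'   columns `tavg` (deg C), `prec` (mm, non-negative) and `prat` (ratio in
#'   `[0, 1]`).
#' @param delta one row of a [scenario_table()], or a named list/vector with
#'   elements `dTavg`, `dPrec`, `dPrat` (each scalar or per-cell vector).
#' @return the projected climate grid, same cells and order; attributes
#'   `period` (the scenario key, when available) and `n_clipped` (number of
#'   ratio values clipped).
#' @export
apply_change_field <- function(baseline, delta) {
  baseline <- validate_cell_table(baseline)
  missing_v <- setdiff(CLIMATE_VARS, names(baseline))
  if (length(missing_v)) {
    fail("baseline grid is missing variable(s): %s",
         paste(missing_v, collapse = ", "))
  }
  if (is.data.frame(delta)) {
    key <- if (all(c("model", "sres") %in% names(delta))) {
      make_scenario_keys(delta$model[1], delta$sres[1])
    }
    delta <- as.list(delta[1, , drop = FALSE])
  } else {
    delta <- as.list(delta)
    key <- NULL
  }
  missing_d <- setdiff(DELTA_VARS, names(delta))
  if (length(missing_d)) {
    fail("delta must provide %s; missing: %s",
         paste(DELTA_VARS, collapse = ", "),
         paste(missing_d, collapse = ", "))
  }
  n <- nrow(baseline)
  get_d <- function(name) {
    d <- as.numeric(delta[[name]])
    if (!length(d) %in% c(1L, n)) {
      fail("delta '%s' must be scalar or length %d", name, n)
    }
    d
  }
  dT <- get_d("dTavg"); dP <- get_d("dPrec"); dR <- get_d("dPrat")

  out <- baseline
  out$tavg <- baseline$tavg + dT
  out$prec <- baseline$prec * (1 + dP / 100)
  if (any(out$prec < 0)) {
    fail("negative projected precipitation (dPrec below -100%%)")
  }
  prat <- baseline$prat * (1 + dR / 100)
  n_clip <- sum(prat < 0 | prat > 1)
  if (n_clip > 0) {
    warning(sprintf("clipped %d useful-precipitation value(s) to [0, 1]",
                    n_clip), call. = FALSE)
  }
  out$prat <- pmin(pmax(prat, 0), 1)
  attr(out, "period") <- if (!is.null(key)) key else "scenario"
  attr(out, "n_clipped") <- n_clip
  out
}

#' Weighted empirical quantile (left-continuous inverse CDF)
#'
#' `Q(p)` is the smallest observed value `x` whose weighted empirical CDF
#' reaches `p`. With unit weights this is the usual type-1 quantile.
#'
#' @param x numeric values.
#' @param w positive weights (recycled scalar allowed).
#' @param p probabilities in `[0, 1]`.
#' @return numeric vector of quantiles, one per element of `p`.
#' @export
weighted_quantile <- function(x, w, p) {
  if (length(w) == 1L) w <- rep(w, length(x))
  if (length(w) != length(x)) fail("x and w must have equal length")
  if (any(w < 0) || sum(w) <= 0) fail("weights must be non-negative, sum > 0")
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  xs <- x[ord]
  vapply(p, function(pi) {
    if (pi <= 0) return(xs[1L])
    xs[which(cw >= pi - 1e-12)[1L]]
  }, numeric(1))
}

#' Per-cell ensemble percentile fields
#'
#' Across an ensemble of projected climate grids (optionally weighted, e.g.
#' by cluster size for a representative subset), computes for every cell and
#' climate variable the weighted mean and weighted empirical percentiles
#' (default 10th and 90th). This is the full-vs-reduced ensemble comparison
#' summary.
#'
#' @param grids list of climate grids sharing the same `cell_id` set/order.
#' @param weights per-grid positive weights, or `NULL` for uniform.
#' @param probs percentile probabilities (default `c(0.1, 0.9)`).
#' @param variables variables to summarise (default `tavg`, `prec`, `prat`).
#' @return data.frame with `cell_id` and, per variable `v`, columns
#'   `v.p<100*prob>` and `v.mean`.
#' @export
percentile_fields <- function(grids, weights = NULL, probs = c(0.1, 0.9),
                              variables = CLIMATE_VARS) {
  if (!length(grids)) fail("need at least one grid")
  ids <- grids[[1L]]$cell_id
  for (g in grids) {
    if (!identical(g$cell_id, ids)) {
      fail("all grids must share the same cell set and order")
    }
  }
  if (is.null(weights)) weights <- rep(1, length(grids))
  if (length(weights) != length(grids)) {
    fail("need one weight per grid")
  }
  out <- data.frame(cell_id = ids, stringsAsFactors = FALSE)
  for (v in variables) {
    M <- vapply(grids, function(g) g[[v]], numeric(length(ids)))
    M <- matrix(M, nrow = length(ids))
    for (p in probs) {
      out[[sprintf("%s.p%g", v, 100 * p)]] <-
        apply(M, 1, weighted_quantile, w = weights, p = p)
    }
    out[[paste0(v, ".mean")]] <-
      as.vector(M %*% weights) / sum(weights)
  }
  out
}
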