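# consensus maps, thresholding, range change

# Sum_ij x_ij * w_ij per cell, with w an (n_model x n_scen) weight matrix
apply_stack_weights <- function(stack, w) {
  d <- dim(stack$prob)
  flat <- matrix(stack$prob, nrow = d[1L])  # columns ordered (i, j)
  drop(flat %*% as.vector(w))
}

new_consensus_map <- function(stack, prob, mode) {
  structure(data.frame(cell_id = dimnames(stack$prob)[[1L]] %||%
                         as.character(seq_len(dim(stack$prob)[1L])),
                       prob = prob, stringsAsFactors = FALSE),
            mode = mode,
            scenarios = dimnames(stack$prob)[[3L]],
            class = c("consensus_map", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_auc_weights <- function(stack) {
  if (any(stack$model_auc <= 0)) fail("all model AUC weights must be > 0")
  stack$model_auc / sum(stack$model_auc)
}

#' AUC-weighted consensus map
#'
#' Per-cell consensual probability of occurrence: each statistical model's
#' map is weighted by its AUC (normalized over models) and scenarios enter
#' uniformly — `sum_ij x_ij * AUC_i / (n_scen * sum_m AUC_m)`. This is the
#' "simple-weighted" aggregation used for the reference period and for the
#' full-ensemble future consensus.
#'
#' @param stack a [probability_stack()].
#' @return a `consensus_map`: data.frame with `cell_id` and `prob`, carrying
#'   its weighting mode and scenario set as attributes.
#' @export
consensus_auc_weighted <- function(stack) {
  wa <- check_auc_weights(stack)
  n_scen <- dim(stack$prob)[3L]
  w <- outer(wa, rep(1 / n_scen, n_scen))
  new_consensus_map(stack, apply_stack_weights(stack, w), "auc")
}

#' Double-weighted consensus map (AUC x cluster size)
#'
#' Consensus over the representative scenarios of a clustering, weighting
#' each probability `x_ij` by the AUC of model `i` (normalized over models)
#' and by the size `nk_j` of the cluster that scenario `j` represents
#' (normalized over clusters):
#' `xbar* = sum_i sum_j x_ij * (AUC_i / sum_m AUC_m) * (nk_j / sum_p nk_p)`.
#' The cluster-size weight prevents scenarios drawn from small clusters from
#' being over-represented. The joint weights sum to 1.
#'
#' @param stack a [probability_stack()] whose scenario axis is the
#'   representative set.
#' @param representatives a [select_representatives()] result (matched to the
#'   stack's scenario keys), or a per-scenario numeric vector of cluster
#'   sizes `nk_j`; may be omitted if the stack carries `cluster_size`.
#' @return a `consensus_map` (see [consensus_auc_weighted()]).
#' @export
consensus_double_weighted <- function(stack, representatives = NULL) {
  wa <- check_auc_weights(stack)
  keys <- dimnames(stack$prob)[[3L]]
  nk <- if (inherits(representatives, "representative_set")) {
    if (is.null(keys)) fail("stack needs scenario keys to match representatives")
    idx <- match(keys, representatives$key)
    if (anyNA(idx)) {
      fail("no cluster size nk_j for scenario(s): %s",
           paste(keys[is.na(idx)], collapse = ", "))
    }
    representatives$size[idx]
  } else if (!is.null(representatives)) {
    as.numeric(representatives)
  } else {
    stack$cluster_size
  }
  n_scen <- dim(stack$prob)[3L]
  if (is.null(nk) || length(nk) != n_scen) {
    fail("need one cluster size nk_j per scenario in the stack")
  }
  if (any(nk < 1)) fail("cluster sizes nk_j must be >= 1")
  w <- outer(wa, nk / sum(nk))
  stopifnot(abs(sum(w) - 1) < 1e-12)
  new_consensus_map(stack, apply_stack_weights(stack, w), "double")
}

#' Threshold maximizing sensitivity + specificity (maxSSS)
#'
#' Sweeps every distinct consensual probability as a candidate threshold
#' (presence predicted where `p >= t`), and returns the candidate maximizing
#' sensitivity + specificity against the observed presence/absence data;
#' ties go to the smallest such threshold. Used to calibrate the
#' reference-period threshold that is then transferred to future projections.
#'
#' @param consensus a `consensus_map` or a numeric probability vector.
#' @param observed binary 0/1 observations, both classes present, aligned to
#'   the consensus cells.
#' @return the threshold, a value in `[0, 1]`.
#' @export
max_sss_threshold <- function(consensus, observed) {
  p <- if (is.data.frame(consensus)) consensus$prob else as.numeric(consensus)
  y <- check_binary(observed, "observed")
  if (length(p) != length(y)) fail("consensus and observed lengths differ")
  if (length(unique(y)) < 2L) fail("observed must contain both classes")
  cand <- sort(unique(p))
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  sss <- vapply(cand, function(t) {
    sum(p >= t & y == 1L) / n1 + sum(p < t & y == 0L) / n0
  }, numeric(1))
  # smallest threshold attaining the max; the 1e-9 slack keeps mathematical
  # ties tied under floating-point summation order
  cand[which(sss >= max(sss) - 1e-9)[1L]]
}

#' Binarize a consensus map
#'
#' Presence wherever `prob >= threshold` (presence-inclusive convention, the
#' same convention under which the maxSSS tie rule is defined). The
#' threshold's provenance is recorded on the result.
#'
#' @param consensus a `consensus_map`.
#' @param threshold value in `[0, 1]`, normally from [max_sss_threshold()]
#'   calibrated on the reference period.
#' @return the consensus map with an added integer `binary` column and a
#'   `threshold` attribute.
#' @export
binarize <- function(consensus, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    fail("threshold must be a single value in [0, 1]")
  }
  consensus$binary <- as.integer(consensus$prob >= threshold)
  attr(consensus, "threshold") <- threshold
  consensus
}

get_binary <- function(x, what) {
  if (is.data.frame(x)) {
    if (!"binary" %in% names(x)) fail("%s has no 'binary' layer", what)
    check_binary(x$binary, what)
  } else {
    check_binary(x, what)
  }
}

#' Range change between two binary maps
#'
#' Under the unlimited-dispersal assumption: gains are cells absent at
#' reference but present in the future; losses are cells present at
#' reference but absent in the future. Both are expressed as percentages of
#' the reference-period presence count, so gains can exceed 100%.
#'
#' @param reference_binary,future_binary binarized consensus maps (or plain
#'   0/1 vectors) on the same cell set.
#' @return object of class `range_change`: list with `gains_pct`,
#'   `losses_pct`, `n_gained`, `n_lost`, `n_reference`.
#' @export
range_change <- function(reference_binary, future_binary) {
  r <- get_binary(reference_binary, "reference")
  f <- get_binary(future_binary, "future")
  if (length(r) != length(f)) fail("maps must share the same cell set")
  n_ref <- sum(r == 1L)
  if (n_ref == 0L) fail("no reference-period presences; gains/losses undefined")
  n_gain <- sum(r == 0L & f == 1L)
  n_loss <- sum(r == 1L & f == 0L)
  structure(list(gains_pct = 100 * n_gain / n_ref,
                 losses_pct = 100 * n_loss / n_ref,
                 n_gained = n_gain, n_lost = n_loss, n_reference = n_ref),
            class = "range_change")
}

#' @export
print.range_change <- function(x, ...) {
  cat(sprintf("Range change: gains %.1f%%, losses %.1f%% (of %d reference cells)\n",
              x$gains_pct, x$losses_pct, x$n_reference))
  invisible(x)
}

#' Cell-wise agreement map between two binary projections
#'
#' Categorizes every cell as `agree_presence`, `agree_absence`, `only_in_a`
#' or `only_in_b`; the four categories partition the cell set. Used to map
#' where a reduced-ensemble projection departs from the full-ensemble one
#' (disagreement typically concentrates at range edges).
#'
#' @param binary_a,binary_b binarized consensus maps or 0/1 vectors on the
#'   same cell set.
#' @return data.frame with `cell_id` and a factor `category`.
#' @export
difference_map <- function(binary_a, binary_b) {
  a <- get_binary(binary_a, "map a")
  b <- get_binary(binary_b, "map b")
  if (length(a) != length(b)) fail("maps must share the same cell set")
  ids <- if (is.data.frame(binary_a)) binary_a$cell_id else
    as.character(seq_along(a))
  lv <- c("agree_presence", "agree_absence", "only_in_a", "only_in_b")
  cat_ <- ifelse(a == 1L & b == 1L, lv[1L],
          ifelse(a == 0L & b == 0L, lv[2L],
          ifelse(a == 1L, lv[3L], lv[4L])))
  data.frame(cell_id = ids, category = factor(cat_, levels = lv),
             stringsAsFactors = FALSE)
}
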