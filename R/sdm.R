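#' Repeated 70/30 split-sample calibration plan
#'
#' Randomly partitions the cells into a calibration set (`calib_fraction`,
#' rounded) and an evaluation set, repeated `repeats` times. Every
#' calibration and evaluation set must contain both presences and absences;
#' a split failing this is redrawn up to `max_retries` times before erroring.
#' Splits are simple random samples by default; set `stratify = TRUE` to
#' sample presences and absences separately.
#'
#' @param presence binary 0/1 vector, one entry per cell.
#' @param calib_fraction fraction of cells used for calibration (default 0.7).
#' @param repeats number of independent splits (default 20).
#' @param rng_seed integer master seed.
#' @param stratify stratify the draw by class (default `FALSE`).
#' @param max_retries redraw budget per split.
#' @return list of `repeats` elements, each
#'   `list(calibration = <indices>, evaluation = <indices>)`; the two sets
#'   partition `seq_along(presence)`.
#' @export
split_sample <- function(presence, calib_fraction = 0.7, repeats = 20L,
                         rng_seed = 1L, stratify = FALSE,
                         max_retries = 100L) {
  y <- check_binary(presence, "presence")
  n <- length(y)
  n_cal <- round(calib_fraction * n)
  if (n_cal < 2L || n - n_cal < 2L) {
    fail("too few cells (%d) for a %.0f/%.0f split", n,
         100 * calib_fraction, 100 * (1 - calib_fraction))
  }
  draw <- function(seed) {
    with_seed(seed, {
      if (stratify) {
        pres <- which(y == 1L); abs_ <- which(y == 0L)
        n_cal_p <- round(calib_fraction * length(pres))
        cal <- c(sample(pres, n_cal_p),
                 sample(abs_, n_cal - n_cal_p))
        sort(cal)
      } else {
        sort(sample.int(n, n_cal))
      }
    })
  }
  lapply(seq_len(repeats), function(r) {
    for (try in 0:max_retries) {
      cal <- draw(split_seed(rng_seed, r * 1000L + try))
      ev <- setdiff(seq_len(n), cal)
      if (length(unique(y[cal])) == 2L && length(unique(y[ev])) == 2L) {
        return(list(calibration = cal, evaluation = ev))
      }
    }
    fail("split %d: could not obtain both classes in both sets after %d retries",
         r, max_retries)
  })
}

#' Fit the reference occurrence model (ridge-stabilized logistic response)
#'
#' A deterministic logistic regression of presence on the climate covariates
#' (optionally with quadratic terms, giving unimodal response curves), fitted
#' by iteratively reweighted least squares with a small ridge penalty on the
#' non-intercept coefficients. The ridge keeps the fit finite under complete
#' separation; covariates are internally centred and scaled for numerical
#' stability, and coefficients are reported on both scales.
#'
#' This is the reference implementation of the pluggable occurrence-model
#' contract: any learner producing per-cell probabilities in `[0, 1]` can be
#' substituted upstream of the consensus layer via [probability_stack()].
#'
#' @param data data.frame holding the presence column and covariates.
#' @param presence name of the binary 0/1 response column (default
#'   `"presence"`).
#' @param covariates covariate column names (default `tavg`, `prec`, `prat`).
#' @param quadratic add squared covariate terms (default `TRUE`).
#' @param ridge ridge penalty on standardized non-intercept coefficients.
#' @param max_iter IRLS iteration cap; non-convergence is flagged, not fatal.
#' @param tol convergence tolerance on the max coefficient change.
#' @return object of class `occurrence_model` with elements `coefficients`
#'   (standardized scale), `coefficients_raw` (original covariate scale),
#'   `se_raw`, `converged`, `algorithm`, plus an `auc` slot filled by
#'   [fit_sdm_ensemble()] or manually.
#' @export
fit_reference_model <- function(data, presence = "presence",
                                covariates = CLIMATE_VARS, quadratic = TRUE,
                                ridge = 1e-6, max_iter = 100L, tol = 1e-8) {
  y <- check_binary(data[[presence]], sprintf("column '%s'", presence))
  if (length(unique(y)) < 2L) fail("need both presences and absences to fit")
  miss <- setdiff(covariates, names(data))
  if (length(miss)) fail("missing covariate(s): %s", paste(miss, collapse = ", "))

  X0 <- as.matrix(data[covariates])
  ctr <- colMeans(X0)
  scl <- apply(X0, 2, sd)
  scl[scl == 0] <- 1
  Xs <- scale(X0, center = ctr, scale = scl)
  X <- cbind(`(Intercept)` = 1, Xs)
  if (quadratic) {
    Q <- Xs^2
    colnames(Q) <- paste0(covariates, "^2")
    X <- cbind(X, Q)
  }
  p <- ncol(X)
  pen <- c(0, rep(ridge, p - 1L))  # intercept unpenalized

  beta <- numeric(p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    H <- XtW %*% X + diag(pen, p)
    beta_new <- drop(solve(H, XtW %*% z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  names(beta) <- colnames(X)

  # delta-method SEs on the original covariate scale (linear terms only)
  eta <- pmin(pmax(drop(X %*% beta), -30), 30)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- t(X * w) %*% X + diag(pen, p)
  se_std <- sqrt(diag(solve(H)))
  names(se_std) <- colnames(X)

  lin <- covariates
  beta_raw <- beta[lin] / scl
  se_raw <- se_std[lin] / scl
  int_raw <- beta[1L] - sum(beta[lin] * ctr / scl)
  if (quadratic) {
    q <- paste0(covariates, "^2")
    beta_raw <- c(beta_raw, beta[q] / scl^2)
    se_raw <- c(se_raw, se_std[q] / scl^2)
    beta_raw[lin] <- beta_raw[lin] - 2 * beta[q] * ctr / scl^2
    int_raw <- int_raw + sum(beta[q] * (ctr / scl)^2)
  }
  beta_raw <- c(`(Intercept)` = unname(int_raw), beta_raw)

  structure(list(coefficients = beta, coefficients_raw = beta_raw,
                 se = se_std, se_raw = se_raw,
                 center = ctr, scale = scl, covariates = covariates,
                 quadratic = quadratic, ridge = ridge,
                 converged = converged, iterations = it,
                 algorithm = "ridge_logistic", auc = NA_real_),
            class = "occurrence_model")
}

#' @export
print.occurrence_model <- function(x, ...) {
  cat(sprintf("Ridge-logistic occurrence model (%s, %d covariates%s)\n",
              if (x$converged) "converged" else "NOT converged",
              length(x$covariates),
              if (x$quadratic) " + quadratic terms" else ""))
  print(round(x$coefficients, 4))
  if (!is.na(x$auc)) cat(sprintf("evaluation AUC: %.3f\n", x$auc))
  invisible(x)
}

#' Predict occurrence probabilities on a climate grid
#'
#' @param object an [fit_reference_model()] fit.
#' @param newdata data.frame holding the model's covariate columns.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.occurrence_model <- function(object, newdata, ...) {
  miss <- setdiff(object$covariates, names(newdata))
  if (length(miss)) {
    fail("covariate column(s) missing from grid: %s",
         paste(miss, collapse = ", "))
  }
  Xs <- scale(as.matrix(newdata[object$covariates]),
              center = object$center, scale = object$scale)
  X <- cbind(1, Xs)
  if (object$quadratic) X <- cbind(X, Xs^2)
  plogis(pmin(pmax(drop(X %*% object$coefficients), -30), 30))
}

#' Area under the ROC curve (rank statistic)
#'
#' The Mann-Whitney form of the AUC: the probability that a randomly drawn
#' presence cell receives a higher score than a randomly drawn absence cell,
#' with ties counted one half. Invariant under strictly monotone transforms
#' of the scores.
#'
#' @param scores numeric prediction scores.
#' @param truth binary 0/1 observations, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, truth) {
  y <- check_binary(truth, "truth")
  if (length(scores) != length(y)) fail("scores and truth lengths differ")
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) fail("truth must contain both classes")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit and evaluate a split-sample ensemble of reference models
#'
#' Applies the [split_sample()] protocol: one reference model per calibration
#' split, each evaluated by [auc()] on its held-out 30%. The per-model AUCs
#' become the model weights of the consensus layer.
#'
#' @inheritParams fit_reference_model
#' @inheritParams split_sample
#' @param repeats number of splits (and models) fitted.
#' @return list of `occurrence_model` objects with their `auc` slots filled;
#'   attribute `splits` keeps the index pairs.
#' @export
fit_sdm_ensemble <- function(data, presence = "presence",
                             covariates = CLIMATE_VARS, quadratic = TRUE,
                             repeats = 20L, calib_fraction = 0.7,
                             rng_seed = 1L, stratify = FALSE) {
  splits <- split_sample(data[[presence]], calib_fraction = calib_fraction,
                         repeats = repeats, rng_seed = rng_seed,
                         stratify = stratify)
  models <- lapply(seq_along(splits), function(i) {
    s <- splits[[i]]
    m <- fit_reference_model(data[s$calibration, , drop = FALSE],
                             presence = presence, covariates = covariates,
                             quadratic = quadratic)
    ev <- data[s$evaluation, , drop = FALSE]
    m$auc <- auc(predict(m, ev), ev[[presence]])
    m$split <- i
    m
  })
  attr(models, "splits") <- splits
  models
}

#' Construct a per-cell probability stack
#'
#' The operand of the consensus layer: occurrence probabilities indexed by
#' (statistical model i, climate scenario j) for every cell, with per-model
#' AUC weights and optional per-scenario metadata (AOGCM, forcing, cluster
#' size).
#'
#' @param prob 3-d array `cells x models x scenarios` of probabilities in
#'   `[0, 1]`; dimnames supply cell ids, model ids, scenario keys.
#' @param model_auc per-model AUC values in `(0, 1]`.
#' @param scenario_model,scenario_sres optional per-scenario AOGCM / forcing
#'   tags (needed by the sensitivity analysis).
#' @param cluster_size optional per-scenario cluster sizes `nk_j` (needed by
#'   [consensus_double_weighted()]).
#' @return object of class `probability_stack`.
#' @export
probability_stack <- function(prob, model_auc, scenario_model = NULL,
                              scenario_sres = NULL, cluster_size = NULL) {
  if (length(dim(prob)) != 3L) {
    fail("prob must be a 3-d array (cells x models x scenarios)")
  }
  if (anyNA(prob) || any(prob < 0 | prob > 1)) {
    fail("probabilities must all lie in [0, 1] with no missing (i, j) pairs")
  }
  n_model <- dim(prob)[2L]
  n_scen <- dim(prob)[3L]
  if (length(model_auc) != n_model) fail("need one AUC per model")
  check_len <- function(x, what) {
    if (!is.null(x) && length(x) != n_scen) {
      fail("%s must have one entry per scenario", what)
    }
    x
  }
  structure(list(prob = prob, model_auc = as.numeric(model_auc),
                 scenario_model = check_len(scenario_model, "scenario_model"),
                 scenario_sres = check_len(scenario_sres, "scenario_sres"),
                 cluster_size = check_len(cluster_size, "cluster_size")),
            class = "probability_stack")
}

#' @export
print.probability_stack <- function(x, ...) {
  d <- dim(x$prob)
  cat(sprintf(
    "Probability stack: %d cells x %d models x %d scenarios (%d per cell)\n",
    d[1L], d[2L], d[3L], d[2L] * d[3L]))
  invisible(x)
}

#' Project an ensemble of models over an ensemble of climate grids
#'
#' @param models list of `occurrence_model` fits with `auc` slots set.
#' @param grids named list of climate grids (names become scenario keys),
#'   all sharing the cell set of the models' covariates.
#' @param scenario_model,scenario_sres,cluster_size optional per-grid
#'   metadata forwarded to [probability_stack()].
#' @return a [probability_stack()] of dimension
#'   `cells x length(models) x length(grids)`.
#' @export
project_stack <- function(models, grids, scenario_model = NULL,
                          scenario_sres = NULL, cluster_size = NULL) {
  if (!length(models) || !length(grids)) fail("need >= 1 model and >= 1 grid")
  ids <- grids[[1L]]$cell_id
  prob <- array(NA_real_,
                dim = c(length(ids), length(models), length(grids)),
                dimnames = list(ids,
                                paste0("m", seq_along(models)),
                                names(grids)))
  for (j in seq_along(grids)) {
    g <- grids[[j]]
    if (!identical(g$cell_id, ids)) {
      fail("grid %d does not share the cell set of grid 1", j)
    }
    for (i in seq_along(models)) {
      prob[, i, j] <- predict(models[[i]], g)
    }
  }
  probability_stack(prob, vapply(models, function(m) m$auc, numeric(1)),
                    scenario_model = scenario_model,
                    scenario_sres = scenario_sres,
                    cluster_size = cluster_size)
}
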