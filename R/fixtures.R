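# synthetic fixtures: the published 27-scenario delta table, a smooth
# multi-gradient climate landscape, and virtual species with known truth

#' The 27-scenario climate delta table
#'
#' The published ensemble of 27 climate-change scenarios for north-eastern
#' North America (2071-2100 vs 1961-1990): nine CMIP3 AOGCMs crossed with
#' three SRES forcing scenarios (A2, A1B, B1), each described by the regional
#' change in mean annual temperature (`dTavg`, degrees C), total annual
#' precipitation (`dPrec`, %) and useful precipitation (`dPrat`, %). The
#' values are embedded verbatim and verified against frozen column checksums
#' at construction time.
#'
#' @return a [scenario_table()] of 27 scenarios, 9 AOGCMs x 3 forcings.
#' @export
#' @examples
#' tab <- cmip3_deltas_fixture()
#' summarize_deltas(tab)
cmip3_deltas_fixture <- function() {
  txt <- "center,model,sres,dTavg,dPrec,dPrat
CCCMA,CGCM3.1 (T47),A2,5.0,18.2,-4.2
CCCMA,CGCM3.1 (T47),A1B,3.9,15.3,-3.6
CCCMA,CGCM3.1 (T47),B1,2.8,7.7,-3.2
CNRM,CM3,A2,4.5,9.4,-4.0
CNRM,CM3,A1B,3.5,8.4,-3.1
CNRM,CM3,B1,2.2,5.4,-2.5
CSIRO,MK3.0,A2,3.9,11.8,-1.6
CSIRO,MK3.0,A1B,2.8,6.7,-2.8
CSIRO,MK3.0,B1,1.8,4.8,-1.5
CSIRO,MK3.5,A2,4.7,11.0,-2.7
CSIRO,MK3.5,A1B,3.9,15.4,-0.7
CSIRO,MK3.5,B1,2.9,7.3,-2.5
GFDL,CM2.0,A2,5.2,3.9,-7.4
GFDL,CM2.0,A1B,4.3,9.6,-3.4
GFDL,CM2.0,B1,2.8,8.1,-2.0
IPSL,CM4,A2,6.9,2.8,-2.4
IPSL,CM4,A1B,5.8,5.4,-2.8
IPSL,CM4,B1,4.2,1.6,-2.2
CCSR,MIROC3.2 (Medres),A2,6.8,-0.8,-9.3
CCSR,MIROC3.2 (Medres),A1B,5.8,3.1,-7.1
CCSR,MIROC3.2 (Medres),B1,4.0,5.7,-5.2
MIUB,ECHO-G,A2,5.0,12.6,-0.1
MIUB,ECHO-G,A1B,4.8,11.4,-0.2
MIUB,ECHO-G,B1,3.4,5.9,0.3
MRI,CGCM2.3.2,A2,3.7,13.7,-1.1
MRI,CGCM2.3.2,A1B,3.3,11.0,-1.3
MRI,CGCM2.3.2,B1,2.5,8.9,0.2"
  tab <- scenario_table(utils::read.csv(text = txt, stringsAsFactors = FALSE,
                                        check.names = FALSE))
  # frozen transcription checksums (exact decimal sums of each column x 10)
  sums <- vapply(tab[DELTA_VARS], function(x) sum(round(x * 10)), numeric(1))
  if (nrow(tab) != 27L ||
      !identical(unname(sums), c(1104, 2243, -764))) {
    fail("embedded scenario fixture failed its checksum")  # nocov
  }
  tab
}

# box-filter moving average over the lattice; radius in cells
smooth_lattice <- function(values, row, col, radius = 1L) {
  nx <- max(col); ny <- max(row)
  M <- matrix(NA_real_, nrow = ny, ncol = nx)
  M[cbind(row, col)] <- values
  out <- matrix(0, ny, nx)
  cnt <- matrix(0, ny, nx)
  for (dr in -radius:radius) {
    rs <- pmin(pmax(seq_len(ny) + dr, 1L), ny)
    for (dc in -radius:radius) {
      cs <- pmin(pmax(seq_len(nx) + dc, 1L), nx)
      out <- out + M[rs, cs, drop = FALSE]
      cnt <- cnt + 1
    }
  }
  (out / cnt)[cbind(row, col)]
}

#' Synthetic baseline climate landscape
#'
#' A rectangular lattice carrying a smooth south-to-north mean annual
#' temperature gradient (warm south, cold north, emulating a temperate to
#' boreal transect), a west-to-east total annual precipitation gradient and
#' a mild south-to-north gradient in useful precipitation, plus seeded
#' spatially correlated noise (white noise smoothed by a box filter on the
#' lattice). Deterministic per seed.
#'
#' @param nx,ny lattice width and height in cells (default 20 x 20).
#' @param rng_seed integer seed.
#' @param noise_sd named per-variable SD of the pre-smoothing noise; zero
#'   gives exact linear gradients.
#' @param tavg_range,prec_range,prat_range endpoint values of the gradients
#'   (south to north for `tavg`/`prat`, west to east for `prec`).
#' @return a climate grid: data.frame with `cell_id`, lattice coordinates
#'   `x`, `y`, and variables `tavg`, `prec`, `prat`; attribute
#'   `period = "reference"`.
#' @export
make_baseline_grid <- function(nx = 20L, ny = 20L, rng_seed = 1L,
                               noise_sd = c(tavg = 0.6, prec = 40,
                                            prat = 0.015),
                               tavg_range = c(14, -2),
                               prec_range = c(800, 1300),
                               prat_range = c(0.28, 0.42)) {
  if (nx < 1L || ny < 1L) fail("nx and ny must be >= 1")
  col <- rep(seq_len(nx), times = ny)
  row <- rep(seq_len(ny), each = nx)
  fr <- function(v, n) if (n == 1L) rep(0.5, length(v)) else (v - 1) / (n - 1)
  gy <- fr(row, ny)  # 0 south -> 1 north
  gx <- fr(col, nx)  # 0 west -> 1 east
  n <- nx * ny
  noise <- with_seed(rng_seed, {
    lapply(c(tavg = "tavg", prec = "prec", prat = "prat"), function(v) {
      s <- noise_sd[[v]]
      if (is.null(s) || s == 0) rep(0, n) else
        smooth_lattice(rnorm(n, 0, s), row, col)
    })
  })
  grid <- data.frame(
    cell_id = sprintf("c%05d", seq_len(n)),
    x = col, y = row,
    tavg = tavg_range[1] + (tavg_range[2] - tavg_range[1]) * gy + noise$tavg,
    prec = pmax(prec_range[1] + (prec_range[2] - prec_range[1]) * gx +
                  noise$prec, 0),
    prat = pmin(pmax(prat_range[1] + (prat_range[2] - prat_range[1]) * gy +
                       noise$prat, 0), 1),
    stringsAsFactors = FALSE)
  attr(grid, "period") <- "reference"
  grid
}

#' Virtual species specification
#'
#' Coefficients of a logistic occurrence response to climate. The default
#' species has a unimodal thermal optimum near 7 degrees C, a moderate
#' preference for wetter cells and a positive response to useful
#' precipitation — a strong-signal species in the middle of the default
#' landscape, with prevalence around 0.4.
#'
#' @param intercept intercept on the logit scale.
#' @param linear,quadratic named coefficients (per climate variable) of the
#'   linear and squared terms, on the raw covariate scale.
#' @return list of class `virtual_species_spec`.
#' @export
virtual_species_spec <- function(intercept = -11.5,
                                 linear = c(tavg = 2.2, prec = 0.004,
                                            prat = 10),
                                 quadratic = c(tavg = -0.16)) {
  structure(list(intercept = intercept, linear = linear,
                 quadratic = quadratic),
            class = "virtual_species_spec")
}

#' Sample a virtual species on a climate grid
#'
#' Computes the species' true occurrence probability surface
#' `plogis(response(grid))` from its [virtual_species_spec()] and draws the
#' observed presence/absence layer as independent Bernoulli trials. The true
#' probability surface is kept alongside the samples so that model-recovery
#' tests have known ground truth.
#'
#' @param grid a climate grid (see [make_baseline_grid()]).
#' @param spec a [virtual_species_spec()].
#' @param rng_seed integer seed for the Bernoulli draw.
#' @return occurrence data: the grid plus `true_prob` and binary `presence`
#'   columns.
#' @export
make_virtual_species <- function(grid, spec = virtual_species_spec(),
                                 rng_seed = 1L) {
  grid <- validate_cell_table(grid)
  covs <- union(names(spec$linear), names(spec$quadratic))
  miss <- setdiff(covs, names(grid))
  if (length(miss)) {
    fail("grid is missing covariate(s) required by the species: %s",
         paste(miss, collapse = ", "))
  }
  eta <- rep(spec$intercept, nrow(grid))
  for (v in names(spec$linear)) eta <- eta + spec$linear[[v]] * grid[[v]]
  for (v in names(spec$quadratic)) {
    eta <- eta + spec$quadratic[[v]] * grid[[v]]^2
  }
  if (anyNA(eta) || any(!is.finite(eta))) {
    fail("non-finite species response; check the coefficients")
  }
  p <- plogis(eta)
  occ <- grid
  occ$true_prob <- p
  occ$presence <- with_seed(rng_seed, rbinom(nrow(grid), 1L, p))
  prev <- mean(occ$presence)
  if (prev == 0 || prev == 1) {
    fail(paste0("degenerate realized prevalence (", prev,
                "); adjust the species coefficients"))
  }
  occ
}
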