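# shared internal helpers

# canonical climate variable names used by the projection / SDM layers
CLIMATE_VARS <- c("tavg", "prec", "prat")
DELTA_VARS <- c("dTavg", "dPrec", "dPrat")

fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
# Counter-based seed splitting: sub-task `counter` under master seed `seed`
# gets its own RNG seed, independent of how many draws other sub-tasks
# consumed. All arithmetic stays below 2^53 so doubles are exact.
split_seed <- function(seed, counter) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(counter) * 69621
  as.integer(s %% 2147483629) + 1L
}

# evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# scenario identity = (model, forcing); center is metadata only
make_scenario_keys <- function(model, sres) paste(model, sres, sep = ":")

#' @noRd
scenario_keys <- function(table) {
  make_scenario_keys(table$model, table$sres)
}

check_binary <- function(x, what) {
  if (!all(x %in% c(0, 1))) {
    fail("%s must contain only 0/1 values", what)
  }
  as.integer(x)
}
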