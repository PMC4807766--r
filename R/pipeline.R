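# end-to-end orchestration and the command-line entry point

#' Parse a flat key = value run-configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment;
#' blank lines ignored. Values are kept as strings; consumers coerce.
#'
#' @param path configuration file path.
#' @return named list of character values.
#' @export
parse_run_config <- function(path) {
  if (!file.exists(path)) fail("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) fail("cannot parse config line: '%s'", ln)
    out[[m[2]]] <- trimws(m[3])
  }
  out
}

config_get <- function(config, key, default = NULL, as = identity) {
  v <- config[[key]]
  if (is.null(v) || !nzchar(v)) {
    if (is.null(default)) fail("config is missing required key '%s'", key)
    return(default)
  }
  as(v)
}

#' Run the full scenario-selection and ensemble-forecasting pipeline
#'
#' Executes, in order: scenario clustering and representative selection;
#' baseline-grid and virtual-species generation (or loading, if paths are
#' configured); change-field projection of every scenario; split-sample
#' SDM fitting with AUC evaluation; reference-period consensus and maxSSS
#' threshold; future consensus from the full ensemble (AUC-weighted) and
#' from the representatives (double-weighted); gain/loss statistics and the
#' full-vs-reduced difference map; and optionally the arbitrary-AOGCM
#' sensitivity analysis. Every stage's outputs are written under `out_dir`
#' and recorded, with md5 checksums and per-stage input/output lists, in
#' `manifest.json`; a resolved copy of the configuration is written next to
#' the outputs. Reruns with identical configuration and seeds reproduce
#' identical checksums.
#'
#' Recognized config keys (all optional unless noted): `out_dir` (required),
#' `seed`, `k` (`auto` or integer), `restarts`, `cost_weight`,
#' `scenario_table` (path; defaults to the packaged 27-scenario fixture),
#' `baseline` / `occurrences` (paths; defaults to synthetic fixtures),
#' `nx`, `ny`, `repeats`, `run_sensitivity` (`true`/`false`).
#'
#' @param config named list (see [parse_run_config()]) or a path to a
#'   configuration file.
#' @return the manifest, invisibly: list with per-stage outputs, file
#'   checksums and headline numbers.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- parse_run_config(config)
  }
  out_dir <- config_get(config, "out_dir")
  seed <- config_get(config, "seed", 1L, as.integer)
  k <- config_get(config, "k", "auto")
  restarts <- config_get(config, "restarts", 999L, as.integer)
  cost_weight <- config_get(config, "cost_weight", 1, as.numeric)
  repeats <- config_get(config, "repeats", 20L, as.integer)
  nx <- config_get(config, "nx", 20L, as.integer)
  ny <- config_get(config, "ny", 20L, as.integer)
  run_sens <- tolower(config_get(config, "run_sensitivity", "false")) %in%
    c("true", "1", "yes")

  # validate declared inputs before any stage runs
  for (key in c("scenario_table", "baseline", "occurrences")) {
    p <- config[[key]]
    if (!is.null(p) && nzchar(p) && !file.exists(p)) {
      fail("config key '%s' points to a missing file: %s", key, p)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(stages = list(), files = list())
  emit <- function(stage, inputs, outputs) {
    manifest$stages[[stage]] <<- list(inputs = inputs, outputs = outputs)
  }
  save_json <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    path
  }
  save_csv <- function(x, name) write_cell_table(x, file.path(out_dir, name))

  # resolved configuration copy
  resolved <- utils::modifyList(
    list(out_dir = out_dir, seed = seed, k = k, restarts = restarts,
         cost_weight = cost_weight, repeats = repeats, nx = nx, ny = ny,
         run_sensitivity = run_sens),
    config)
  cfg_path <- save_json(resolved, "config.resolved.json")

  stage <- "cluster"
  tab <- if (!is.null(config$scenario_table)) {
    read_scenario_table(config$scenario_table)
  } else {
    cmip3_deltas_fixture()
  }
  sel <- cluster_scenarios(tab, k = k, restarts = restarts,
                           rng_seed = seed, cost_weight = cost_weight)
  sol_path <- save_json(clustering_to_list(sel), "solution.json")
  emit(stage, config$scenario_table %||% "<packaged scenario fixture>",
       sol_path)

  stage <- "fixtures"
  baseline <- if (!is.null(config$baseline)) {
    read_cell_table(config$baseline)
  } else {
    make_baseline_grid(nx = nx, ny = ny, rng_seed = split_seed(seed, 1L))
  }
  occ <- if (!is.null(config$occurrences)) {
    read_cell_table(config$occurrences)
  } else {
    make_virtual_species(baseline, rng_seed = split_seed(seed, 2L))
  }
  base_path <- save_csv(baseline, "baseline.csv")
  occ_path <- save_csv(occ, "occurrences.csv")
  emit(stage, character(), c(base_path, occ_path))

  stage <- "project"
  keys <- scenario_keys(tab)
  grids <- lapply(seq_len(nrow(tab)), function(i) {
    suppressWarnings(apply_change_field(baseline, tab[i, , drop = FALSE]))
  })
  names(grids) <- keys
  emit(stage, c(base_path, sol_path), character())

  stage <- "fit"
  models <- fit_sdm_ensemble(occ, repeats = repeats,
                             rng_seed = split_seed(seed, 3L))
  aucs <- vapply(models, `[[`, numeric(1), "auc")
  models_path <- save_json(
    list(n_models = length(models), auc = aucs,
         mean_auc = mean(aucs), sd_auc = sd(aucs)), "models.json")
  emit(stage, occ_path, models_path)

  stage <- "consensus_reference"
  ref_stack <- project_stack(models, list(reference = baseline))
  ref_cons <- consensus_auc_weighted(ref_stack)
  threshold <- max_sss_threshold(ref_cons, occ$presence)
  ref_bin <- binarize(ref_cons, threshold)
  ref_path <- save_csv(ref_bin, "consensus_reference.csv")
  emit(stage, c(occ_path, models_path), ref_path)

  stage <- "consensus_future"
  full_stack <- project_stack(models, grids,
                              scenario_model = tab$model,
                              scenario_sres = tab$sres)
  full_cons <- binarize(consensus_auc_weighted(full_stack), threshold)
  reps <- sel$representatives
  rep_stack <- project_stack(models, grids[reps$key],
                             scenario_model = reps$model,
                             scenario_sres = reps$sres,
                             cluster_size = reps$size)
  dw_cons <- binarize(consensus_double_weighted(rep_stack, reps), threshold)
  full_path <- save_csv(full_cons, "consensus_full.csv")
  dw_path <- save_csv(dw_cons, "consensus_double_weighted.csv")
  outs <- c(full_path, dw_path)
  if (tolower(config_get(config, "write_stack", "false")) %in%
      c("true", "1", "yes")) {
    outs <- c(outs, write_stack_csv(full_stack,
                                    file.path(out_dir, "stack.csv")))
  }
  emit(stage, c(ref_path, sol_path), outs)

  stage <- "compare"
  rc_full <- range_change(ref_bin, full_cons)
  rc_dw <- range_change(ref_bin, dw_cons)
  diff <- difference_map(full_cons, dw_cons)
  cmp <- list(threshold = threshold,
              full = unclass(rc_full)[c("gains_pct", "losses_pct")],
              double_weighted = unclass(rc_dw)[c("gains_pct", "losses_pct")],
              difference_counts = as.list(table(diff$category)))
  cmp_path <- save_json(cmp, "compare.json")
  diff_path <- save_csv(diff, "difference_map.csv")
  emit(stage, c(full_path, dw_path), c(cmp_path, diff_path))

  if (run_sens) {
    stage <- "sensitivity"
    sens <- aogcm_sensitivity(full_stack, threshold, ref_bin,
                              rng_seed = split_seed(seed, 4L))
    sens_path <- save_json(
      list(spread = sens$spread,
           runs = lapply(sens$runs, function(r) {
             r[c("combination", "q", "gains_pct", "losses_pct",
                 "n_projections")]
           })),
      "sensitivity.json")
    emit(stage, c(full_path, ref_path), sens_path)
  }

  produced <- list.files(out_dir, full.names = TRUE)
  manifest$files <- as.list(tools::md5sum(sort(produced)))
  manifest$headline <- list(k = sel$k, rsq = sel$solution$rsq,
                            threshold = threshold, compare = cmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

clustering_to_list <- function(sel) {
  ctr <- attr(sel$Z, "scaled:center")
  scl <- attr(sel$Z, "scaled:scale")
  back <- sweep(sweep(sel$solution$centroids, 2, scl, "*"), 2, ctr, "+")
  list(k = sel$k,
       rsq = sel$solution$rsq,
       restarts = sel$restarts,
       rng_seed = sel$rng_seed,
       cost_weight = sel$cost_weight,
       assignment = as.list(sel$solution$assignment),
       centroids_standardized = sel$solution$centroids,
       centroids = back,
       rsq_profile = as.data.frame(sel$profile),
       representatives = as.data.frame(sel$representatives))
}

# --- command-line interface -------------------------------------------------

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) fail("unexpected argument '%s'", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      flags[[key]] <- "true"
      i <- i + 1L
    } else {
      flags[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  flags
}

cli_log <- function(fmt, ...) {
  message(sprintf("[scenoset] %s", sprintf(fmt, ...)))
}

#' Command-line entry point
#'
#' Dispatches `scenoset <subcommand> --flag value ...`. Subcommands:
#' `cluster` (scenario selection), `project` (change-field projection),
#' `fixtures` (synthetic inputs), `run` (full pipeline from a config file).
#' Designed to be called from an `Rscript` wrapper; see
#' `system.file("cli", "scenoset.R", package = "scenoset")`.
#'
#' @param args character vector of command-line arguments
#'   (e.g. `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status: 0 success, 1 computation error,
#'   2 validation/usage error.
#' @export
scenoset_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: scenoset <cluster|project|fit|consensus|sensitivity|fixtures|run> [--flag value ...]",
    "  cluster     --table deltas.csv [--k auto] [--restarts 999] [--seed 1] --out solution.json",
    "  project     --baseline grid.csv --table deltas.csv --scenario MODEL:SRES --out future.csv",
    "  fit         --occurrences occ.csv [--repeats 20] [--seed 1] --out models.json",
    "  consensus   --stack stack.csv --mode auc|double [--threshold t] --out consensus.csv",
    "  sensitivity --stack stack.csv --threshold t --reference ref.csv --out sensitivity.json",
    "  fixtures    --what deltas|grid|species [--seed 1] [--nx 20] [--ny 20] --out dir/",
    "  run         --config run.cfg",
    sep = "\n")
  if (!length(args)) {
    message(usage)
    return(2L)
  }
  cmd <- args[[1L]]
  flags <- tryCatch(parse_cli_flags(args[-1L]), error = function(e) e)
  if (inherits(flags, "error")) {
    message(conditionMessage(flags), "\n", usage)
    return(2L)
  }
  need <- function(key) {
    if (is.null(flags[[key]])) fail("missing required flag --%s", key)
    flags[[key]]
  }
  run <- switch(cmd,
    cluster = function() {
      tab <- read_scenario_table(need("table"))
      sel <- cluster_scenarios(
        tab, k = flags$k %||% "auto",
        restarts = as.integer(flags$restarts %||% "999"),
        rng_seed = as.integer(flags$seed %||% "1"))
      jsonlite::write_json(clustering_to_list(sel), need("out"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      cli_log("k = %d, Rsq = %.4f -> %s", sel$k, sel$solution$rsq,
              flags$out)
    },
    project = function() {
      tab <- read_scenario_table(need("table"))
      baseline <- read_cell_table(need("baseline"))
      key <- need("scenario")
      i <- match(key, scenario_keys(tab))
      if (is.na(i)) fail("scenario '%s' not found in table", key)
      out <- apply_change_field(baseline, tab[i, , drop = FALSE])
      write_cell_table(out, need("out"))
      cli_log("projected %d cells under %s -> %s", nrow(out), key, flags$out)
    },
    fixtures = function() {
      what <- need("what")
      out <- need("out")
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      seed <- as.integer(flags$seed %||% "1")
      if (what == "deltas") {
        write_scenario_table(cmip3_deltas_fixture(), file.path(out, "deltas.csv"))
      } else if (what == "grid") {
        write_cell_table(make_baseline_grid(
          nx = as.integer(flags$nx %||% "20"),
          ny = as.integer(flags$ny %||% "20"), rng_seed = seed),
          file.path(out, "baseline.csv"))
      } else if (what == "species") {
        g <- make_baseline_grid(nx = as.integer(flags$nx %||% "20"),
                                ny = as.integer(flags$ny %||% "20"),
                                rng_seed = seed)
        write_cell_table(make_virtual_species(g, rng_seed = seed + 1L),
                         file.path(out, "occurrences.csv"))
      } else {
        fail("unknown fixture '%s' (deltas|grid|species)", what)
      }
      cli_log("wrote %s fixture under %s", what, out)
    },
    fit = function() {
      occ <- read_cell_table(need("occurrences"))
      models <- fit_sdm_ensemble(
        occ, repeats = as.integer(flags$repeats %||% "20"),
        rng_seed = as.integer(flags$seed %||% "1"))
      jsonlite::write_json(
        lapply(models, function(m) {
          list(algorithm = m$algorithm, split = m$split, auc = m$auc,
               converged = m$converged,
               coefficients = as.list(m$coefficients_raw))
        }),
        need("out"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
      cli_log("fitted %d models (mean AUC %.3f) -> %s", length(models),
              mean(vapply(models, `[[`, numeric(1), "auc")), flags$out)
    },
    consensus = function() {
      stack <- read_stack_csv(need("stack"))
      mode <- flags$mode %||% "auc"
      cons <- if (mode == "double") {
        consensus_double_weighted(stack)
      } else if (mode == "auc") {
        consensus_auc_weighted(stack)
      } else {
        fail("unknown consensus mode '%s' (auc|double)", mode)
      }
      if (!is.null(flags$threshold)) {
        cons <- binarize(cons, as.numeric(flags$threshold))
      }
      write_cell_table(cons, need("out"))
      cli_log("%s consensus over %d scenarios -> %s", mode,
              dim(stack$prob)[3L], flags$out)
    },
    sensitivity = function() {
      stack <- read_stack_csv(need("stack"))
      ref <- read_cell_table(need("reference"))
      if (!"binary" %in% names(ref)) {
        fail("reference map must have a 'binary' column")
      }
      sens <- aogcm_sensitivity(
        stack, as.numeric(need("threshold")), ref$binary,
        rng_seed = as.integer(flags$seed %||% "1"))
      jsonlite::write_json(
        list(spread = sens$spread,
             runs = lapply(sens$runs, function(r) {
               r[c("combination", "q", "gains_pct", "losses_pct",
                   "n_projections")]
             })),
        need("out"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
      cli_log("sensitivity over %d runs -> %s", length(sens$runs), flags$out)
    },
    run = function() {
      run_pipeline(need("config"))
      cli_log("pipeline complete")
    },
    NULL)
  if (is.null(run)) {
    message(sprintf("unknown subcommand '%s'\n%s", cmd, usage))
    return(2L)
  }
  res <- tryCatch({ run(); 0L },
    error = function(e) {
      message("error: ", conditionMessage(e))
      # validation-style failures (bad input) exit 2, computation errors 1
      if (grepl("missing|not found|must|unknown|duplicate",
                conditionMessage(e))) 2L else 1L
    })
  res
}
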