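#' Construct and validate a scenario delta table
#'
#' A scenario table holds one row per climate-change scenario. Each scenario
#' is an AOGCM x forcing combination described by regional climate deltas:
#' `dTavg` (additive change in mean annual temperature, degrees C), `dPrec`
#' (relative change in total annual precipitation, percent) and `dPrat`
#' (relative change in useful precipitation, the summer/annual precipitation
#' ratio, percent). Extra delta columns are permitted and carried through.
#'
#' The scenario identity is the `(model, sres)` pair; `center` (the research
#' centre that ran the AOGCM) is metadata only, because a single centre may
#' contribute several models.
#'
#' @param data data.frame with character columns `center`, `model`, `sres`
#'   and at least one numeric delta column.
#' @return `data` with class `scenario_table` and attribute `delta_vars`
#'   naming the delta columns, in input row order.
#' @export
#' @examples
#' tab <- scenario_table(data.frame(
#'   center = "X", model = c("m1", "m2"), sres = "A2",
#'   dTavg = c(1, 2), dPrec = c(5, -5), dPrat = c(0, 1)))
#' delta_vars(tab)
scenario_table <- function(data) {
  data <- as.data.frame(data)
  id_cols <- c("center", "model", "sres")
  missing_ids <- setdiff(id_cols, names(data))
  if (length(missing_ids)) {
    fail("scenario table is missing id column(s): %s",
         paste(missing_ids, collapse = ", "))
  }
  deltas <- setdiff(names(data), id_cols)
  if (!length(deltas)) fail("scenario table has no delta columns")
  for (v in deltas) {
    x <- data[[v]]
    if (!is.numeric(x)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(x)))))
      fail("non-numeric delta value in column '%s' (row %s)", v,
           paste(utils::head(bad, 3), collapse = ", "))
    }
    if (!all(is.finite(x))) {
      fail("non-finite delta value in column '%s' (row %s)", v,
           paste(which(!is.finite(x)), collapse = ", "))
    }
  }
  keys <- make_scenario_keys(data$model, data$sres)
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)]
    fail("duplicate scenario key(s): %s (rows %s)",
         paste(unique(dup), collapse = ", "),
         paste(which(keys %in% dup), collapse = ", "))
  }
  rownames(data) <- NULL
  structure(data, delta_vars = deltas,
            class = c("scenario_table", "data.frame"))
}

#' Names of the delta columns of a scenario table
#' @param table a [scenario_table()].
#' @return character vector of delta column names.
#' @export
delta_vars <- function(table) attr(table, "delta_vars")

#' @export
print.scenario_table <- function(x, ...) {
  cat(sprintf("Scenario delta table: %d scenarios x %d variables (%s)\n",
              nrow(x), length(delta_vars(x)),
              paste(delta_vars(x), collapse = ", ")))
  print(as.data.frame(x), ...)
  invisible(x)
}

# comma/tab auto-detection; explicit `delimiter` wins
detect_delimiter <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) >=
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

#' Read a scenario delta table from delimited text
#'
#' Expects a header row naming `center`, `model`, `sres` (case-insensitive)
#' plus one or more numeric delta columns. The delimiter is auto-detected
#' (comma or tab) unless given explicitly.
#'
#' @param path file path.
#' @param delimiter `NULL` (auto-detect), `","` or `"\t"`.
#' @return a [scenario_table()], preserving file row order.
#' @export
read_scenario_table <- function(path, delimiter = NULL) {
  if (!file.exists(path)) fail("file not found: %s", path)
  sep <- detect_delimiter(path, delimiter)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = NA, fill = FALSE,
                           comment.char = "")
  # case-insensitive id-column matching
  for (id in c("center", "model", "sres")) {
    hit <- which(tolower(names(raw)) == id)
    if (length(hit) == 1L) names(raw)[hit] <- id
  }
  scenario_table(raw)
}

#' Write a scenario table to delimited text
#' @param table a [scenario_table()].
#' @param path output file path.
#' @param delimiter field separator, default comma.
#' @return `path`, invisibly.
#' @export
write_scenario_table <- function(table, path, delimiter = ",") {
  utils::write.table(as.data.frame(table), path, sep = delimiter,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-variable summary of scenario deltas
#'
#' Mean, sample standard deviation (n - 1 denominator, the reporting
#' convention for scenario-ensemble tables), minimum and maximum of every
#' delta column, with the scenario keys attaining the extremes.
#'
#' @param table a [scenario_table()] with at least 2 scenarios.
#' @return data.frame with one row per delta variable and columns
#'   `variable`, `mean`, `sd`, `min`, `max`, `argmin`, `argmax`.
#' @export
summarize_deltas <- function(table) {
  table <- scenario_table(table)
  if (nrow(table) < 2L) {
    fail("need >= 2 scenarios to summarize (sample SD undefined)")
  }
  keys <- scenario_keys(table)
  rows <- lapply(delta_vars(table), function(v) {
    x <- table[[v]]
    data.frame(variable = v, mean = mean(x), sd = sd(x),
               min = min(x), max = max(x),
               argmin = keys[which.min(x)], argmax = keys[which.max(x)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a per-cell table from delimited text
#'
#' Cell tables are the gridded data container: a `cell_id` column of unique
#' opaque identifiers plus numeric per-cell columns. Ragged rows are an
#' error.
#'
#' @param path file path.
#' @param delimiter `NULL` (auto-detect), `","` or `"\t"`.
#' @return data.frame with a character `cell_id` column first.
#' @export
read_cell_table <- function(path, delimiter = NULL) {
  if (!file.exists(path)) fail("file not found: %s", path)
  sep <- detect_delimiter(path, delimiter)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, fill = FALSE,
                           comment.char = "")
  validate_cell_table(tab)
}

validate_cell_table <- function(tab) {
  if (!"cell_id" %in% names(tab)) fail("cell table needs a 'cell_id' column")
  tab$cell_id <- as.character(tab$cell_id)
  if (anyDuplicated(tab$cell_id)) {
    fail("duplicated cell_id: %s",
         paste(unique(tab$cell_id[duplicated(tab$cell_id)]), collapse = ", "))
  }
  tab[c("cell_id", setdiff(names(tab), "cell_id"))]
}

#' Write a per-cell table to delimited text
#'
#' Values round-trip losslessly through [read_cell_table()] at full double
#' precision (17 significant digits).
#'
#' @param table data.frame with a unique `cell_id` column.
#' @param path output file path.
#' @param delimiter field separator, default comma.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path, delimiter = ",") {
  table <- validate_cell_table(table)
  out <- as.data.frame(lapply(table, function(x) {
    if (is.double(x)) sprintf("%.17g", x) else x
  }), stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(out, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
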