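# long-format text serialization of probability stacks

#' Write a probability stack as long-format delimited text
#'
#' One row per (cell, model, scenario) triple with columns `cell_id`,
#' `model_id`, `scenario_id`, `p`, the per-model `auc` (repeated), and any
#' available per-scenario metadata (`scenario_model`, `scenario_sres`,
#' `cluster_size`, repeated). The file is self-contained: [read_stack_csv()]
#' reconstructs the full stack from it.
#'
#' @param stack a [probability_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack_csv <- function(stack, path) {
  d <- dim(stack$prob)
  dn <- dimnames(stack$prob)
  cells <- dn[[1L]] %||% as.character(seq_len(d[1L]))
  models <- dn[[2L]] %||% paste0("m", seq_len(d[2L]))
  scens <- dn[[3L]] %||% paste0("s", seq_len(d[3L]))
  long <- data.frame(
    cell_id = rep(cells, times = d[2L] * d[3L]),
    model_id = rep(rep(models, each = d[1L]), times = d[3L]),
    scenario_id = rep(scens, each = d[1L] * d[2L]),
    p = as.vector(stack$prob),
    auc = rep(rep(stack$model_auc, each = d[1L]), times = d[3L]),
    stringsAsFactors = FALSE)
  scen_rep <- function(x) rep(x, each = d[1L] * d[2L])
  if (!is.null(stack$scenario_model)) {
    long$scenario_model <- scen_rep(stack$scenario_model)
  }
  if (!is.null(stack$scenario_sres)) {
    long$scenario_sres <- scen_rep(stack$scenario_sres)
  }
  if (!is.null(stack$cluster_size)) {
    long$cluster_size <- scen_rep(stack$cluster_size)
  }
  out <- as.data.frame(lapply(long, function(x) {
    if (is.double(x)) sprintf("%.17g", x) else x
  }), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format probability stack
#'
#' Inverse of [write_stack_csv()]. The (cell, model, scenario) index grid
#' must be complete; cells, models and scenarios keep their order of first
#' appearance in the file.
#'
#' @param path file path.
#' @return a [probability_stack()].
#' @export
read_stack_csv <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  long <- utils::read.table(path, header = TRUE, sep = ",",
                            stringsAsFactors = FALSE, fill = FALSE)
  need <- c("cell_id", "model_id", "scenario_id", "p", "auc")
  miss <- setdiff(need, names(long))
  if (length(miss)) {
    fail("stack file is missing column(s): %s", paste(miss, collapse = ", "))
  }
  cells <- unique(long$cell_id)
  models <- unique(long$model_id)
  scens <- unique(long$scenario_id)
  if (nrow(long) != length(cells) * length(models) * length(scens)) {
    fail("incomplete stack: expected %d x %d x %d rows, found %d",
         length(cells), length(models), length(scens), nrow(long))
  }
  prob <- array(NA_real_,
                dim = c(length(cells), length(models), length(scens)),
                dimnames = list(cells, models, scens))
  prob[cbind(match(long$cell_id, cells), match(long$model_id, models),
             match(long$scenario_id, scens))] <- long$p
  if (anyNA(prob)) fail("incomplete stack: duplicated or missing triples")
  per_model <- long[!duplicated(long$model_id), ]
  per_scen <- long[!duplicated(long$scenario_id), ]
  pick <- function(col) {
    if (col %in% names(long)) per_scen[[col]][match(scens,
                                                    per_scen$scenario_id)]
  }
  probability_stack(prob,
                    model_auc = per_model$auc[match(models,
                                                    per_model$model_id)],
                    scenario_model = pick("scenario_model"),
                    scenario_sres = pick("scenario_sres"),
                    cluster_size = pick("cluster_size"))
}
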