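# Readers/writers for the delimited-text formats the pipeline exchanges:
# omics matrices (samples x features, first column = sample ID, header =
# feature IDs), label tables, edge lists, YAML run configs and JSON metrics.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0L) "\t" else ","
}

#' Read an omics matrix from delimited text
#'
#' Expects samples x features orientation: first column sample identifiers,
#' header row feature identifiers. Delimiter (tab or comma) is auto-detected
#' unless given.
#'
#' @param path file path.
#' @param sep `"\t"`, `","`, or NULL to auto-detect.
#' @return numeric matrix with sample rownames and feature colnames.
#' @export
read_omics_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in ", path)
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Write an omics matrix as delimited text
#' @param X samples x features matrix with dimnames.
#' @param path output path.
#' @param sep delimiter (default tab).
#' @export
write_omics_matrix <- function(X, path, sep = "\t") {
  df <- data.frame(sample_id = rownames(X) %||% paste0("s", seq_len(nrow(X))),
                   X, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-label table (columns: sample_id, label)
#' @param path file path.
#' @param sep delimiter or NULL to auto-detect.
#' @return labels named by sample identifier.
#' @export
read_labels <- function(path, sep = NULL) {
  sep <- sep %||% detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  y <- df[[2L]]
  names(y) <- as.character(df[[1L]])
  y
}

#' Write a sample-label table
#' @param y labels named by sample identifier.
#' @param path output path.
#' @export
write_labels <- function(y, path) {
  utils::write.table(
    data.frame(sample_id = names(y) %||% seq_along(y), label = unname(y)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge list (columns: source, target, optional score)
#' @param path file path.
#' @param sep delimiter or NULL to auto-detect.
#' @return data.frame.
#' @export
read_edge_list <- function(path, sep = NULL) {
  sep <- sep %||% detect_sep(path)
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

#' Write an edge list
#' @param edges data.frame (e.g. from [graph_to_edges()]).
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' Serialize an evaluation report (or any metrics list) to JSON
#'
#' Output is deterministic for a given report: no timestamps, stable key
#' order, full numeric precision; the config echo (including every seed) is
#' embedded so a run can be reproduced from its output alone.
#'
#' @param report an `eval_report` or plain list.
#' @param path output path.
#' @export
write_metrics_json <- function(report, path) {
  x <- unclass(report)
  if (!is.null(x$per_repeat)) x$per_repeat <- as.data.frame(x$per_repeat)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read back a metrics JSON file
#' @param path JSON file.
#' @return named list.
#' @export
read_metrics_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
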