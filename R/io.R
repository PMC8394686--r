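#' Read a multichannel panel from delimited text
#'
#' Expects one header row of channel names and one row per time point;
#' comma or tab delimiter is auto-detected from the header line. Malformed
#' input is rejected with the offending location: non-numeric or missing
#' cells are reported with their data row number and column label, ragged
#' rows and duplicate labels with their position.
#'
#' @param path file path.
#' @return a [ts_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      colClasses = "character", comment.char = "",
                      quote = "\""),
    error = function(e) stop("malformed panel file ", path, ": ",
                             conditionMessage(e)))
  labels <- names(df)
  if (anyDuplicated(labels))
    stop("duplicate channel label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  M <- matrix(NA_real_, nrow(df), ncol(df))
  for (col in seq_along(df)) {
    raw <- trimws(df[[col]])
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad)) {
      shown <- if (raw[bad[1]] == "" || is.na(df[[col]][bad[1]]))
        "missing value" else paste0("non-numeric value '", raw[bad[1]], "'")
      stop(shown, " at row ", bad[1], ", column '", labels[col], "'")
    }
    M[, col] <- val
  }
  ts_panel(M, labels = labels)
}

#' Write a panel as delimited text
#'
#' Emits the same dialect [read_panel()] accepts: a header of channel names
#' and one row per time point, at full precision.
#'
#' @param panel a [ts_panel()].
#' @param path file path.
#' @param sep `","` (default) or `"\t"`.
#' @return invisibly, `path`.
#' @export
write_panel <- function(panel, path, sep = ",") {
  df <- as.data.frame(unclass(as.matrix(panel)))
  names(df) <- colnames(panel)
  fmt <- vapply(df, function(x) format(x, digits = 17, trim = TRUE,
                                       scientific = FALSE),
                character(nrow(df)))
  utils::write.table(fmt, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = colnames(panel))
  invisible(path)
}

#' Write / read a VAR model as structured text
#'
#' Serializes n, p, labels, the coefficient stack A (list of p n x n
#' matrices, row-major nested lists) and Sigma as YAML, so benchmark models
#' are inspectable and hand-editable.
#'
#' @param model a [var_model()].
#' @param path file path.
#' @return `write_var_model` returns `path` invisibly; `read_var_model`
#'   returns the reconstructed [var_model()].
#' @export
write_var_model <- function(model, path) {
  obj <- list(
    n = model$n, p = model$p, labels = as.list(model$labels),
    A = lapply(seq_len(model$p), function(r)
      lapply(seq_len(model$n), function(i) as.list(model$A[i, , r]))),
    Sigma = lapply(seq_len(model$n), function(i) as.list(model$Sigma[i, ])))
  writeLines(yaml::as.yaml(obj, precision = 17L), path)
  invisible(path)
}

#' @rdname write_var_model
#' @export
read_var_model <- function(path) {
  obj <- yaml::read_yaml(path)
  n <- obj$n; p <- obj$p
  A <- array(0, dim = c(n, n, p))
  for (r in seq_len(p))
    A[, , r] <- do.call(rbind, lapply(obj$A[[r]], unlist))
  Sigma <- do.call(rbind, lapply(obj$Sigma, unlist))
  var_model(A, Sigma = Sigma, labels = unlist(obj$labels),
            check_stationary = FALSE)
}

#' Write a graph as a TSV edge list
#'
#' Columns source, target, weight; an empty graph yields a header-only
#' file. Byte-identical output for identical graphs.
#'
#' @param graph a [causal_graph()].
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_edges <- function(graph, path) {
  stopifnot(inherits(graph, "causal_graph"))
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plain-list form of a scan report
#'
#' The JSON-serializable structure written by [write_report()]: schema
#' version, method, per-step omitted sets, edge lists, important nodes and
#' feedback pairs, and the hidden-hub evidence summary.
#'
#' @param report a [subnetwork_scan()] result.
#' @return a nested list.
#' @export
report_to_list <- function(report) {
  ev <- hidden_hub_evidence(report)
  list(
    schema_version = as.character(utils::packageVersion("gcnet")),
    method = report$method,
    steps = lapply(report$steps, function(st) list(
      omitted = as.list(st$omitted),
      nodes = as.list(st$graph$nodes),
      edges = lapply(seq_len(nrow(st$graph$edges)), function(e) list(
        source = st$graph$edges$source[e],
        target = st$graph$edges$target[e],
        weight = st$graph$edges$weight[e])),
      important_nodes = as.list(st$important_nodes),
      feedback_pairs = lapply(seq_len(nrow(st$feedback_pairs)), function(r)
        as.list(unname(st$feedback_pairs[r, ]))))),
    hidden_evidence = list(
      flag = ev$flag,
      common_nodes = as.list(ev$common_nodes),
      union_nodes = as.list(ev$union_nodes)))
}

#' Write / read a scan report as JSON
#'
#' @param report a [subnetwork_scan()] result.
#' @param path file path.
#' @return `write_report` returns `path` invisibly; `read_report` returns
#'   the parsed list in the exact shape of [report_to_list()].
#' @export
write_report <- function(report, path) {
  json <- jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
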