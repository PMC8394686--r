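#' Configuration for inference and sub-network scanning
#'
#' Bundles the knobs shared by [infer_graph()], [subnetwork_scan()] and the
#' benchmark harness.
#'
#' @param method `"rpdc"` or `"dpc"`.
#' @param order VAR order policy: a fixed integer, or `"aic"`/`"bic"` to
#'   select over `1..p_max` per panel (default `"bic"`).
#' @param p_max largest order tried under criterion-based selection
#'   (default 5).
#' @param alpha significance level (default 0.05).
#' @param B surrogate count for DPC (default 1000, the harness scale;
#'   single analyses may prefer 10000).
#' @param n_freq rPDC grid size (default 64).
#' @param rule rPDC significance rule (default `"all_frequencies"`).
#' @param depth maximum number of removal steps in a scan (default 3).
#' @param min_channels smallest sub-network analysed (default 3; with two
#'   channels partialization degenerates).
#' @param seed optional integer seed.
#' @return a `scan_config` list.
#' @export
scan_config <- function(method = c("rpdc", "dpc"), order = "bic", p_max = 5L,
                        alpha = 0.05, B = 1000L, n_freq = 64L,
                        rule = "all_frequencies", depth = 3L,
                        min_channels = 3L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1, min_channels >= 3, depth >= 0)
  if (method == "dpc" && B < 100) stop("DPC requires B >= 100")
  structure(list(method = method, order = order, p_max = as.integer(p_max),
                 alpha = alpha, B = as.integer(B), n_freq = as.integer(n_freq),
                 rule = rule, depth = as.integer(depth),
                 min_channels = as.integer(min_channels), seed = seed),
            class = "scan_config")
}

resolve_order <- function(panel, config) {
  if (is.numeric(config$order)) return(as.integer(config$order))
  select_order(panel, p_max = config$p_max, criterion = config$order)
}

#' Infer a significant-edge graph from a panel
#'
#' Single-shot inference with either method under a [scan_config()]:
#' resolves the VAR order, fits, computes the causal measure and its
#' significance, and returns the edge graph.
#'
#' @param panel a [ts_panel()].
#' @param config a [scan_config()]; `config$method` picks the measure.
#' @return a [causal_graph()].
#' @export
infer_graph <- function(panel, config = scan_config()) {
  p <- resolve_order(panel, config)
  if (config$method == "rpdc") {
    rpdc_analysis(panel, p, n_freq = config$n_freq, alpha = config$alpha,
                  rule = config$rule)$graph
  } else {
    dpc_analysis(panel, p, B = config$B, alpha = config$alpha)$graph
  }
}

#' Systematic sub-network scan
#'
#' Step 0 infers a graph on all observed channels. Each subsequent step
#' removes the current important nodes (all nodes tied at the maximal
#' out-degree are removed together), refits from scratch on the remaining
#' channels, re-infers, and records the reciprocal (feedback) pairs. The
#' scan stops when no node is important, fewer than `min_channels` channels
#' would remain, `depth` removal steps have been taken, or inference fails
#' (the failure is recorded and the scan ends gracefully).
#'
#' @param panel a [ts_panel()] with at least 3 channels.
#' @param config a [scan_config()]; its `seed`, if set, makes the whole scan
#'   reproducible.
#' @return object of class `scan_report`: `steps`, a list whose elements
#'   carry `omitted` (cumulative omitted labels), `graph`,
#'   `important_nodes`, `feedback_pairs`; plus `method`, `config`, and
#'   `error` (NULL or the message that stopped the scan).
#' @export
subnetwork_scan <- function(panel, config = scan_config()) {
  stopifnot(ncol(panel) >= 3)
  if (!is.null(config$seed)) set.seed(config$seed)
  current <- ts_panel(as.matrix(panel))
  omitted <- character(0)
  steps <- list()
  error <- NULL
  for (step in 0:config$depth) {
    graph <- tryCatch(infer_graph(current, config), error = function(e) e)
    if (inherits(graph, "error")) {
      error <- conditionMessage(graph)
      break
    }
    imp <- important_nodes(graph)
    steps[[length(steps) + 1L]] <- list(
      omitted = omitted, graph = graph, important_nodes = imp,
      feedback_pairs = two_cycles(graph))
    if (length(imp) == 0) break
    remaining <- setdiff(colnames(current), imp)
    if (length(remaining) < config$min_channels || step == config$depth) break
    omitted <- c(omitted, imp)
    current <- panel_subset(current, remaining)
  }
  structure(list(steps = steps, method = config$method, config = config,
                 error = error),
            class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat("<scan_report> method = ", x$method, ", ", length(x$steps),
      " step(s)\n", sep = "")
  for (s in seq_along(x$steps)) {
    st <- x$steps[[s]]
    cat("  step ", s - 1, ": omitted {",
        paste(st$omitted, collapse = ","), "}, ",
        nrow(st$graph$edges), " edges, important {",
        paste(st$important_nodes, collapse = ","), "}, feedback ",
        nrow(st$feedback_pairs), "\n", sep = "")
  }
  if (!is.null(x$error)) cat("  stopped on error: ", x$error, "\n", sep = "")
  invisible(x)
}

#' Hidden-hub evidence from a scan report
#'
#' The evidence flag is raised iff any scan step exhibits at least one
#' feedback (reciprocal) pair. The candidate influenced set is the union of
#' all nodes participating in feedback pairs; when two or more steps show
#' feedback, the nodes common to every such step are additionally isolated
#' (the commonly driven nodes). Nodes that gained outgoing links relative to
#' the previous step are listed per step for side-by-side reporting.
#'
#' @param report a [subnetwork_scan()] result.
#' @return object of class `hub_evidence`: `flag` (logical),
#'   `common_nodes`, `union_nodes` (character vectors), and
#'   `gained_out_links` (list, per step from step 1 on).
#' @export
hidden_hub_evidence <- function(report) {
  stopifnot(inherits(report, "scan_report"))
  per_step <- lapply(report$steps, function(st)
    unique(as.character(st$feedback_pairs)))
  with_fb <- per_step[vapply(per_step, length, integer(1)) > 0]
  flag <- length(with_fb) > 0
  union_nodes <- sort(unique(as.character(unlist(with_fb))))
  common_nodes <- if (length(with_fb) >= 2) sort(Reduce(intersect, with_fb))
                  else union_nodes
  gained <- list()
  if (length(report$steps) >= 2) {
    for (s in 2:length(report$steps)) {
      prev <- report$steps[[s - 1]]$graph
      cur <- report$steps[[s]]$graph
      shared <- intersect(prev$nodes, cur$nodes)
      key <- function(e) paste(e$source, e$target, sep = "\r")
      pe <- prev$edges[prev$edges$source %in% shared &
                       prev$edges$target %in% shared, , drop = FALSE]
      ce <- cur$edges[cur$edges$source %in% shared &
                       cur$edges$target %in% shared, , drop = FALSE]
      new_edges <- ce[!key(ce) %in% key(pe), , drop = FALSE]
      gained[[s - 1]] <- sort(unique(new_edges$source))
    }
  }
  structure(list(flag = flag, common_nodes = common_nodes,
                 union_nodes = union_nodes, gained_out_links = gained),
            class = "hub_evidence")
}

#' @export
print.hub_evidence <- function(x, ...) {
  cat("<hub_evidence> flag = ", x$flag, sep = "")
  if (x$flag)
    cat("; common {", paste(x$common_nodes, collapse = ","),
        "}, union {", paste(x$union_nodes, collapse = ","), "}", sep = "")
  cat("\n")
  invisible(x)
}
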