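#' Multichannel time-series panel
#'
#' Container for a T x n block of observations, one row per time point and
#' one column per channel. All inference functions in gcnet consume panels.
#'
#' @param values numeric matrix (or object coercible to one), T rows, n
#'   columns. Column names, if present, become the channel labels.
#' @param labels optional character vector of n unique channel names;
#'   defaults to the column names of `values` or `X1..Xn`.
#' @return An object of class `ts_panel`: the numeric matrix with labels as
#'   column names and attribute-free numeric storage.
#' @export
ts_panel <- function(values, labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L) stop("panel must contain at least one time point")
  if (anyNA(values) || any(!is.finite(values)))
    stop("panel contains missing or non-finite entries")
  if (is.null(labels)) labels <- colnames(values)
  if (is.null(labels)) labels <- paste0("X", seq_len(ncol(values)))
  labels <- as.character(labels)
  if (length(labels) != ncol(values))
    stop("number of labels (", length(labels), ") does not match channel count (",
         ncol(values), ")")
  if (anyDuplicated(labels))
    stop("channel labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  dimnames(values) <- list(NULL, labels)
  structure(values, class = c("ts_panel", "matrix", "array"))
}

#' @export
print.ts_panel <- function(x, ...) {
  cat("<ts_panel> ", nrow(x), " time points x ", ncol(x), " channels: ",
      paste(colnames(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of time points / channels of a panel
#' @param panel a `ts_panel`
#' @return integer
#' @export
panel_length <- function(panel) nrow(panel)

#' @rdname panel_length
#' @export
panel_channels <- function(panel) colnames(panel)

#' Select a subset of channels
#'
#' @param panel a `ts_panel`
#' @param keep character vector of labels (or integer indices) to retain.
#' @return a `ts_panel` with the selected columns, in the requested order.
#' @export
panel_subset <- function(panel, keep) {
  if (is.character(keep)) {
    missing <- setdiff(keep, colnames(panel))
    if (length(missing))
      stop("unknown channel(s): ", paste(missing, collapse = ", "))
  }
  ts_panel(unclass(panel)[, keep, drop = FALSE])
}

#' Drop channels from a panel
#' @param panel a `ts_panel`
#' @param drop labels of channels to remove.
#' @return a `ts_panel` without the dropped columns.
#' @export
panel_drop <- function(panel, drop) {
  panel_subset(panel, setdiff(colnames(panel), as.character(drop)))
}

#' Subtract each channel's sample mean
#' @param panel a `ts_panel`
#' @return centered `ts_panel`
#' @export
panel_center <- function(panel) {
  ts_panel(scale(unclass(panel), center = TRUE, scale = FALSE),
           labels = colnames(panel))
}
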