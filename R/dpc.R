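#' Directed partial correlation from a VAR fit
#'
#' Rescales the least-squares VAR coefficients into directed partial
#' correlations (DPC): for source j, target i and lag h > 0,
#' \deqn{\hat\pi_{ij}(h) = \hat A_{ij}(h) / \sqrt{\hat\Sigma_{ii}\,
#'       \hat\rho_{jj}(h)},}
#' \deqn{\hat\rho_{jj}(h) = \hat K_{jj} + \sum_{\nu=1}^{h-1} \sum_{k,l}
#'       \hat A_{kj}(\nu) \hat K_{kl} \hat A_{lj}(\nu)
#'       + \hat A_{ij}(h)^2 / \hat\Sigma_{ii},}
#' where \eqn{\hat K = \hat\Sigma^{-1}}. The value is the correlation between
#' X_i(t) and X_j(t-h) after removing the linear effects of all other
#' channels; with this normalization \eqn{|\hat\pi| < 1} whenever
#' \eqn{\hat\Sigma} is positive definite. Negative lags carry no extra
#' information (\eqn{\pi_{ij}(-h) = \pi_{ij}(h)}); see [dpc_value()].
#'
#' @param fit a [fit_var()] result with invertible `SigmaHat`.
#' @param form `"division"` (default, the normalized correlation above) or
#'   `"product"` (the literal un-normalized rescaling
#'   \eqn{\hat A_{ij}(h)\sqrt{\hat\Sigma_{ii}\hat\rho_{jj}(h)}}, kept only
#'   for comparison).
#' @return object of class `dpc_result`: `pi` (n x n x p array,
#'   `pi[i, j, h]` = DPC of j -> i at lag h), `p`, `labels`, `form`.
#' @export
compute_dpc <- function(fit, form = c("division", "product")) {
  form <- match.arg(form)
  stopifnot(inherits(fit, "var_fit"))
  n <- fit$n; p <- fit$p
  rc <- rcond(fit$SigmaHat)
  if (!is.finite(rc) || rc < 1e-12)
    stop("residual covariance is numerically singular; DPC undefined")
  K <- solve(fit$SigmaHat)
  sig_ii <- diag(fit$SigmaHat)
  A <- fit$Ahat
  # cumulative quadratic term of rho_jj(h): sum_{nu < h} diag(A(nu)' K A(nu))
  cumquad <- matrix(0, n, p)            # [j, h]
  if (p > 1) {
    for (h in 2:p) {
      Anu <- A[, , h - 1]
      cumquad[, h] <- cumquad[, h - 1] + diag(t(Anu) %*% K %*% Anu)
    }
  }
  pi_arr <- array(0, dim = c(n, n, p),
                  dimnames = list(fit$labels, fit$labels, NULL))
  for (h in seq_len(p)) {
    Ah <- A[, , h]
    # rho[i, j] = K_jj + cumquad[j, h] + A_ij(h)^2 / Sigma_ii
    rho <- outer(rep(1, n), diag(K) + cumquad[, h]) + Ah^2 / sig_ii
    pi_arr[, , h] <- if (form == "division") Ah / sqrt(sig_ii * rho)
                     else Ah * sqrt(sig_ii * rho)
  }
  structure(list(pi = pi_arr, p = p, labels = fit$labels, form = form),
            class = "dpc_result")
}

#' @export
print.dpc_result <- function(x, ...) {
  cat("<dpc_result> ", length(x$labels), " channels, ", x$p, " lag(s), ",
      x$form, " form\n", sep = "")
  invisible(x)
}

#' DPC value at a (possibly negative) lag
#'
#' Reports \eqn{\pi_{ij}(h)} with the stated symmetry
#' \eqn{\pi_{ij}(h) = \pi_{ij}(-h)} for h < 0.
#'
#' @param result a [compute_dpc()] result.
#' @param i,j target and source channel (label or index).
#' @param h nonzero lag with |h| <= p.
#' @return scalar DPC value.
#' @export
dpc_value <- function(result, i, j, h) {
  h <- as.integer(h)
  if (h == 0L || abs(h) > result$p)
    stop("lag must be nonzero with |h| <= p = ", result$p)
  result$pi[i, j, abs(h)]
}

#' AAFT surrogate of a panel
#'
#' Per channel: (a) the series is rank-remapped onto an ordered Gaussian
#' sample, (b) the Fourier phases of the Gaussianized series are randomized
#' independently (amplitudes and Hermitian symmetry preserved), (c) the
#' result is rank-remapped back onto the original amplitudes. The
#' spectrum/amplitude adjustment is then iterated until the relative spectral
#' mismatch stops improving. Each surrogate channel is an exact permutation
#' of the observed channel; phases are drawn independently per channel, so
#' cross-channel dependence is destroyed and the surrogate serves as a
#' no-causality null.
#'
#' @param panel a [ts_panel()] with at least 8 time points and no constant
#'   channel.
#' @param seed optional integer seed (otherwise the current RNG state is
#'   used, e.g. inside a bootstrap loop).
#' @param max_iter iteration cap for the spectral refinement (default 100).
#' @param tol relative spectral-improvement threshold that stops the
#'   refinement (default 1e-4).
#' @return a [ts_panel()] of the same dimensions and labels.
#' @export
aaft_surrogate <- function(panel, seed = NULL, max_iter = 100L, tol = 1e-4) {
  X <- as.matrix(panel)
  if (nrow(X) < 8) stop("AAFT surrogate requires at least 8 time points")
  if (!is.null(seed)) set.seed(seed)
  ts_panel(cpp_aaft_panel(X, as.integer(max_iter), tol),
           labels = colnames(X))
}

#' Percentile-bootstrap order-statistic indices
#'
#' For B ascending surrogate values, the endpoints of the percentile
#' interval are the (alpha B)-th and ((1 - alpha) B)-th order statistics
#' (non-integer products are floored); e.g. B = 10000, alpha = 0.05 gives
#' the 500th and 9500th sorted values.
#'
#' @param B surrogate count with `B * alpha >= 1`.
#' @param alpha significance level in (0, 0.5).
#' @return integer vector `c(lo, hi)` of 1-based indices.
#' @export
bootstrap_indices <- function(B, alpha) {
  stopifnot(alpha > 0, alpha < 0.5)
  if (B * alpha < 1)
    stop("B * alpha must be >= 1 (got B = ", B, ", alpha = ", alpha, ")")
  c(lo = as.integer(floor(alpha * B)),
    hi = as.integer(floor((1 - alpha) * B)))
}

#' AAFT-surrogate bootstrap confidence intervals for DPC
#'
#' Generates B AAFT surrogates of the panel (one surrogate set shared by all
#' edges), refits the VAR[p] on each, recomputes the DPC, and per
#' (target, source, lag) cell takes the [bootstrap_indices()] order
#' statistics of the ascending surrogate sample as the interval endpoints.
#' Surrogate fits that fail numerically are discarded and redrawn (bounded
#' retries).
#'
#' @param panel a [ts_panel()].
#' @param p VAR order used for the original and every surrogate fit.
#' @param B number of surrogates (default 10000; >= 1000 recommended,
#'   >= 100 required).
#' @param alpha significance level (default 0.05).
#' @param seed optional integer seed; identical seeds give identical
#'   intervals.
#' @param bonferroni if TRUE, divide alpha by the number of tested cells
#'   n(n-1)p before taking order statistics (off by default; the per-value
#'   test applies no multiplicity correction).
#' @param max_iter,tol AAFT refinement controls, see [aaft_surrogate()].
#' @param divisor passed to [fit_var()].
#' @return object of class `dpc_ci`: arrays `lo`, `hi` (n x n x p), `B`,
#'   `alpha`, `alpha_used`, `seed`, `p`, `labels`, `n_failed` (number of
#'   redrawn surrogates).
#' @export
dpc_bootstrap_ci <- function(panel, p, B = 10000L, alpha = 0.05, seed = NULL,
                             bonferroni = FALSE, max_iter = 100L, tol = 1e-4,
                             divisor = "T") {
  stopifnot(B >= 100)
  X <- as.matrix(panel)
  n <- ncol(X)
  labels <- colnames(X)
  if (is.null(labels)) labels <- paste0("X", seq_len(n))
  alpha_used <- if (bonferroni) alpha / (n * (n - 1) * p) else alpha
  idx <- bootstrap_indices(B, alpha_used)
  if (!is.null(seed)) set.seed(seed)
  ncell <- n * n * p
  samples <- matrix(NA_real_, B, ncell)
  n_failed <- 0L
  for (r in seq_len(B)) {
    for (attempt in seq_len(20L)) {
      val <- tryCatch({
        surr <- cpp_aaft_panel(X, as.integer(max_iter), tol)
        sfit <- fit_var(surr, p, divisor = divisor)
        as.numeric(compute_dpc(sfit)$pi)
      }, error = function(e) e)
      if (!inherits(val, "error")) break
      n_failed <- n_failed + 1L
      if (attempt == 20L)
        stop("surrogate fitting failed 20 times in a row: ",
             conditionMessage(val))
    }
    samples[r, ] <- val
  }
  if (n_failed > 0)
    message("dpc_bootstrap_ci: ", n_failed, " surrogate fit(s) redrawn")
  lo <- hi <- array(NA_real_, dim = c(n, n, p),
                    dimnames = list(labels, labels, NULL))
  for (cc in seq_len(ncell)) {
    srt <- sort.int(samples[, cc], method = "quick")
    lo[cc] <- srt[idx["lo"]]
    hi[cc] <- srt[idx["hi"]]
  }
  structure(list(lo = lo, hi = hi, B = as.integer(B), alpha = alpha,
                 alpha_used = alpha_used, seed = seed, p = as.integer(p),
                 labels = labels, n_failed = n_failed),
            class = "dpc_ci")
}

#' Significant-edge graph from DPC values and bootstrap intervals
#'
#' An edge j -> i is declared present iff \eqn{\hat\pi_{ij}(h)} falls outside
#' its surrogate interval [lo, hi] for at least one lag h; the edge weight is
#' the largest |DPC| over the significant lags. Self-edges are excluded.
#'
#' @param result a [compute_dpc()] result.
#' @param ci a [dpc_bootstrap_ci()] built from the same panel and order.
#' @return a [causal_graph()].
#' @export
dpc_significance <- function(result, ci) {
  stopifnot(inherits(result, "dpc_result"), inherits(ci, "dpc_ci"))
  if (result$p != ci$p || !identical(result$labels, ci$labels))
    stop("DPC result and bootstrap CI dimensions do not match")
  n <- length(result$labels)
  sig <- result$pi < ci$lo | result$pi > ci$hi    # n x n x p
  edges <- data.frame(source = character(0), target = character(0),
                      weight = numeric(0))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    hs <- which(sig[i, j, ])
    if (length(hs))
      edges <- rbind(edges, data.frame(
        source = result$labels[j], target = result$labels[i],
        weight = max(abs(result$pi[i, j, hs]))))
  }
  causal_graph(result$labels, edges)
}

#' Full DPC analysis of a panel
#'
#' Convenience wrapper: fits the VAR, computes the DPC, builds the AAFT
#' surrogate bootstrap intervals, and extracts the significant-edge graph.
#'
#' @inheritParams dpc_bootstrap_ci
#' @param center passed to [fit_var()].
#' @return object of class `dpc_analysis`: `fit`, `result`, `ci`, `graph`,
#'   and the configuration used.
#' @export
dpc_analysis <- function(panel, p, B = 10000L, alpha = 0.05, seed = NULL,
                         bonferroni = FALSE, divisor = "T", center = FALSE,
                         max_iter = 100L, tol = 1e-4) {
  fit <- fit_var(panel, p, divisor = divisor, center = center)
  result <- compute_dpc(fit)
  ci <- dpc_bootstrap_ci(panel, p, B = B, alpha = alpha, seed = seed,
                         bonferroni = bonferroni, max_iter = max_iter,
                         tol = tol, divisor = divisor)
  structure(list(fit = fit, result = result, ci = ci,
                 graph = dpc_significance(result, ci),
                 p = p, B = B, alpha = alpha, seed = seed),
            class = "dpc_analysis")
}

#' Tabulate DPC values, intervals and significance
#'
#' @param result a [compute_dpc()] result.
#' @param ci the matching [dpc_bootstrap_ci()].
#' @return data.frame with columns source, target, lag, dpc_value, ci_lo,
#'   ci_hi, significant (0/1); one row per ordered pair and lag,
#'   self-pairs excluded.
#' @export
dpc_edge_table <- function(result, ci) {
  stopifnot(result$p == ci$p, identical(result$labels, ci$labels))
  n <- length(result$labels)
  rows <- expand.grid(i = seq_len(n), j = seq_len(n), h = seq_len(result$p))
  rows <- rows[rows$i != rows$j, , drop = FALSE]
  idx <- cbind(rows$i, rows$j, rows$h)
  out <- data.frame(
    source = result$labels[rows$j], target = result$labels[rows$i],
    lag = rows$h, dpc_value = result$pi[idx],
    ci_lo = ci$lo[idx], ci_hi = ci$hi[idx])
  out$significant <- as.integer(out$dpc_value < out$ci_lo |
                                out$dpc_value > out$ci_hi)
  out[order(out$source, out$target, out$lag), , drop = FALSE]
}
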