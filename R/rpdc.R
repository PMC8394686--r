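#' Angular frequency grid in (0, pi)
#'
#' Equally spaced angular frequencies strictly inside (0, pi), the default
#' evaluation grid for rPDC spectra.
#'
#' @param n_freq number of frequencies (default 64).
#' @return strictly increasing numeric vector of length `n_freq`.
#' @export
frequency_grid <- function(n_freq = 64L) {
  stopifnot(n_freq >= 1)
  pi * seq_len(n_freq) / (n_freq + 1)
}

check_grid <- function(omegas) {
  omegas <- as.numeric(omegas)
  if (length(omegas) == 0) stop("frequency grid is empty")
  if (any(omegas <= 0) || any(omegas >= pi))
    stop("frequencies must lie strictly inside (0, pi)")
  if (is.unsorted(omegas, strictly = TRUE))
    stop("frequency grid must be strictly increasing")
  omegas
}

#' Fourier transform of VAR coefficients
#'
#' \deqn{A(\omega) = I - \sum_{r=1}^{p} \hat A(r) e^{-i \omega r}.}
#'
#' @param fit a [fit_var()] result.
#' @param omegas angular frequencies in (0, pi) (default [frequency_grid()]).
#' @return complex array n x n x length(omegas).
#' @export
fourier_coefficients <- function(fit, omegas = frequency_grid()) {
  stopifnot(inherits(fit, "var_fit"))
  omegas <- check_grid(omegas)
  n <- fit$n; p <- fit$p
  out <- array(0i, dim = c(n, n, length(omegas)),
               dimnames = list(fit$labels, fit$labels, NULL))
  I <- diag(n)
  for (w in seq_along(omegas)) {
    Aw <- I + 0i
    for (r in seq_len(p))
      Aw <- Aw - fit$Ahat[, , r] * exp(-1i * omegas[w] * r)
    out[, , w] <- Aw
  }
  out
}

#' Real/imaginary coordinate vector of one transfer entry
#'
#' @param Aw a single complex n x n matrix A(omega), e.g. one slice of
#'   [fourier_coefficients()].
#' @param k,j target and source channel (label or index), k != j.
#' @return numeric 2-vector (Re A_kj, Im A_kj).
#' @export
z_vector <- function(Aw, k, j) {
  if (identical(k, j))
    stop("self-influence (k = j) is not defined for rPDC edges")
  a <- Aw[k, j]
  c(Re(a), Im(a))
}

# p x p block of Rp^{-1} belonging to source channel j:
# entries ((l-1)n + j, (m-1)n + j), l, m = 1..p
source_block <- function(Rp_inv, j, n, p) {
  idx <- (seq_len(p) - 1L) * n + j
  Rp_inv[idx, idx, drop = FALSE]
}

#' Asymptotic covariance of the transfer-entry coordinates
#'
#' Covariance (up to the 1/N factor) of
#' \eqn{(\mathrm{Re}\,\hat A_{kj}(\omega), \mathrm{Im}\,\hat A_{kj}(\omega))}
#' induced by the least-squares coefficient covariance
#' \eqn{\mathrm{Cov}(\hat A_{kj}(l), \hat A_{kj}(m)) =
#'   \Sigma_{kk} [R_p^{-1}]_{jj}(l,m) / N}:
#' \deqn{V_{kj}(\omega) = \Sigma_{kk} \sum_{l,m=1}^{p} H_{jj}(l,m)
#'   \begin{pmatrix} \cos l\omega \cos m\omega & -\cos l\omega \sin m\omega\\
#'   -\sin l\omega \cos m\omega & \sin l\omega \sin m\omega \end{pmatrix},}
#' where \eqn{H_{jj}} is the source-j block pattern of \eqn{R_p^{-1}}. The
#' off-diagonal minus sign follows from
#' \eqn{\mathrm{Re}\,A_{kj} = -\sum_r \hat A_{kj}(r)\cos r\omega} while
#' \eqn{\mathrm{Im}\,A_{kj} = +\sum_r \hat A_{kj}(r)\sin r\omega}; it keeps
#' the quadratic form chi-squared calibrated. The covariance used downstream
#' is V/N with N the number of points entering the fit.
#'
#' @param fit a [fit_var()] result with invertible `Rp`.
#' @param k,j target and source channel, k != j.
#' @param omega a single angular frequency.
#' @return 2 x 2 symmetric matrix. For p = 1 the matrix is rank 1 by
#'   construction (a trigonometric outer product); [compute_rpdc()] then
#'   uses its pseudo-inverse.
#' @export
z_covariance <- function(fit, k, j, omega) {
  stopifnot(inherits(fit, "var_fit"))
  if (identical(k, j)) stop("self-influence (k = j) has no rPDC covariance")
  rc <- rcond(fit$Rp)
  if (!is.finite(rc) || rc < 1e-12)
    stop("lag-covariance matrix is numerically singular")
  n <- fit$n; p <- fit$p
  ki <- if (is.character(k)) match(k, fit$labels) else as.integer(k)
  ji <- if (is.character(j)) match(j, fit$labels) else as.integer(j)
  H <- source_block(solve(fit$Rp), ji, n, p)
  cl <- cos(seq_len(p) * omega)
  sl <- sin(seq_len(p) * omega)
  skk <- fit$SigmaHat[ki, ki]
  skk * rbind(c(drop(cl %*% H %*% cl), -drop(cl %*% H %*% sl)),
              c(-drop(sl %*% H %*% cl), drop(sl %*% H %*% sl)))
}

# quadratic form z' V^+ z for a symmetric 2x2 V, with the rank used
quad_form_pinv <- function(V, z, rel_tol = 1e-10) {
  a <- V[1, 1]; b <- V[2, 2]; d <- V[1, 2]
  tr <- a + b
  det <- a * b - d * d
  if (tr <= 0) return(list(stat = 0, rank = 0L))
  if (det > rel_tol * tr * tr) {
    stat <- (b * z[1]^2 - 2 * d * z[1] * z[2] + a * z[2]^2) / det
    list(stat = stat, rank = 2L)
  } else {
    # rank 1: V = tr * u u', pinv = V / tr^2
    stat <- (a * z[1]^2 + 2 * d * z[1] * z[2] + b * z[2]^2) / (tr * tr)
    list(stat = stat, rank = 1L)
  }
}

#' Renormalized partial directed coherence
#'
#' For every ordered pair (target k, source j), k != j, and every grid
#' frequency, computes the Wald-type statistic
#' \deqn{\hat\lambda_{kj}(\omega) = \hat Z_{kj}(\omega)^T
#'   V_{kj}(\omega)^{-1} \hat Z_{kj}(\omega)}
#' with Z the (Re, Im) coordinates of the transfer entry and V the
#' coefficient-induced covariance ([z_covariance()]). Where V is rank
#' deficient (always at p = 1) the Moore-Penrose pseudo-inverse is used and
#' the rank is recorded so the significance test can reduce its degrees of
#' freedom. Under no influence j -> k, N lambda is asymptotically
#' chi-squared with 2 (or rank) degrees of freedom, N = T - p.
#'
#' @param fit a [fit_var()] result.
#' @param omegas angular frequency grid (default [frequency_grid()]).
#' @param alpha significance level stored with the result (default 0.05).
#' @return object of class `rpdc_result`: `lam` (n x n x n_freq,
#'   `lam[k, j, w]` >= 0), `rank` (same shape), `omegas`, `N`, `alpha`,
#'   `critical` (= chi^2_{2, 1-alpha} / N), `labels`, `p`.
#' @export
compute_rpdc <- function(fit, omegas = frequency_grid(), alpha = 0.05) {
  stopifnot(inherits(fit, "var_fit"))
  omegas <- check_grid(omegas)
  n <- fit$n; p <- fit$p
  rc <- rcond(fit$Rp)
  if (!is.finite(rc) || rc < 1e-12)
    stop("lag-covariance matrix is numerically singular")
  H <- solve(fit$Rp)
  nw <- length(omegas)
  Aw <- fourier_coefficients(fit, omegas)
  lam <- array(0, dim = c(n, n, nw),
               dimnames = list(fit$labels, fit$labels, NULL))
  rank <- array(0L, dim = c(n, n, nw))
  cosM <- cos(outer(seq_len(p), omegas))   # p x nw
  sinM <- sin(outer(seq_len(p), omegas))
  for (j in seq_len(n)) {
    Hjj <- source_block(H, j, n, p)
    HC <- Hjj %*% cosM
    HS <- Hjj %*% sinM
    a_w <- colSums(cosM * HC)
    b_w <- colSums(sinM * HS)
    d_w <- -colSums(cosM * HS)
    for (k in seq_len(n)) {
      if (k == j) next
      skk <- fit$SigmaHat[k, k]
      zre <- Re(Aw[k, j, ])
      zim <- Im(Aw[k, j, ])
      for (w in seq_len(nw)) {
        V <- skk * matrix(c(a_w[w], d_w[w], d_w[w], b_w[w]), 2, 2)
        qf <- quad_form_pinv(V, c(zre[w], zim[w]))
        lam[k, j, w] <- qf$stat
        rank[k, j, w] <- qf$rank
      }
    }
  }
  N <- fit$n_eff
  structure(list(lam = lam, rank = rank, omegas = omegas, N = N,
                 alpha = alpha, critical = rpdc_critical_value(alpha, N),
                 labels = fit$labels, p = p),
            class = "rpdc_result")
}

#' @export
print.rpdc_result <- function(x, ...) {
  cat("<rpdc_result> ", length(x$labels), " channels, ",
      length(x$omegas), " frequencies, N = ", x$N,
      ", critical = ", format(x$critical, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Critical value of the rPDC pointwise test
#'
#' \eqn{\chi^2_{df, 1-\alpha} / N}: the 1 - alpha quantile of the
#' chi-squared distribution (2 degrees of freedom by default) divided by the
#' number of data points entering the fit.
#'
#' @param alpha significance level in (0, 1).
#' @param N number of data points (T - p in this package).
#' @param df degrees of freedom (default 2; reduced to the rank of V for
#'   rank-deficient cells).
#' @return scalar critical value; decreasing in N.
#' @export
rpdc_critical_value <- function(alpha, N, df = 2) {
  stopifnot(alpha > 0, alpha < 1, N > 0)
  stats::qchisq(1 - alpha, df = df) / N
}

#' Significant-edge graph from an rPDC result
#'
#' Default rule `all_frequencies` (the curve-reading rule: the rPDC curve
#' must lie completely above the critical line): edge j -> k is present iff
#' \eqn{\hat\lambda_{kj}(\omega)} exceeds the critical value at every grid
#' frequency; its weight is the minimum lambda over the grid. Alternatives:
#' `any_frequency` (exceeds at >= 1 frequency; weight = max lambda) and
#' `fraction` (exceeds at >= `fraction` of the grid). Cells with
#' rank-deficient covariance are tested against the chi-squared quantile
#' with the reduced degrees of freedom. No multiplicity correction is
#' applied across edges.
#'
#' @param result a [compute_rpdc()] result.
#' @param rule significance rule (see above).
#' @param fraction grid fraction for `rule = "fraction"` (default 0.5).
#' @param alpha significance level (defaults to the one stored in `result`).
#' @return a [causal_graph()].
#' @export
rpdc_significance <- function(result,
                              rule = c("all_frequencies", "any_frequency",
                                       "fraction"),
                              fraction = 0.5, alpha = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(result, "rpdc_result"))
  if (is.null(alpha)) alpha <- result$alpha
  n <- length(result$labels)
  crit <- array(Inf, dim = dim(result$lam))
  for (df in unique(as.integer(result$rank))) {
    if (df < 1) next
    crit[result$rank == df] <- rpdc_critical_value(alpha, result$N, df = df)
  }
  sig <- result$lam > crit
  edges <- data.frame(source = character(0), target = character(0),
                      weight = numeric(0))
  for (k in seq_len(n)) for (j in seq_len(n)) {
    if (k == j) next
    s <- sig[k, j, ]
    present <- switch(rule,
      all_frequencies = all(s),
      any_frequency   = any(s),
      fraction        = mean(s) >= fraction)
    if (present) {
      weight <- if (rule == "all_frequencies") min(result$lam[k, j, ])
                else max(result$lam[k, j, s])
      edges <- rbind(edges, data.frame(
        source = result$labels[j], target = result$labels[k],
        weight = weight))
    }
  }
  causal_graph(result$labels, edges)
}

#' Full rPDC analysis of a panel
#'
#' Convenience wrapper: fits the VAR, computes rPDC over the grid, and
#' extracts the significant-edge graph.
#'
#' @param panel a [ts_panel()].
#' @param p VAR order.
#' @param n_freq grid size (default 64).
#' @param alpha significance level (default 0.05).
#' @param rule passed to [rpdc_significance()].
#' @param divisor,center passed to [fit_var()].
#' @return object of class `rpdc_analysis`: `fit`, `result`, `graph`, and
#'   the configuration used.
#' @export
rpdc_analysis <- function(panel, p, n_freq = 64L, alpha = 0.05,
                          rule = "all_frequencies", divisor = "T",
                          center = FALSE) {
  fit <- fit_var(panel, p, divisor = divisor, center = center)
  result <- compute_rpdc(fit, frequency_grid(n_freq), alpha = alpha)
  structure(list(fit = fit, result = result,
                 graph = rpdc_significance(result, rule = rule),
                 p = p, n_freq = n_freq, alpha = alpha, rule = rule),
            class = "rpdc_analysis")
}

#' Tabulate rPDC values against the critical line
#'
#' @param result a [compute_rpdc()] result.
#' @return data.frame with columns source, target, omega, rpdc_value,
#'   critical_value, significant (0/1); self-pairs excluded.
#' @export
rpdc_edge_table <- function(result) {
  n <- length(result$labels)
  nw <- length(result$omegas)
  rows <- expand.grid(k = seq_len(n), j = seq_len(n), w = seq_len(nw))
  rows <- rows[rows$k != rows$j, , drop = FALSE]
  idx <- cbind(rows$k, rows$j, rows$w)
  crit <- vapply(result$rank[idx], function(df)
    if (df < 1) Inf else rpdc_critical_value(result$alpha, result$N, df = df),
    numeric(1))
  out <- data.frame(
    source = result$labels[rows$j], target = result$labels[rows$k],
    omega = result$omegas[rows$w], rpdc_value = result$lam[idx],
    critical_value = crit)
  out$significant <- as.integer(out$rpdc_value > out$critical_value)
  out[order(out$source, out$target, out$omega), , drop = FALSE]
}
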