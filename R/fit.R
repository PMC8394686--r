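#' Lag-covariance matrices of a panel
#'
#' Computes the (p n) x (p n) moment matrix composed of the sub-matrices
#' \deqn{\hat R_p(h,\nu) = \frac{1}{T-p} \sum_{t=p+1}^{T} X(t-h) X(t-\nu)^T,
#'       \quad h,\nu = 1..p,}
#' together with the stacked cross blocks
#' \eqn{\hat r_p = (\hat R_p(0,1), ..., \hat R_p(0,p))} built with the same
#' normalization. These are the building blocks of the least-squares VAR
#' estimator and of the rPDC estimator covariance.
#'
#' @param panel a [ts_panel()] (or plain numeric matrix, T x n).
#' @param p model order, with `T > p`.
#' @return list with `Rp` ((p n) x (p n)), `rp` (n x (p n), lag blocks in
#'   order), `Y` (the (T-p) x n response block X(t)), `W` (the (T-p) x (p n)
#'   lagged regressor block), and `n_eff = T - p`.
#' @export
lag_covariance <- function(panel, p) {
  X <- as.matrix(panel)
  T <- nrow(X); n <- ncol(X)
  p <- as.integer(p)
  if (p < 1) stop("model order p must be >= 1")
  if (T <= p)
    stop("insufficient data: T = ", T, " time points for order p = ", p)
  Z <- stats::embed(X, p + 1L)          # row t: [X(t), X(t-1), ..., X(t-p)]
  Y <- Z[, seq_len(n), drop = FALSE]
  W <- Z[, -seq_len(n), drop = FALSE]
  n_eff <- T - p
  list(Rp = crossprod(W) / n_eff,
       rp = crossprod(Y, W) / n_eff,
       Y = Y, W = W, n_eff = n_eff)
}

#' Fit a VAR[p] by least squares
#'
#' Solves the normal equations built from [lag_covariance()]:
#' the stacked coefficient estimate is
#' \eqn{[\hat A(1), ..., \hat A(p)] = \hat r_p \hat R_p^{-1}},
#' residuals are \eqn{\hat\epsilon(t) = X(t) - \sum_h \hat A(h) X(t-h)} and
#' the innovation covariance is
#' \eqn{\hat\Sigma = \frac{1}{T}\sum_t \hat\epsilon(t)\hat\epsilon(t)^T}
#' (divisor `T`; set `divisor = "T-p"` for the per-term count). No intercept
#' is fitted: the process is assumed zero-mean (use `center = TRUE` to
#' subtract channel means first).
#'
#' @param panel a [ts_panel()] or T x n matrix.
#' @param p model order.
#' @param divisor `"T"` (default) or `"T-p"`, the denominator of
#'   \eqn{\hat\Sigma}.
#' @param center subtract channel means before fitting (default FALSE).
#' @return object of class `var_fit`: `Ahat` (n x n x p, `Ahat[i,j,h]` =
#'   effect of channel j at lag h on channel i), `SigmaHat`, `residuals`
#'   ((T-p) x n), `Rp`, `rp`, `p`, `n`, `T`, `n_eff = T - p`, `labels`.
#' @export
fit_var <- function(panel, p, divisor = c("T", "T-p"), center = FALSE) {
  divisor <- match.arg(divisor)
  X <- as.matrix(panel)
  labels <- colnames(X)
  if (is.null(labels)) labels <- paste0("X", seq_len(ncol(X)))
  if (center) X <- scale(X, center = TRUE, scale = FALSE)
  lc <- lag_covariance(X, p)
  n <- ncol(X); T <- nrow(X)
  rc <- rcond(lc$Rp)
  if (!is.finite(rc) || rc < 1e-12)
    stop("lag-covariance matrix is numerically singular ",
         "(reciprocal condition number ", format(rc, digits = 3),
         "); more data or a smaller order is needed")
  B <- lc$rp %*% solve(lc$Rp)           # n x (p n), lag blocks in order
  E <- lc$Y - lc$W %*% t(B)
  denom <- if (divisor == "T") T else lc$n_eff
  SigmaHat <- crossprod(E) / denom
  Ahat <- array(B, dim = c(n, n, p))
  dimnames(Ahat) <- list(labels, labels, NULL)
  dimnames(SigmaHat) <- list(labels, labels)
  structure(
    list(Ahat = Ahat, SigmaHat = SigmaHat, residuals = E,
         Rp = lc$Rp, rp = lc$rp, p = as.integer(p), n = n, T = T,
         n_eff = lc$n_eff, labels = labels, divisor = divisor),
    class = "var_fit")
}

#' @export
print.var_fit <- function(x, ...) {
  cat("<var_fit> n = ", x$n, ", p = ", x$p, ", T = ", x$T,
      " (", x$n_eff, " effective)\n", sep = "")
  invisible(x)
}

#' Select a VAR order by information criterion
#'
#' Fits orders 1..p_max and returns the minimizer of
#' \eqn{\log\det\hat\Sigma_p + \mathrm{penalty} \cdot p n^2 / (T-p)}
#' with penalty 2 (AIC) or log(T-p) (BIC), or simply the configured order
#' when `criterion = "fixed"`.
#'
#' @param panel a [ts_panel()] or matrix.
#' @param p_max largest order tried (>= 1).
#' @param criterion `"bic"` (default), `"aic"`, or `"fixed"`.
#' @param p_fixed the order returned under `criterion = "fixed"`.
#' @return integer order.
#' @export
select_order <- function(panel, p_max = 10L, criterion = c("bic", "aic", "fixed"),
                         p_fixed = NULL) {
  criterion <- match.arg(criterion)
  if (criterion == "fixed") {
    if (is.null(p_fixed)) stop("criterion = \"fixed\" requires p_fixed")
    return(as.integer(p_fixed))
  }
  stopifnot(p_max >= 1)
  ic <- vapply(seq_len(p_max), function(p) {
    fit <- fit_var(panel, p, divisor = "T-p")
    ld <- as.numeric(determinant(fit$SigmaHat, logarithm = TRUE)$modulus)
    pen <- if (criterion == "aic") 2 else log(fit$n_eff)
    ld + pen * p * fit$n^2 / fit$n_eff
  }, numeric(1))
  which.min(ic)
}
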