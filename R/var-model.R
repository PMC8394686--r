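#' Vector autoregressive model
#'
#' Defines a VAR[p] process
#' \deqn{X(t) = \sum_{r=1}^{p} A(r) X(t-r) + \epsilon(t), \quad
#'       \epsilon(t) \sim N(0, \Sigma),}
#' with n x n coefficient matrices A(r). The entry `A[i, j, r]` is the effect
#' of channel j at lag r on channel i (source j -> target i); every module in
#' gcnet shares this index convention.
#'
#' @param A coefficient array: either an n x n x p array or a list of p
#'   n x n matrices (lag 1 first).
#' @param Sigma n x n symmetric positive-definite innovation covariance;
#'   defaults to the identity.
#' @param labels optional channel names (default `X1..Xn`).
#' @param check_stationary if TRUE (default), reject models whose companion
#'   matrix has spectral radius >= 1.
#' @return An object of class `var_model` with fields `n`, `p`, `A`
#'   (n x n x p), `Sigma`, `labels`.
#' @export
var_model <- function(A, Sigma = NULL, labels = NULL, check_stationary = TRUE) {
  if (is.list(A)) {
    p <- length(A)
    n <- nrow(A[[1]])
    A <- array(unlist(lapply(A, as.matrix)), dim = c(n, n, p))
  }
  if (length(dim(A)) == 2L) A <- array(A, dim = c(dim(A), 1L))
  stopifnot(length(dim(A)) == 3L, dim(A)[1] == dim(A)[2])
  n <- dim(A)[1]
  p <- dim(A)[3]
  if (is.null(Sigma)) Sigma <- diag(n)
  Sigma <- as.matrix(Sigma)
  if (!isTRUE(all.equal(Sigma, t(Sigma), tolerance = 1e-10)))
    stop("Sigma must be symmetric")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("Sigma must be positive definite (smallest eigenvalue ",
         format(min(ev)), ")")
  if (is.null(labels)) labels <- paste0("X", seq_len(n))
  labels <- as.character(labels)
  stopifnot(length(labels) == n, !anyDuplicated(labels))
  model <- structure(
    list(n = n, p = p, A = A, Sigma = Sigma, labels = labels),
    class = "var_model")
  if (check_stationary && spectral_radius(model) >= 1)
    stop("model is not stationary: companion spectral radius ",
         format(spectral_radius(model)), " >= 1")
  model
}

#' @export
print.var_model <- function(x, ...) {
  cat("<var_model> n = ", x$n, ", p = ", x$p,
      ", spectral radius = ", format(spectral_radius(x), digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Companion matrix of a VAR[p]
#'
#' Rewrites the model as a VAR[1] on the stacked state
#' (X(t), ..., X(t-p+1)); the (np) x (np) block matrix returned here governs
#' its dynamics.
#'
#' @param model a `var_model`
#' @return (n*p) x (n*p) numeric matrix.
#' @export
companion_matrix <- function(model) {
  n <- model$n; p <- model$p
  C <- matrix(0, n * p, n * p)
  for (r in seq_len(p)) C[1:n, ((r - 1) * n + 1):(r * n)] <- model$A[, , r]
  if (p > 1) C[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  C
}

#' Spectral radius of the companion matrix
#'
#' The model is stationary iff the value is strictly below 1 (equivalently,
#' the roots of the lag polynomial lie outside the unit circle).
#'
#' @param model a `var_model`
#' @return largest eigenvalue modulus of [companion_matrix()].
#' @export
spectral_radius <- function(model) {
  max(Mod(eigen(companion_matrix(model), only.values = TRUE)$values))
}

#' Simulate a stationary VAR process
#'
#' Draws Gaussian innovations with covariance `Sigma` and iterates the VAR
#' recursion from a zero initial state, discarding `burn_in` transient
#' samples.
#'
#' @param model a stationary `var_model`
#' @param T number of retained time points (> 0).
#' @param burn_in transient samples discarded before recording (default 500).
#' @param seed integer seed; identical seeds yield identical panels.
#' @return a [ts_panel()] with `T` rows and the model's channel labels.
#' @export
simulate_var <- function(model, T, burn_in = 500L, seed = NULL) {
  stopifnot(inherits(model, "var_model"), T > 0, burn_in >= 0)
  sr <- spectral_radius(model)
  if (sr >= 1)
    stop("refusing to simulate a non-stationary model (spectral radius ",
         format(sr), " >= 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- model$n; p <- model$p
  L <- t(chol(model$Sigma))
  total <- T + burn_in
  eps <- L %*% matrix(stats::rnorm(n * total), n, total)
  X <- matrix(0, n, total + p)  # p leading zero columns as initial state
  for (t in seq_len(total)) {
    tt <- t + p
    acc <- eps[, t]
    for (r in seq_len(p)) acc <- acc + model$A[, , r] %*% X[, tt - r]
    X[, tt] <- acc
  }
  out <- t(X[, (p + burn_in + 1):(p + total), drop = FALSE])
  ts_panel(out, labels = model$labels)
}
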