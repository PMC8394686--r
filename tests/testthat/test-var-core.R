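test_that("spectral radius matches closed forms and gates simulation", {
  # all-zero coefficients -> radius 0
  m0 <- var_model(array(0, c(2, 2, 2)))
  expect_equal(spectral_radius(m0), 0)
  # univariate AR(1): companion matrix is the scalar itself
  expect_equal(spectral_radius(ar1_model(0.9)), 0.9)
  # explosive model is rejected at construction and by simulate_var
  expect_error(var_model(array(1.1, c(1, 1, 1))), "stationary")
  m_bad <- var_model(array(1.1, c(1, 1, 1)), check_stationary = FALSE)
  expect_error(simulate_var(m_bad, 100, seed = 1), "stationary")
})

test_that("var_model validates the noise covariance", {
  expect_error(var_model(array(0, c(2, 2, 1)),
                         Sigma = matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_error(var_model(array(0, c(2, 2, 1)),
                         Sigma = matrix(c(1, 0.5, 0, 1), 2)),
               "symmetric")
})

test_that("simulation reproduces population moments", {
  # pure white noise: sample covariance ~ I
  m <- var_model(array(0, c(2, 2, 1)))
  x <- simulate_var(m, 10000, seed = 1)
  expect_lt(max(abs(cov(unclass(x)) - diag(2))), 0.06)
  # AR(1) with a = 0.9: lag-1 autocorrelation ~ 0.9
  y <- simulate_var(ar1_model(0.9), 10000, seed = 2)
  r1 <- cor(y[-1, 1], y[-nrow(y), 1])
  expect_lt(abs(r1 - 0.9), 0.02)
  # determinism
  expect_identical(simulate_var(m, 50, seed = 7), simulate_var(m, 50, seed = 7))
})

test_that("benchmark simulation is variance-stable across thirds", {
  # per-channel variance of each third of the series, averaged over 50
  # seeds: stationarity means the thirds agree (here within 20%)
  thirds <- rep(1:3, each = 2000 %/% 3, length.out = 2000)
  acc <- array(0, c(3, 6))
  for (s in 1:50) {
    x <- benchmark_panel(T = 2000, seed = s)
    acc <- acc + t(sapply(split(seq_len(2000), thirds),
                          function(idx) apply(x[idx, ], 2, var)))
  }
  acc <- acc / 50
  ratio <- apply(acc, 2, function(v) max(v) / min(v))
  expect_true(all(is.finite(acc)))
  expect_lt(max(ratio), 1.2)
})

test_that("lag covariance follows its defining sums", {
  lc0 <- lag_covariance(matrix(0, 20, 2), 1)
  expect_true(all(lc0$Rp == 0))
  # hand evaluation: series (1,2,3), p = 1: Rp = (1^2 + 2^2)/2 = 2.5
  lc <- lag_covariance(matrix(c(1, 2, 3), 3, 1), 1)
  expect_equal(drop(lc$Rp), 2.5)
  expect_equal(drop(lc$rp), (2 * 1 + 3 * 2) / 2)
  # iid standard normal, large T: Rp ~ identity-block structure
  set.seed(3)
  lc2 <- lag_covariance(matrix(rnorm(40000), 20000, 2), 2)
  expect_lt(max(abs(lc2$Rp - diag(4))), 0.05)
  expect_true(isSymmetric(lc2$Rp, tol = 1e-12))
  expect_error(lag_covariance(matrix(rnorm(4), 2, 2), 2), "insufficient")
})

test_that("fit_var equals brute-force least squares on short panels", {
  for (seed in 1:5) {
    set.seed(seed)
    T <- sample(15:30, 1)
    n <- sample(1:3, 1)
    p <- sample(1:2, 1)
    X <- matrix(rnorm(T * n), T, n)
    fit <- fit_var(ts_panel(X), p)
    # direct OLS of X(t) on stacked lagged regressors, same normalization
    Y <- X[(p + 1):T, , drop = FALSE]
    W <- do.call(cbind, lapply(1:p, function(h) X[(p + 1 - h):(T - h), ,
                                                  drop = FALSE]))
    B <- t(solve(crossprod(W), crossprod(W, Y)))
    expect_lt(max(abs(B - matrix(fit$Ahat, n, n * p))), 1e-8)
    E <- Y - W %*% t(B)
    expect_lt(max(abs(crossprod(E) / T - fit$SigmaHat)), 1e-8)
  }
})

test_that("fit_var recovers known coefficients and shrinks with T", {
  m <- known_var2()
  x <- simulate_var(m, 5000, seed = 4)
  fit <- fit_var(x, 2)
  expect_lt(max(abs(fit$Ahat - m$A)), 0.06)
  # white noise: coefficients near zero, SigmaHat near sample covariance
  w <- simulate_var(var_model(array(0, c(2, 2, 1))), 4000, seed = 5)
  fw <- fit_var(w, 1)
  expect_lt(max(abs(fw$Ahat)), 0.05)
  expect_lt(max(abs(fw$SigmaHat - cov(unclass(w)))), 0.02)
  # consistency: average Frobenius error decreases from T=500 to T=8000
  err_at <- function(T) mean(sapply(1:20, function(s) {
    fit <- fit_var(simulate_var(m, T, seed = 100 + s), 2)
    sqrt(sum((fit$Ahat - m$A)^2))
  }))
  expect_lt(err_at(8000), err_at(500))
})

test_that("fit divisor options differ by the stated factor", {
  x <- simulate_var(known_var2(), 200, seed = 6)
  fT <- fit_var(x, 2, divisor = "T")
  fTp <- fit_var(x, 2, divisor = "T-p")
  expect_equal(fT$SigmaHat * 200, fTp$SigmaHat * 198)
})

test_that("select_order recovers the generating order", {
  hits1 <- sapply(1:10, function(s)
    select_order(simulate_var(ar1_model(0.7), 800, seed = s), p_max = 5))
  expect_gte(mean(hits1 == 1), 0.8)
  hits2 <- sapply(1:10, function(s)
    select_order(simulate_var(known_var2(), 1500, seed = 20 + s), p_max = 5))
  expect_gte(mean(hits2 == 2), 0.8)
  expect_identical(select_order(NULL, criterion = "fixed", p_fixed = 2L), 2L)
})

test_that("panel container enforces its invariants", {
  expect_error(ts_panel(matrix(c(1, NA), 2, 1)), "missing")
  expect_error(ts_panel(matrix(1:4, 2, 2), labels = c("a", "a")), "unique")
  p <- ts_panel(matrix(1:6, 3, 2), labels = c("a", "b"))
  expect_identical(panel_channels(panel_drop(p, "a")), "b")
  expect_error(panel_subset(p, "zzz"), "unknown channel")
})
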