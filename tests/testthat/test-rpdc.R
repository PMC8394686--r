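test_that("Fourier coefficients match a direct summation oracle", {
  x <- simulate_var(known_var2(), 400, seed = 16)
  fit <- fit_var(x, 2)
  omegas <- frequency_grid(16)
  Aw <- fourier_coefficients(fit, omegas)
  for (w in c(1, 7, 16)) {
    direct <- diag(2) + 0i
    for (r in 1:2)
      direct <- direct - fit$Ahat[, , r] * exp(-1i * omegas[w] * r)
    expect_lt(max(Mod(Aw[, , w] - direct)), 1e-12)
  }
  # zero coefficients -> identity at every frequency
  fit0 <- fit
  fit0$Ahat[] <- 0
  Aw0 <- fourier_coefficients(fit0, omegas)
  expect_true(all(Aw0 == array(diag(2) + 0i, dim(Aw0))))
  # univariate p=1 near omega = pi: e^{-i pi} = -1, so A -> 1 + a
  f1 <- fit_var(simulate_var(ar1_model(0.5), 200, seed = 17), 1)
  expect_equal(Re(drop(fourier_coefficients(f1, pi - 1e-9))),
               1 + drop(f1$Ahat), tolerance = 1e-6)
})

test_that("z_vector extracts the coordinate pair and rejects self-pairs", {
  Aw <- matrix(c(1 + 0i, -0.3 + 0.4i, 0.2 - 0.1i, 1 + 0i), 2, 2)
  expect_equal(z_vector(Aw, 2, 1), c(-0.3, 0.4))
  expect_equal(z_vector(Aw, 1, 2), c(0.2, -0.1))
  expect_error(z_vector(Aw, 1, 1), "k = j")
  # single-lag coupling c: A_kj(w) = -c e^{-iw} -> (-c cos w, c sin w)
  fit <- list(Ahat = array(c(0, 0.7, 0, 0), c(2, 2, 1)), n = 2L, p = 1L,
              labels = c("X1", "X2"))
  class(fit) <- "var_fit"
  w <- 0.9
  Awc <- fourier_coefficients(fit, w)[, , 1]
  expect_equal(z_vector(Awc, 2, 1), c(-0.7 * cos(w), 0.7 * sin(w)))
})

test_that("z_covariance reduces to the single-term trig form at p = 1", {
  x <- simulate_var(coupled_pair(0.4, self = 0.3), 600, seed = 18)
  fit <- fit_var(x, 1)
  H <- solve(fit$Rp)
  w <- 1.1
  V <- z_covariance(fit, 2, 1, w)
  expected <- fit$SigmaHat[2, 2] * H[1, 1] *
    rbind(c(cos(w)^2, -cos(w) * sin(w)),
          c(-sin(w) * cos(w), sin(w)^2))
  expect_equal(V, expected, tolerance = 1e-12)
  # single-lag case: rank 1 by construction
  expect_lt(abs(det(V)), 1e-12 * sum(diag(V))^2)
  expect_error(z_covariance(fit, 1, 1, w), "k = j")
})

test_that("z_covariance matches a direct plug-in oracle on white noise", {
  set.seed(19)
  x <- ts_panel(matrix(rnorm(3 * 4000), 4000, 3))
  fit <- fit_var(x, 2)
  H <- solve(fit$Rp)
  # H approximates the inverse sample covariance block-diagonally
  expect_lt(max(abs(fit$Rp - diag(6))), 0.1)
  for (w in c(0.5, 2.2)) {
    V <- z_covariance(fit, 3, 1, w)
    cl <- cos(1:2 * w); sl <- sin(1:2 * w)
    Hjj <- H[c(1, 4), c(1, 4)]
    oracle <- fit$SigmaHat[3, 3] *
      rbind(c(cl %*% Hjj %*% cl, -cl %*% Hjj %*% sl),
            c(-sl %*% Hjj %*% cl, sl %*% Hjj %*% sl))
    expect_lt(max(abs(V - oracle)), 1e-10)
  }
})

test_that("compute_rpdc equals a from-scratch scalar evaluation on bivariate VAR(1)", {
  x <- simulate_var(coupled_pair(0.5, self = 0.4), 800, seed = 20)
  fit <- fit_var(x, 1)
  omegas <- frequency_grid(8)
  r <- compute_rpdc(fit, omegas)
  H <- solve(fit$Rp)
  for (w in seq_along(omegas)) {
    for (pair in list(c(2, 1), c(1, 2))) {
      k <- pair[1]; j <- pair[2]
      a <- fit$Ahat[k, j, 1]
      z <- c(-a * cos(omegas[w]), a * sin(omegas[w]))
      # rank-1 V = sigma_kk H_jj u u', u = (cos w, -sin w); z = -a u, so
      # lambda = a^2 / (sigma_kk H_jj)
      lam <- a^2 / (fit$SigmaHat[k, k] * H[j, j])
      expect_equal(r$lam[k, j, w], lam, tolerance = 1e-10)
      expect_identical(r$rank[k, j, w], 1L)
    }
  }
  expect_true(all(r$lam >= 0))
})

test_that("rPDC statistic is nonnegative on random fits", {
  for (s in 1:20) {
    x <- simulate_var(known_var2(), 150, seed = 500 + s)
    r <- compute_rpdc(fit_var(x, 2), frequency_grid(8))
    expect_true(all(r$lam >= 0))
  }
})

test_that("null N*lambda follows the chi-squared reference", {
  # no coupling: N * lambda at a fixed frequency ~ chi^2 with rank dof
  stats <- t(sapply(1:500, function(s) {
    x <- null_panel(n = 2, T = 400, seed = 600 + s)
    fit <- fit_var(x, 2)
    r <- compute_rpdc(fit, pi / 2)
    c(fit$n_eff * r$lam[2, 1, 1], r$rank[2, 1, 1])
  }))
  expect_true(all(stats[, 2] == 2))
  q95 <- quantile(stats[, 1], 0.95)
  expect_gt(q95, 5.0)
  expect_lt(q95, 7.2)
})

test_that("critical value follows the chi-squared quantile and scales as 1/N", {
  # closed form for df = 2: -2 log(alpha)
  expect_equal(rpdc_critical_value(0.05, 1), -2 * log(0.05), tolerance = 1e-10)
  expect_equal(rpdc_critical_value(0.05, 1000), -2 * log(0.05) / 1000,
               tolerance = 1e-10)
  Ns <- c(10, 100, 1000, 10000)
  expect_true(all(diff(rpdc_critical_value(0.05, Ns)) < 0))
})

test_that("rPDC significance rules behave as documented", {
  x <- simulate_var(coupled_pair(0.6, self = 0.4), 2000, seed = 21)
  r <- compute_rpdc(fit_var(x, 1), frequency_grid(16))
  g_all <- rpdc_significance(r, "all_frequencies")
  expect_edge(g_all, "X1", "X2")
  # true edge weight is the minimum lambda over the grid
  expect_equal(g_all$edges$weight[g_all$edges$source == "X1"],
               min(r$lam[2, 1, ]))
  # a result forced below the critical line gives an empty graph
  r0 <- r
  r0$lam[] <- 0
  expect_identical(nrow(rpdc_significance(r0)$edges), 0L)
  # any_frequency is at least as liberal as all_frequencies
  g_any <- rpdc_significance(r, "any_frequency")
  expect_gte(nrow(g_any$edges), nrow(g_all$edges))
  expect_error(compute_rpdc(fit_var(x, 1), numeric(0)), "empty")
})

test_that("strong edges dominate absent edges across the grid", {
  hits <- sapply(1:30, function(s) {
    x <- simulate_var(coupled_pair(0.5, self = 0.4), 2000, seed = 700 + s)
    r <- compute_rpdc(fit_var(x, 1), frequency_grid(16))
    all(r$lam[2, 1, ] > r$lam[1, 2, ])
  })
  expect_gte(mean(hits), 0.9)
})
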