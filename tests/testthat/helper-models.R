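# Small fixture models shared across tests; all built in code.

# univariate AR(1): x(t) = a x(t-1) + e
ar1_model <- function(a = 0.9, sigma = 1) {
  var_model(array(a, c(1, 1, 1)), Sigma = matrix(sigma))
}

# bivariate VAR(1) with a single directed coupling 1 -> 2 of strength c
coupled_pair <- function(c = 0.5, self = 0) {
  A <- array(0, c(2, 2, 1))
  diag(A[, , 1]) <- self
  A[2, 1, 1] <- c
  var_model(A)
}

# stationary VAR(2) with known mixed-lag structure, for recovery tests
known_var2 <- function() {
  A1 <- matrix(c(0.5, 0.0,
                 0.3, 0.4), 2, 2, byrow = TRUE)
  A2 <- matrix(c(-0.2, 0.0,
                  0.0, -0.1), 2, 2, byrow = TRUE)
  var_model(array(c(A1, A2), c(2, 2, 2)))
}

# independent AR(2) channels (the benchmark's self-dynamics, no coupling)
null_panel <- function(n = 3, T = 300, seed = 1) {
  A <- array(0, c(n, n, 2))
  diag(A[, , 1]) <- 0.5
  diag(A[, , 2]) <- -0.1
  simulate_var(var_model(A), T, burn_in = 300, seed = seed)
}

expect_edge <- function(graph, source, target) {
  expect_true(any(graph$edges$source == source & graph$edges$target == target),
              label = paste0("edge ", source, "->", target, " present"))
}
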