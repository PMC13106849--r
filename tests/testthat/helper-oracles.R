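# Independent brute-force oracle for Kendall statistics on a time series.
brute_kendall <- function(x) {
  n <- length(x)
  S <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) S <- S + sign(x[j] - x[i])
  }
  D <- n * (n - 1) / 2
  tie_sizes <- as.integer(table(x))
  U <- sum(tie_sizes * (tie_sizes - 1) / 2)
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(tie_sizes * (tie_sizes - 1) * (2 * tie_sizes + 5))) / 18
  tau <- if (D - U <= 0) 0 else S / sqrt(D * (D - U))
  list(S = S, tau = tau, var_S = var_S)
}

# Independent restricted log-likelihood via dense matrix algebra.
indep_reml_ll <- function(tau2, y, v, X) {
  V <- diag(v + tau2)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  -0.5 * as.numeric(determinant(V, logarithm = TRUE)$modulus +
                      determinant(XtViX, logarithm = TRUE)$modulus +
                      t(r) %*% Vi %*% r)
}

# Grid bracket + golden-section refinement on the independent likelihood.
grid_reml <- function(y, v, X) {
  upper <- max(2 * var(y), 4 * mean(v))
  grid <- seq(0, upper, length.out = 400)
  ll <- vapply(grid, function(t2) indep_reml_ll(t2, y, v, X), numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(function(t2) indep_reml_ll(t2, y, v, X), c(lo, hi),
                  maximum = TRUE, tol = 1e-12)
  if (indep_reml_ll(0, y, v, X) >= opt$objective) 0 else opt$maximum
}
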