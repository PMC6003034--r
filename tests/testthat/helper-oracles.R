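# Independent brute-force oracles used to cross-check the implementation.

# Product-moment correlation from explicit sums (no stats::cor).
brute_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x)
  sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Partial correlation of columns i and j given all remaining columns,
# via correlation of least-squares residuals.
residual_pcorr <- function(X, i, j) {
  others <- setdiff(seq_len(ncol(X)), c(i, j))
  if (length(others) == 0) {
    return(stats::cor(X[, i], X[, j]))
  }
  Z <- X[, others, drop = FALSE]
  ri <- stats::residuals(stats::lm(X[, i] ~ Z))
  rj <- stats::residuals(stats::lm(X[, j] ~ Z))
  stats::cor(ri, rj)
}

# Loop-based shrinkage intensity: per-pair variance of the correlation
# estimate over the sum of squared off-diagonal correlations.
brute_shrinkage_lambda <- function(X) {
  n <- nrow(X)
  Z <- scale(X)
  num <- 0
  den <- 0
  for (i in seq_len(ncol(Z) - 1)) {
    for (j in seq(i + 1, ncol(Z))) {
      w <- Z[, i] * Z[, j]
      r <- n / (n - 1) * mean(w)
      num <- num + n / (n - 1)^3 * sum((w - mean(w))^2)
      den <- den + r^2
    }
  }
  min(1, max(0, num / den))
}

# Reference oils with the derived index columns appended.
reference_with_indices <- function() {
  add_derived_indices(argan_oils())
}

# Random valid fatty-acid profile (4 acids, closed to 100).
random_profile <- function() {
  v <- stats::runif(4, 1, 10)
  stats::setNames(100 * v / sum(v), c("palmitic", "stearic", "oleic", "linoleic"))
}
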