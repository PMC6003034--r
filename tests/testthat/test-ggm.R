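test_that("standardization centers, scales, and is idempotent", {
  expect_equal(unname(standardize(cbind(a = c(1, 2, 3)))[, 1]), c(-1, 0, 1))

  set.seed(41)
  X <- matrix(stats::rnorm(40), 10, 4)
  Z <- standardize(X)
  expect_equal(unname(colMeans(Z)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, stats::sd)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unclass(standardize(Z)), unclass(Z), tolerance = 1e-12,
    ignore_attr = TRUE
  )

  expect_error(standardize(cbind(a = 1:3, b = rep(2, 3))), "b")
})

test_that("shrinkage precision estimation has the closed-form limits", {
  set.seed(43)
  X <- matrix(stats::rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))

  # full shrinkage: precision is the identity
  pe1 <- estimate_precision(X, lambda = 1)
  expect_equal(unname(pe1$omega), diag(3), tolerance = 1e-12)

  # p = 2, lambda = 0: 2x2 closed-form inverse of the correlation matrix
  Y <- X[, 1:2]
  r <- stats::cor(Y)[1, 2]
  pe0 <- estimate_precision(Y, lambda = 0)
  expect_equal(
    unname(pe0$omega),
    matrix(c(1, -r, -r, 1), 2) / (1 - r^2),
    tolerance = 1e-10
  )

  # omega inverts the shrunk covariance
  pe <- estimate_precision(X)
  expect_equal(unname(pe$omega %*% pe$sigma_shrunk), diag(3),
    tolerance = 1e-10
  )
  expect_gte(pe$lambda, 0)
  expect_lte(pe$lambda, 1)

  expect_error(estimate_precision(X, lambda = 1.5), "lambda")
  expect_error(estimate_precision(X[1:2, ]), "at least 3")
})

test_that("auto shrinkage keeps the precision finite when n < p and matches brute force", {
  set.seed(47)
  X <- matrix(stats::rnorm(7 * 10), 7, 10,
    dimnames = list(NULL, paste0("v", 1:10))
  )
  pe <- estimate_precision(X) # sample covariance is singular here
  expect_true(all(is.finite(pe$omega)))
  ev <- eigen(pe$omega, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))

  expect_equal(pe$lambda, brute_shrinkage_lambda(X), tolerance = 1e-12)

  # unshrunk inversion of a singular covariance must fail loudly
  expect_error(estimate_precision(X, lambda = 0), "positive definite")
})

test_that("partial correlations match the residual-regression oracle at lambda 0", {
  set.seed(53)
  for (p in 2:4) {
    X <- matrix(stats::rnorm(60 * p), 60, p,
      dimnames = list(NULL, paste0("v", seq_len(p)))
    )
    # correlate the columns so the check is not a null case
    X[, 1] <- X[, 1] + 0.5 * X[, p]
    pc <- partial_correlations(estimate_precision(X, lambda = 0))
    expect_equal(diag(pc), rep(1, p), ignore_attr = TRUE)
    for (i in seq_len(p - 1)) {
      for (j in seq(i + 1, p)) {
        expect_equal(pc[i, j], residual_pcorr(X, i, j), tolerance = 1e-10)
      }
    }
  }

  # diagonal precision means no conditional associations
  pc0 <- partial_correlations(diag(c(2, 3, 4)))
  expect_equal(pc0[upper.tri(pc0)], rep(0, 3))
})

test_that("edge selection thresholds by |partial correlation|", {
  pc <- diag(4)
  pc[1, 2] <- pc[2, 1] <- 0.9
  pc[1, 3] <- pc[3, 1] <- -0.45
  pc[2, 4] <- pc[4, 2] <- 0.31
  pc[3, 4] <- pc[4, 3] <- 0.05
  dimnames(pc) <- list(letters[1:4], letters[1:4])

  expect_equal(nrow(select_edges(pc, tau = 0)), choose(4, 2))
  expect_equal(nrow(select_edges(pc, tau = 1)), 0)

  got <- select_edges(pc, tau = 0.3)
  # enumeration: exactly the three pairs at or above 0.3 in magnitude
  expect_equal(nrow(got), 3)
  expect_setequal(paste(got$from, got$to), c("a b", "a c", "b d"))
  expect_equal(got$pcorr[got$from == "a" & got$to == "c"], -0.45)

  expect_error(select_edges(pc, tau = -0.1), "tau")
  expect_error(select_edges(pc, tau = 1.2), "tau")
})

test_that("orientation scores are reciprocal and follow the partial-variance order", {
  set.seed(59)
  X <- matrix(stats::rnorm(30 * 5), 30, 5,
    dimnames = list(NULL, paste0("v", 1:5))
  )
  pe <- estimate_precision(X)
  g <- node_order_scores(pe)
  B <- outer(g, g, "/")
  expect_equal(unname(B * t(B)), matrix(1, 5, 5), tolerance = 1e-12)

  # diagonal precision: smaller omega_kk means larger score, orients outward
  pe_diag <- pe
  pe_diag$omega <- diag(c(0.5, 2, 1, 1, 1))
  dimnames(pe_diag$omega) <- dimnames(pe$omega)
  g2 <- node_order_scores(pe_diag)
  expect_gt(g2[["v1"]], g2[["v2"]])
  net <- orient_edges(
    data.frame(from = "v1", to = "v2", pcorr = 0.5),
    g2
  )
  expect_equal(net$edges$from, "v1")
  expect_equal(net$edges$to, "v2")
  expect_true(net$edges$directed)
  expect_equal(net$edges$B, g2[["v1"]] / g2[["v2"]])

  # equal scores within tolerance stay undirected
  g_tie <- c(a = 1, b = 1 + 1e-12, c = 2)
  net_tie <- orient_edges(
    data.frame(from = c("a", "b"), to = c("b", "c"), pcorr = c(0.4, 0.4)),
    g_tie,
    tie_eps = 1e-9
  )
  expect_false(net_tie$edges$directed[1])
  expect_true(net_tie$edges$directed[2])

  expect_error(
    orient_edges(data.frame(from = "a", to = "z", pcorr = 0.4), g_tie),
    "z"
  )
})

test_that("oriented graphs are acyclic on random inputs", {
  set.seed(61)
  for (k in 1:200) {
    p <- sample(3:8, 1)
    g <- stats::setNames(stats::runif(p, 0.1, 2), paste0("v", seq_len(p)))
    pairs <- utils::combn(names(g), 2)
    keep <- stats::runif(ncol(pairs)) < 0.5
    edges <- data.frame(
      from = pairs[1, keep], to = pairs[2, keep],
      pcorr = stats::runif(sum(keep), -1, 1)
    )
    net <- orient_edges(edges, g)
    expect_true(is_acyclic(net))
  }
})

test_that("shrinkage deflates partial correlations to zero", {
  # p = 2: exact closed form, pcorr = (1 - lambda) * r, monotone by algebra
  set.seed(66)
  Y <- matrix(stats::rnorm(40), 20, 2)
  r <- stats::cor(Y)[1, 2]
  for (l in seq(0, 1, by = 0.25)) {
    pc <- partial_correlations(estimate_precision(Y, lambda = l))
    expect_equal(pc[1, 2], (1 - l) * r, tolerance = 1e-12)
  }

  # general p: full shrinkage kills every association, the strongest one
  # decays along the way, and magnitudes are negligible near lambda = 1
  # (per-pair monotonicity does NOT hold in general: a weak pair can
  # transiently strengthen while the dominant pairs deflate)
  set.seed(67)
  X <- matrix(stats::rnorm(25 * 4), 25, 4)
  X[, 2] <- X[, 2] + X[, 1]
  lambdas <- seq(0, 1, by = 0.1)
  mags <- sapply(lambdas, function(l) {
    pc <- partial_correlations(estimate_precision(X, lambda = l))
    abs(pc[upper.tri(pc)])
  })
  expect_equal(unname(mags[, ncol(mags)]), rep(0, nrow(mags)))
  maxima <- apply(mags, 2, max)
  expect_true(all(diff(maxima) <= 1e-12))
  near_one <- sapply(c(0.95, 0.99), function(l) {
    pc <- partial_correlations(estimate_precision(X, lambda = l))
    max(abs(pc[upper.tri(pc)]))
  })
  expect_true(all(near_one < 0.05))
})

test_that("build_network composes the stages and flags redundant variables", {
  X <- encode_samples(argan_oils())
  net <- build_network(X)
  expect_s3_class(net, "oil_network")
  expect_equal(net$nodes, analysis_variables())
  expect_true(is_acyclic(net))
  expect_equal(dim(net$pcorr), c(10, 10))

  # a duplicated column has the strongest conditional association of all pairs
  set.seed(71)
  Y <- matrix(stats::rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  Y <- cbind(Y, d = Y[, "a"] + stats::rnorm(50, 0, 1e-6))
  netY <- build_network(Y, tau = 0)
  pcY <- netY$pcorr
  off <- which(upper.tri(pcY), arr.ind = TRUE)
  best <- off[which.max(abs(pcY[off])), ]
  expect_setequal(colnames(pcY)[best], c("a", "d"))

  # independent columns at n = 500 leave the network near-empty
  set.seed(73)
  Z <- matrix(stats::rnorm(500 * 6), 500, 6,
    dimnames = list(NULL, paste0("v", 1:6))
  )
  netZ <- build_network(Z, tau = 0.3)
  expect_equal(nrow(netZ$edges), 0)
})
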