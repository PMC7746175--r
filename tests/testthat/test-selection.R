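# Architecture enumeration, Monte-Carlo cross-validation, selection
# tie-breaks and the PCA variant.

test_that("architecture enumeration covers the bounded space deterministically", {
  small <- enumerateArchitectures(3, 1)
  expect_equal(small, list(1L, 2L, 3L))
  expect_equal(enumerateArchitectures(2, 2), list(1L, 2L, c(1L, 1L)))

  full <- enumerateArchitectures(17, 2)
  # independent combinatorial count: 17 single-layer widths plus, for each
  # total t = 2..17, the t-1 ordered two-layer splits
  expect_equal(length(full), 17 + sum(seq_len(16)))
  expect_true(all(vapply(full, function(h) sum(h) <= 17, logical(1))))
  expect_true(all(vapply(full, length, integer(1)) <= 2))
  expect_false(any(duplicated(vapply(full, paste, character(1), collapse = "x"))))
  totals <- vapply(full, sum, numeric(1))
  expect_true(!is.unsorted(totals)) # ordered by total neurons
})

test_that("the t-based confidence interval matches the closed form", {
  ci <- mseConfidenceInterval(c(280, 290, 300))
  expect_equal(ci$mean, 290)
  expect_equal(ci$low, 290 - qt(0.975, 2) * 10 / sqrt(3), tolerance = 1e-9)
  expect_equal(ci$low, 265.16, tolerance = 1e-2)
  expect_equal(ci$high, 314.84, tolerance = 1e-2)
  one <- mseConfidenceInterval(42)
  expect_equal(one$low, 42)
  expect_equal(one$high, 42)
})

test_that("CI halves shrink roughly as 1/sqrt(repeats) on homoskedastic MSEs", {
  set.seed(5)
  widths <- vapply(c(10, 40, 160), function(n) {
    half <- replicate(200, {
      ci <- mseConfidenceInterval(rnorm(n, 290, 20))
      (ci$high - ci$low) / 2
    })
    mean(half)
  }, numeric(1))
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.15)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.15)
})

test_that("Monte-Carlo CV is reproducible and honors its contracts", {
  set.seed(8)
  X <- matrix(rnorm(40 * 5), 40, 5)
  colnames(X) <- paste0("f", 1:5)
  y <- X %*% c(1, -1, 0.5, 0, 2) + rnorm(40, 0, 0.1)
  a <- monteCarloCV(X, y, 2L, nRepeats = 3, seed = 11, maxEpochs = 20)
  b <- monteCarloCV(X, y, 2L, nRepeats = 3, seed = 11, maxEpochs = 20)
  expect_identical(a$mses, b$mses)
  expect_lte(a$ciLow, a$meanMSE)
  expect_gte(a$ciHigh, a$meanMSE)
  expect_equal(a$nRepeats, 3L)
  expect_error(monteCarloCV(X[1:5, ], y[1:5], 2L), "at least 10")
  expect_error(monteCarloCV(X, y, 2L, trainFraction = 1), "between 0 and 1")
})

test_that("a constant target is learned to near-zero validation MSE", {
  set.seed(9)
  X <- matrix(rnorm(30 * 4), 30, 4)
  colnames(X) <- paste0("f", 1:4)
  y <- rep(5, 30)
  sc <- monteCarloCV(X, y, 2L, nRepeats = 3, seed = 2, maxEpochs = 50)
  expect_lt(sc$meanMSE, 1e-6)
})

test_that("selection takes the argmin with neuron/layer tie-breaks", {
  mk <- function(h, m) structure(list(hidden = as.integer(h), mses = m,
                                      meanMSE = m, ciLow = m, ciHigh = m,
                                      nRepeats = 1L, pca = FALSE),
                                 class = "ArchitectureScore")
  expect_equal(selectArchitecture(list(mk(3, 300), mk(5, 290), mk(7, 295))), 5L)
  # equal mean, equal neurons: fewer layers wins
  expect_equal(selectArchitecture(list(mk(c(5, 5), 290), mk(10, 290))), 10L)
  # equal mean: fewer total neurons wins
  expect_equal(selectArchitecture(list(mk(12, 290), mk(4, 290))), 4L)
  expect_equal(selectArchitecture(list(mk(c(2, 1), 100))), c(2L, 1L))
  expect_error(selectArchitecture(list()), "at least one")
})

test_that("PCA at removal fraction 0 is a lossless orthogonal rotation", {
  set.seed(10)
  X <- scale(matrix(rnorm(40 * 6), 40, 6))
  pc <- pcaTransform(X)
  co <- crossprod(pc$scores) / (nrow(X) - 1)
  expect_lt(max(abs(co[upper.tri(co)])), 1e-10)
  expect_equal(pc$scores %*% t(pc$rotation), unclass(X),
               tolerance = 1e-10, ignore_attr = TRUE)
  # 2-D data with axis variances (4, 1): first component on the x axis
  set.seed(11)
  Y <- cbind(rnorm(500, sd = 2), rnorm(500, sd = 1))
  Y <- sweep(Y, 2, colMeans(Y))
  p2 <- pcaTransform(Y)
  expect_gt(abs(p2$rotation[1, 1]), 0.99)
  expect_gt(p2$rotation[which.max(abs(p2$rotation[, 1])), 1], 0) # sign fix
})

test_that("a rank-deficient matrix keeps only its rank with a warning", {
  set.seed(3)
  X <- matrix(rnorm(20 * 2), 20, 2)
  X3 <- cbind(X, X[, 1] + X[, 2])
  expect_warning(pc <- pcaTransform(X3), "retaining")
  expect_equal(ncol(pc$rotation), 2)
})

test_that("PCA preprocessing is MSE-neutral for a linear model", {
  # rotation invariance: on a linear-activation network the PCA rotation
  # cannot change the attainable least-squares fit
  set.seed(14)
  X <- scale(matrix(rnorm(50 * 5), 50, 5))
  y <- X %*% c(2, -1, 0, 1, 0.5) + rnorm(50, 0, 0.2)
  fitOn <- function(Z) {
    lin <- netModel(ncol(Z), integer(0), seed = 1, activation = "identity")
    tail(trainLM(lin, Z, y, lambdaInit = 1e-12, maxEpochs = 1)$history, 1)
  }
  pc <- pcaTransform(X)
  expect_equal(fitOn(pc$scores), fitOn(unclass(X)), tolerance = 1e-8)
})
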