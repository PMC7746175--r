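# Network forward pass, analytic Jacobian, Levenberg-Marquardt trainer and
# serialization.

test_that("forward pass propagates hand-computable cases", {
  m <- netModel(3, c(2), seed = 1)
  zero <- setParamVector(m, rep(0, nParams(m)))
  expect_equal(forwardPass(zero, matrix(rnorm(9), 3, 3)), rep(0, 3))

  # hidden weights zero, output bias beta -> constant network
  m2 <- netModel(4, c(3), seed = 2)
  th <- rep(0, nParams(m2))
  th[length(th)] <- 4.25 # the output bias is the last parameter
  const <- setParamVector(m2, th)
  expect_equal(forwardPass(const, matrix(rnorm(20), 5, 4)), rep(4.25, 5))

  # one hidden neuron, hand-set parameters
  m3 <- netModel(1, c(1), seed = 3)
  m3@weights[[1]][] <- 0.3; m3@biases[[1]] <- -0.1
  m3@weights[[2]][] <- 1.7; m3@biases[[2]] <- 0.25
  x <- 0.9
  expect_equal(forwardPass(m3, matrix(x, 1, 1)),
               1.7 * tanh(0.3 * x - 0.1) + 0.25, tolerance = 1e-12)
  expect_equal(predict(m3, matrix(x, 1, 1)), forwardPass(m3, matrix(x, 1, 1)))
  expect_error(forwardPass(m3, matrix(1, 1, 2)), "input neurons")
})

test_that("the analytic Jacobian matches central finite differences", {
  set.seed(31)
  archs <- list(integer(0), 3L, c(4L, 2L), c(2L, 5L))
  for (h in archs) {
    m <- netModel(3, h, seed = sample.int(1e6, 1))
    X <- matrix(rnorm(15), 5, 3)
    J <- netJacobian(m, X)
    Jfd <- fdJacobian(m, X)
    expect_equal(dim(J), c(5, nParams(m)))
    expect_lt(max(abs(J - Jfd)) / max(1, max(abs(Jfd))), 1e-6)
  }
})

test_that("Jacobian rows duplicate with duplicated samples; bias column is 1", {
  m <- netModel(2, c(3), seed = 6)
  x <- matrix(c(0.4, -1, 0.4, -1), 2, 2, byrow = TRUE)
  J <- netJacobian(m, x)
  expect_equal(J[1, ], J[2, ])
  lin <- netModel(2, integer(0), seed = 1, activation = "identity")
  Jl <- netJacobian(lin, matrix(0, 1, 2))
  expect_equal(unname(Jl[1, ]), c(0, 0, 1)) # w1, w2, output bias
})

test_that("one LM step at vanishing damping solves the linear LS problem", {
  lin <- netModel(1, integer(0), seed = 1, activation = "identity")
  lin@weights[[1]][] <- 0; lin@biases[[1]] <- 0
  fit <- trainLM(lin, matrix(c(1, 2), 2, 1), c(2, 4),
                 lambdaInit = 1e-12, maxEpochs = 1)
  expect_equal(fit$model@weights[[1]][1, 1], 2, tolerance = 1e-8)
  expect_equal(fit$model@biases[[1]], 0, tolerance = 1e-8)
  expect_equal(tail(fit$history, 1), 0, tolerance = 1e-12)
})

test_that("LM with identity activation reproduces ordinary least squares", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 30; p <- 4
    X <- matrix(rnorm(n * p), n, p)
    y <- X %*% rnorm(p) + rnorm(n)
    lin <- netModel(p, integer(0), seed = rep, activation = "identity")
    fit <- trainLM(lin, X, y, lambdaInit = 1e-12, maxEpochs = 1)
    ols <- unname(coef(lm(y ~ X)))
    expect_equal(c(fit$model@weights[[1]]), ols[-1], tolerance = 1e-7)
    expect_equal(fit$model@biases[[1]], ols[1], tolerance = 1e-7)
  }
})

test_that("an exactly fitting model takes zero accepted steps", {
  lin <- netModel(1, integer(0), seed = 1, activation = "identity")
  lin@weights[[1]][] <- 2; lin@biases[[1]] <- 0
  fit <- trainLM(lin, matrix(c(1, 2), 2, 1), c(2, 4))
  expect_equal(fit$epochs, 0)
  expect_equal(fit$history, 0)
})

test_that("LM learns sin(x) to high accuracy within 200 epochs", {
  x <- matrix(seq(-3, 3, length.out = 50), 50, 1)
  y <- sin(x[, 1])
  net <- netModel(1, 8L, seed = 42)
  fit <- trainLM(net, x, y, maxEpochs = 200)
  expect_lt(tail(fit$history, 1), 1e-3)
  expect_true(all(diff(fit$history) < 0)) # accepted steps strictly decrease
})

test_that("training is bit-reproducible given seed, data and config", {
  set.seed(77)
  X <- matrix(rnorm(60), 20, 3)
  y <- sin(X[, 1]) + 0.5 * X[, 2]
  a <- trainLM(netModel(3, c(4), seed = 5), X, y, maxEpochs = 30)
  b <- trainLM(netModel(3, c(4), seed = 5), X, y, maxEpochs = 30)
  expect_identical(paramVector(a$model), paramVector(b$model))
  expect_identical(a$history, b$history)
})

test_that("mse follows its definition", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(0, 0), c(3, 4)), 12.5)
  set.seed(2)
  p <- rnorm(10); t <- rnorm(10)
  expect_equal(mse(p + 3, t + 3), mse(p, t), tolerance = 1e-12)
  expect_error(mse(1:3, 1:4), "equal")
})

test_that("model serialization reloads the exact network", {
  m <- netModel(18, c(7, 3), seed = 99)
  path <- tempfile(fileext = ".json")
  saveNetModel(m, path, extras = list(note = "fixture"))
  back <- loadNetModel(path)
  expect_equal(paramVector(back$model), paramVector(m), tolerance = 1e-12)
  expect_identical(back$model@hidden, m@hidden)
  expect_identical(back$model@activation, m@activation)
  X <- matrix(rnorm(36), 2, 18)
  expect_equal(forwardPass(back$model, X), forwardPass(m, X),
               tolerance = 1e-12)
  unlink(path)
})

test_that("NetModel validity rejects inconsistent shapes", {
  m <- netModel(3, c(2), seed = 1)
  expect_error(methods::validObject(
    methods::new("NetModel", nInputs = 3L, hidden = 2L,
                 weights = list(matrix(0, 2, 2), matrix(0, 2, 1)),
                 biases = m@biases, activation = "tanh", seed = 1L)
  ), "shape")
  expect_error(setParamVector(m, rep(0, 3)), "length")
})
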