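# Feed-forward regression network and Levenberg-Marquardt trainer,
# implemented from first principles: analytic per-sample Jacobian of the
# network output with respect to every weight and bias, and a damped
# Gauss-Newton loop that solves (J'J + lambda I) delta = J'e.

.actFun <- function(activation) {
  switch(activation, tanh = tanh, identity = identity)
}

# derivative expressed through the activation output a = f(z)
.actDerivFromOutput <- function(activation, a) {
  switch(activation, tanh = 1 - a^2, identity = array(1, dim = dim(a)))
}

#' Create a feed-forward regression network
#'
#' Architecture `nInputs - hidden... - 1` with bounded sigmoidal (tanh)
#' hidden units and a linear output. Parameters are initialized uniformly
#' in `[-initScale, initScale]` from `seed`; the Nguyen-Widrow variant
#' rescales first-layer rows for better coverage of the input space.
#'
#' @param nInputs number of input neurons (18 for the full predictor set).
#' @param hidden integer vector of hidden widths (length 0, 1 or 2).
#' @param seed initialization seed.
#' @param activation hidden activation, `"tanh"` (default) or
#'   `"identity"`.
#' @param initScale half-width of the uniform initialization.
#' @param init `"uniform"` (default) or `"nguyen-widrow"`.
#' @return a [NetModel-class].
#' @examples
#' m <- netModel(18, c(10), seed = 1)
#' m
#' @export
netModel <- function(nInputs, hidden = integer(0), seed = 1L,
                     activation = c("tanh", "identity"),
                     initScale = 0.5, init = c("uniform", "nguyen-widrow")) {
  activation <- match.arg(activation)
  init <- match.arg(init)
  sizes <- c(as.integer(nInputs), as.integer(hidden), 1L)
  nl <- length(sizes) - 1L
  pars <- withSeed(seed, {
    lapply(seq_len(nl), function(l) {
      w <- matrix(stats::runif(sizes[l] * sizes[l + 1], -initScale, initScale),
                  sizes[l], sizes[l + 1])
      b <- stats::runif(sizes[l + 1], -initScale, initScale)
      list(w = w, b = b)
    })
  })
  if (init == "nguyen-widrow" && length(hidden)) {
    h <- sizes[2]
    beta <- 0.7 * h^(1 / sizes[1])
    w <- pars[[1]]$w
    norms <- sqrt(colSums(w^2))
    norms[norms == 0] <- 1
    pars[[1]]$w <- sweep(w, 2, beta / norms, "*")
    pars[[1]]$b <- seq(-beta, beta, length.out = h)
  }
  methods::new("NetModel",
    nInputs = as.integer(nInputs), hidden = as.integer(hidden),
    weights = lapply(pars, `[[`, "w"), biases = lapply(pars, `[[`, "b"),
    activation = activation, seed = as.integer(seed)
  )
}

#' Number of free parameters of a network
#' @param model a [NetModel-class].
#' @return integer count of weights plus biases.
#' @export
nParams <- function(model) {
  sum(vapply(model@weights, length, integer(1))) +
    sum(vapply(model@biases, length, integer(1)))
}

#' Flatten / restore the parameter vector
#'
#' Layer by layer, column-major weights first, then biases — the same
#' ordering as the columns of [netJacobian()].
#'
#' @param model a [NetModel-class].
#' @return `paramVector()`: numeric vector; `setParamVector()`: the model
#'   with parameters replaced.
#' @export
paramVector <- function(model) {
  unlist(lapply(seq_along(model@weights), function(l) {
    c(as.numeric(model@weights[[l]]), model@biases[[l]])
  }), use.names = FALSE)
}

#' @rdname paramVector
#' @param theta replacement parameter vector (length [nParams()]).
#' @export
setParamVector <- function(model, theta) {
  if (length(theta) != nParams(model)) stop("wrong parameter-vector length")
  pos <- 0L
  for (l in seq_along(model@weights)) {
    nw <- length(model@weights[[l]])
    nb <- length(model@biases[[l]])
    model@weights[[l]][] <- theta[pos + seq_len(nw)]
    model@biases[[l]] <- theta[pos + nw + seq_len(nb)]
    pos <- pos + nw + nb
  }
  model
}

.asInputMatrix <- function(model, features) {
  x <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  if (ncol(x) != model@nInputs) {
    stop(sprintf("feature length %d does not match the %d input neurons",
                 ncol(x), model@nInputs))
  }
  x
}

# forward pass keeping per-layer activations (for the Jacobian)
.forwardFull <- function(model, x) {
  f <- .actFun(model@activation)
  acts <- vector("list", length(model@weights) + 1L)
  acts[[1]] <- x
  a <- x
  nl <- length(model@weights)
  for (l in seq_len(nl)) {
    z <- sweep(a %*% model@weights[[l]], 2, model@biases[[l]], "+")
    a <- if (l < nl) f(z) else z # linear output layer
    acts[[l + 1L]] <- a
  }
  acts
}

#' Forward pass
#'
#' @param model a [NetModel-class].
#' @param features numeric vector (one sample) or matrix (rows = samples)
#'   with [nParams()]-consistent width.
#' @return numeric vector of predictions (NFHAS-difference points).
#' @export
forwardPass <- function(model, features) {
  x <- .asInputMatrix(model, features)
  acts <- .forwardFull(model, x)
  as.numeric(acts[[length(acts)]])
}

#' @describeIn forwardPass `predict` method for NetModel.
#' @param object a [NetModel-class].
#' @param newdata features as in `forwardPass`.
#' @param ... ignored.
#' @export
setMethod("predict", "NetModel", function(object, newdata, ...) {
  forwardPass(object, newdata)
})

#' Jacobian of the network output w.r.t. all parameters
#'
#' Analytic backpropagated derivatives: one row per sample, one column per
#' parameter in [paramVector()] order.
#'
#' @param model a [NetModel-class].
#' @param features sample matrix (rows = samples).
#' @return numeric matrix `n x nParams(model)`.
#' @export
netJacobian <- function(model, features) {
  x <- .asInputMatrix(model, features)
  n <- nrow(x)
  nl <- length(model@weights)
  acts <- .forwardFull(model, x)
  # G[[l]]: d output / d preactivation of layer l, per sample
  G <- vector("list", nl)
  G[[nl]] <- matrix(1, n, 1)
  if (nl > 1L) {
    for (l in (nl - 1L):1L) {
      deriv <- .actDerivFromOutput(model@activation, acts[[l + 1L]])
      G[[l]] <- (G[[l + 1L]] %*% t(model@weights[[l + 1L]])) * deriv
    }
  }
  blocks <- lapply(seq_len(nl), function(l) {
    aPrev <- acts[[l]]
    g <- G[[l]]
    pin <- ncol(aPrev)
    pout <- ncol(g)
    jw <- aPrev[, rep(seq_len(pin), times = pout), drop = FALSE] *
      g[, rep(seq_len(pout), each = pin), drop = FALSE]
    cbind(jw, g)
  })
  do.call(cbind, blocks)
}

#' Mean squared error
#'
#' @param predictions,targets equal-length numeric vectors.
#' @return mean of squared differences.
#' @examples
#' mse(c(0, 0), c(3, 4)) # 12.5
#' @export
mse <- function(predictions, targets) {
  if (length(predictions) != length(targets) || !length(targets)) {
    stop("predictions and targets must have equal positive length")
  }
  mean((predictions - targets)^2)
}

#' Train a network with Levenberg-Marquardt
#'
#' Damped Gauss-Newton on the squared error: at each epoch the step
#' `delta = (J'J + lambda I)^-1 J'e` is tried; if it lowers the MSE it is
#' accepted and `lambda` is multiplied by `lambdaDown`, otherwise the step
#' is rejected and `lambda` is multiplied by `lambdaUp` until a step is
#' accepted or `lambda` exceeds `lambdaMax`. A singular system is never
#' fatal: the damping is raised and the solve retried. Training stops on
#' `maxEpochs`, on a small error gradient (`gradTol` on
#' `max |d MSE / d theta|`), or when `lambda` exhausts its range. The
#' history of accepted MSE values is non-increasing by construction.
#'
#' @param model a [NetModel-class] (initial parameters).
#' @param features sample matrix (rows = samples).
#' @param targets numeric vector of training targets.
#' @param lambdaInit,lambdaUp,lambdaDown,lambdaMax damping schedule.
#' @param maxEpochs maximum number of accepted steps.
#' @param gradTol gradient stopping tolerance.
#' @return list with `model` (trained), `history` (MSE after each accepted
#'   step, starting at the initial MSE), `epochs` (accepted steps) and
#'   `lambda` (final damping).
#' @export
trainLM <- function(model, features, targets,
                    lambdaInit = 1e-3, lambdaUp = 10, lambdaDown = 0.1,
                    lambdaMax = 1e10, maxEpochs = 1000, gradTol = 1e-7) {
  if (lambdaInit <= 0 || lambdaUp <= 1 || lambdaDown <= 0 || lambdaDown >= 1) {
    stop("need lambdaInit > 0, lambdaUp > 1 and 0 < lambdaDown < 1")
  }
  x <- .asInputMatrix(model, features)
  y <- as.numeric(targets)
  if (nrow(x) != length(y) || any(!is.finite(y))) {
    stop("targets must be finite and match the number of samples")
  }
  n <- length(y)
  err <- y - forwardPass(model, x)
  current <- mean(err^2)
  history <- current
  lambda <- lambdaInit
  epochs <- 0L
  p <- nParams(model)
  while (epochs < maxEpochs) {
    J <- netJacobian(model, x)
    g <- crossprod(J, err) # (dMSE/dtheta) = -2 g / n
    if (max(abs(g)) * 2 / n < gradTol) break
    JtJ <- crossprod(J)
    accepted <- FALSE
    while (lambda <= lambdaMax) {
      delta <- tryCatch(
        solve(JtJ + diag(lambda, p), g),
        error = function(e) NULL
      )
      if (!is.null(delta)) {
        cand <- setParamVector(model, paramVector(model) + as.numeric(delta))
        candErr <- y - forwardPass(cand, x)
        candMse <- mean(candErr^2)
        if (is.finite(candMse) && candMse < current) {
          model <- cand
          err <- candErr
          current <- candMse
          history <- c(history, current)
          epochs <- epochs + 1L
          lambda <- max(lambda * lambdaDown, .Machine$double.xmin)
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * lambdaUp
    }
    if (!accepted) break
  }
  list(model = model, history = history, epochs = epochs, lambda = lambda)
}

#' Serialize / reload a network as JSON
#'
#' Stores architecture, parameters at full precision, the activation, the
#' init seed and optional extras (e.g. z-score parameters) for exact
#' reload.
#'
#' @param model a [NetModel-class].
#' @param path JSON file path.
#' @param extras named list stored verbatim alongside the model.
#' @return `saveNetModel()`: the path, invisibly; `loadNetModel()`: a list
#'   with `model` and `extras`.
#' @export
saveNetModel <- function(model, path, extras = list()) {
  obj <- list(
    nInputs = model@nInputs, hidden = model@hidden,
    activation = model@activation, seed = model@seed,
    weights = lapply(model@weights, function(w) {
      list(dim = dim(w), values = as.numeric(w))
    }),
    biases = model@biases,
    extras = extras
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname saveNetModel
#' @export
loadNetModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  weights <- lapply(obj$weights, function(w) {
    matrix(as.numeric(unlist(w$values)), w$dim[[1]], w$dim[[2]])
  })
  biases <- lapply(obj$biases, function(b) as.numeric(unlist(b)))
  obj$nInputs <- obj$nInputs[[1]]
  obj$hidden <- as.integer(unlist(obj$hidden))
  obj$activation <- obj$activation[[1]]
  obj$seed <- obj$seed[[1]]
  model <- methods::new("NetModel",
    nInputs = as.integer(obj$nInputs), hidden = as.integer(obj$hidden),
    weights = weights, biases = biases,
    activation = obj$activation, seed = as.integer(obj$seed)
  )
  list(model = model, extras = obj$extras)
}
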