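# Architecture search by Monte-Carlo cross-validation: repeated random
# 70/30 train/validation splits, fresh initialization per repeat, z-score
# (and optional PCA) parameters fitted on the training side only, and the
# validation MSE averaged over repeats with a Student-t 95% interval.

#' Enumerate candidate architectures
#'
#' All single-hidden-layer widths `1..maxNeurons` plus, when
#' `maxLayers >= 2`, every two-layer split `(n1, n2)` with `n1, n2 >= 1`
#' and `n1 + n2 <= maxNeurons`. Deterministic order: by total hidden
#' neurons, then number of layers, then first-layer width.
#'
#' @param maxNeurons maximum total hidden neurons (study protocol: 17).
#' @param maxLayers maximum hidden layers (1 or 2; study protocol: 2).
#' @return list of integer vectors of hidden widths.
#' @examples
#' length(enumerateArchitectures(3, 1)) # 3
#' enumerateArchitectures(2, 2)         # list(1, 2, c(1, 1))
#' @export
enumerateArchitectures <- function(maxNeurons = 17L, maxLayers = 2L) {
  if (maxNeurons < 1L || maxLayers < 1L) stop("limits must be >= 1")
  out <- list()
  for (tot in seq_len(maxNeurons)) {
    out[[length(out) + 1L]] <- as.integer(tot)
    if (maxLayers >= 2L && tot >= 2L) {
      for (n1 in seq_len(tot - 1L)) {
        out[[length(out) + 1L]] <- as.integer(c(n1, tot - n1))
      }
    }
  }
  out
}

.archId <- function(hidden, pca) {
  sum(hidden) * 1000 + length(hidden) * 100 + hidden[1] + if (pca) 13 else 0
}

#' Monte-Carlo cross-validation of one architecture
#'
#' For each repeat: a fresh random `trainFraction` split of the patients, a
#' fresh parameter initialization, z-score parameters (and, with
#' `pca = TRUE`, PCA loadings) fitted on the training side and applied to
#' the validation side, training via [trainLM()], and the MSE of the
#' trained network on the validation side. The targets stay on their
#' native NFHAS-difference scale. The repeat MSEs are summarised as their
#' mean and Student-t 95% interval
#' (`mean +/- t(0.975, n-1) * sd / sqrt(n)`). Reproducible from `seed`;
#' each (architecture, repeat) pair has its own derived RNG substream, so
#' results do not depend on evaluation order.
#'
#' @param features raw (un-z-scored) `n x p` predictor matrix.
#' @param targets NFHAS-difference vector, length `n`.
#' @param hidden integer vector of hidden widths.
#' @param nRepeats number of Monte-Carlo repeats (study protocol: 10).
#' @param trainFraction fraction of patients used for training (0.70).
#' @param seed global search seed.
#' @param pca apply PCA (all components retained) after z-scoring.
#' @param maxEpochs LM epoch budget per fit.
#' @param ... further arguments to [trainLM()].
#' @return list of class `"ArchitectureScore"`: `hidden`, `mses`,
#'   `meanMSE`, `ciLow`, `ciHigh`, `nRepeats`, `pca`.
#' @export
monteCarloCV <- function(features, targets, hidden, nRepeats = 10L,
                         trainFraction = 0.7, seed = 1L, pca = FALSE,
                         maxEpochs = 100L, ...) {
  n <- nrow(features)
  if (n < 10L) stop("Monte-Carlo cross-validation needs at least 10 samples")
  if (trainFraction <= 0 || trainFraction >= 1) {
    stop("trainFraction must lie strictly between 0 and 1")
  }
  nTrain <- round(trainFraction * n)
  if (nTrain < 1L || nTrain >= n) stop("degenerate split: one side is empty")
  id <- .archId(hidden, pca)
  mses <- vapply(seq_len(nRepeats), function(r) {
    s <- seedStream(seed, id, r)
    idx <- withSeed(s, sample.int(n, nTrain))
    xTr <- features[idx, , drop = FALSE]
    xVa <- features[-idx, , drop = FALSE]
    fit <- zscoreFitMatrix(xTr)
    zTr <- fit$values
    zVa <- applyZscore(xVa, fit$center, fit$scale)
    if (pca) {
      pc <- pcaTransform(zTr)
      zTr <- pc$scores
      zVa <- zVa %*% pc$rotation
    }
    model <- netModel(ncol(zTr), hidden, seed = seedStream(s, 1))
    trained <- trainLM(model, zTr, targets[idx], maxEpochs = maxEpochs, ...)
    mse(forwardPass(trained$model, zVa), targets[-idx])
  }, numeric(1))
  ci <- mseConfidenceInterval(mses)
  structure(
    list(
      hidden = as.integer(hidden), mses = mses, meanMSE = ci$mean,
      ciLow = ci$low, ciHigh = ci$high,
      nRepeats = as.integer(nRepeats), pca = pca
    ),
    class = "ArchitectureScore"
  )
}

#' Student-t confidence interval on repeat MSEs
#'
#' `mean +/- t(1 - (1-level)/2, n-1) * sd / sqrt(n)` over the Monte-Carlo
#' repeat MSEs.
#'
#' @param mses numeric vector of per-repeat MSEs.
#' @param level confidence level (default 0.95).
#' @return list with `mean`, `low`, `high`.
#' @examples
#' mseConfidenceInterval(c(280, 290, 300)) # 290 [265.16, 314.84]
#' @export
mseConfidenceInterval <- function(mses, level = 0.95) {
  if (!length(mses)) stop("at least one MSE is required")
  m <- mean(mses)
  half <- if (length(mses) > 1L) {
    stats::qt(1 - (1 - level) / 2, length(mses) - 1L) *
      stats::sd(mses) / sqrt(length(mses))
  } else {
    0
  }
  list(mean = m, low = m - half, high = m + half)
}

#' @export
print.ArchitectureScore <- function(x, ...) {
  cat(sprintf(
    "architecture [%s]%s: mean MSE %.2f (95%% CI %.2f-%.2f, %d repeats)\n",
    paste(x$hidden, collapse = ", "), if (x$pca) " +PCA" else "",
    x$meanMSE, x$ciLow, x$ciHigh, x$nRepeats
  ))
  invisible(x)
}

#' Select the best-scoring architecture
#'
#' Argmin of the mean cross-validated MSE; ties are broken by fewer total
#' hidden neurons, then fewer layers.
#'
#' @param scores list of `ArchitectureScore` objects from
#'   [monteCarloCV()].
#' @return the winning integer vector of hidden widths.
#' @export
selectArchitecture <- function(scores) {
  if (!length(scores)) stop("at least one architecture score is required")
  key <- vapply(scores, function(s) s$meanMSE, numeric(1))
  neurons <- vapply(scores, function(s) sum(s$hidden), numeric(1))
  layers <- vapply(scores, function(s) length(s$hidden), numeric(1))
  ord <- order(key, neurons, layers)
  scores[[ord[1]]]$hidden
}

#' Run the Monte-Carlo search over a candidate list
#'
#' @param features,targets as in [monteCarloCV()].
#' @param candidates list of hidden-width vectors, e.g. from
#'   [enumerateArchitectures()].
#' @param ... passed to [monteCarloCV()].
#' @return list with `scores` (per candidate), `report` (data.frame:
#'   architecture, layers, neurons, mean MSE, CI) and `best` (selected
#'   hidden widths).
#' @export
searchArchitectures <- function(features, targets,
                                candidates = enumerateArchitectures(),
                                ...) {
  scores <- lapply(candidates, function(h) {
    monteCarloCV(features, targets, h, ...)
  })
  report <- do.call(rbind, lapply(scores, function(s) {
    data.frame(
      architecture = paste(s$hidden, collapse = "x"),
      layers = length(s$hidden), neurons = sum(s$hidden),
      mean_mse = s$meanMSE, ci_low = s$ciLow, ci_high = s$ciHigh,
      repeats = s$nRepeats, stringsAsFactors = FALSE
    )
  }))
  list(scores = scores, report = report, best = selectArchitecture(scores))
}

#' PCA rotation of a (z-scored) feature matrix
#'
#' Principal components via [stats::prcomp()] with no additional centering
#' or scaling (the predictors are z-scored upstream). With the default
#' removal fraction of 0 every component above numerical rank is retained,
#' so the transform is a pure rotation: component scores are mutually
#' uncorrelated and the original matrix is exactly reconstructable.
#' Sign convention: each component's largest-magnitude loading is positive.
#'
#' @param x numeric matrix (rows = samples), centered/z-scored upstream.
#' @param removeFraction fraction of variance allowed to be dropped
#'   (study protocol: 0, i.e. keep everything).
#' @return list with `scores`, `rotation` (to project held-out data via
#'   `newdata %*% rotation`) and `sdev`.
#' @export
pcaTransform <- function(x, removeFraction = 0) {
  if (nrow(x) < 2L) stop("PCA needs at least 2 samples")
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  keep <- pc$sdev > pc$sdev[1] * 1e-12
  if (removeFraction > 0) {
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    keep <- keep & (c(0, cum[-length(cum)]) < (1 - removeFraction))
  }
  if (sum(keep) < ncol(x)) {
    warning(sprintf("retaining %d of %d components (rank/removal limit)",
                    sum(keep), ncol(x)))
  }
  rot <- pc$rotation[, keep, drop = FALSE]
  flip <- apply(rot, 2, function(v) v[which.max(abs(v))] < 0)
  rot[, flip] <- -rot[, flip, drop = FALSE]
  list(scores = x %*% rot, rotation = rot, sdev = pc$sdev[keep])
}
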