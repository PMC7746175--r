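# Cohort-level cleaning and predictor assembly: scaled-MAD outlier
# exclusion on the raw baseline predictor distributions, z-score
# normalization, the fixed 18-feature layout and the NFHAS-difference
# target.

#' Names of the 18 predictors, in their fixed order
#'
#' `(rom_normalized, cv, speed_to_peak)` blocks, each over the six
#' movements `F, E, Llb, Rlb, Lrt, Rrt`.
#'
#' @return character vector of length 18.
#' @export
featureNames <- function() {
  c(paste0("rom_norm_", MOVEMENTS),
    paste0("cv_", MOVEMENTS),
    paste0("speed_", MOVEMENTS))
}

#' Flag outliers by the 3-scaled-MAD rule
#'
#' A value is an outlier when it lies more than 3 scaled median absolute
#' deviations from the median; the scaling constant is 1.4826, the
#' Gaussian-consistency factor (the default of [stats::mad()]). When the
#' MAD is zero (a near-constant vector), values are flagged only when they
#' deviate at all *and* a secondary scaled-IQR criterion
#' (`|x - median| > 3 * IQR / 1.349`) also flags them, so one wild value
#' among constants is caught while genuinely constant vectors stay clean.
#'
#' @param values numeric vector, length `>= 1`, finite.
#' @return logical mask, `TRUE` for outliers.
#' @examples
#' flagOutliers(c(1, 2, 3, 4, 100)) # only 100 is flagged
#' @export
flagOutliers <- function(values) {
  if (!length(values) || any(!is.finite(values))) {
    stop("values must be a non-empty finite numeric vector")
  }
  med <- stats::median(values)
  dev <- abs(values - med)
  m <- stats::mad(values) # 1.4826 * median(|x - median|)
  if (m > 0) return(dev > 3 * m)
  iqr <- stats::IQR(values)
  dev > 0 & dev > 3 * (iqr / 1.349)
}

#' Exclude patients with any outlying raw predictor
#'
#' Applies [flagOutliers()] to each of the 18 raw baseline predictors
#' across the cohort; a patient is excluded when any predictor is flagged,
#' and the excluded patients' follow-up records are dropped too.
#'
#' @param cohort a [NeckCohort-class].
#' @return the filtered cohort; excluded patient ids are attached as
#'   `attr(, "excluded")` and reported via a message.
#' @export
filterOutlierPatients <- function(cohort) {
  raw <- rawFeatures(baselineRecords(cohort))
  mask <- apply(raw, 2, flagOutliers)
  bad <- rownames(raw)[rowSums(mask) > 0]
  message(sprintf("outlier filtering: excluding %d of %d patients",
                  length(bad), nrow(raw)))
  cd <- SummarizedExperiment::colData(cohort)
  out <- cohort[, !(cd$patient_id %in% bad)]
  attr(out, "excluded") <- bad
  out
}

#' z-score a vector
#'
#' Centres and scales to sample mean 0 and sample standard deviation 1
#' (denominator n-1) and returns the transformation parameters so the same
#' transform can be reused on held-out data without leakage.
#'
#' @param values numeric vector, length `>= 2`.
#' @return list with `values` (the z-scores), `center` and `scale`.
#' @examples
#' zscore(c(1, 2, 3))$values # -1 0 1
#' @export
zscore <- function(values) {
  if (length(values) < 2L || any(!is.finite(values))) {
    stop("z-scoring needs at least 2 finite values")
  }
  s <- stats::sd(values)
  if (s == 0) stop("degenerate feature: zero variance, cannot z-score")
  m <- mean(values)
  list(values = (values - m) / s, center = m, scale = s)
}

#' Apply stored z-score parameters
#'
#' @param values numeric vector or matrix (columns = features).
#' @param center,scale parameters from [zscore()] / [buildFeatures()].
#' @return transformed values.
#' @export
applyZscore <- function(values, center, scale) {
  if (is.matrix(values)) {
    sweep(sweep(values, 2, center, "-"), 2, scale, "/")
  } else {
    (values - center) / scale
  }
}

#' Fit per-column z-scoring on a feature matrix
#'
#' Column-wise [zscore()]: returns the standardized matrix together with
#' the per-column centers and scales for reuse on held-out rows via
#' [applyZscore()]. Errors name any degenerate (zero-variance) feature.
#'
#' @param x numeric matrix, rows = samples.
#' @return list with `values`, `center`, `scale`.
#' @export
zscoreFitMatrix <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  degenerate <- colnames(x)[scale == 0]
  if (length(degenerate)) {
    stop("degenerate feature(s) with zero variance: ",
         paste(degenerate, collapse = ", "))
  }
  list(values = applyZscore(x, center, scale), center = center, scale = scale)
}

#' Raw (un-normalized) 18-predictor matrix
#'
#' One row per patient, columns in the fixed [featureNames()] order; values
#' are on their native scales (percent of normative, percent CV, deg/s).
#'
#' @param se a single-time-point cohort subset, e.g.
#'   `baselineRecords(cohort)`.
#' @return numeric matrix `n x 18` with patient ids as rownames.
#' @export
rawFeatures <- function(se) {
  rn <- t(metricMatrix(se, "rom_norm"))
  cv <- t(metricMatrix(se, "cv"))
  sp <- t(metricMatrix(se, "speed"))
  out <- cbind(rn, cv, sp)
  colnames(out) <- featureNames()
  rownames(out) <- SummarizedExperiment::colData(se)$patient_id
  if (anyNA(out)) stop("incomplete record: missing predictor values")
  out
}

#' Build the z-scored feature matrix for a baseline cohort
#'
#' @param cohort a [NeckCohort-class] (its baseline records are used) or a
#'   single-time-point subset.
#' @return list with `features` (`n x 18` z-scored matrix), `center` and
#'   `scale` (named length-18 vectors for reuse on held-out data).
#' @export
buildFeatures <- function(cohort) {
  se <- if (methods::is(cohort, "NeckCohort")) baselineRecords(cohort) else cohort
  raw <- rawFeatures(se)
  fit <- zscoreFitMatrix(raw)
  list(features = fit$values, center = fit$center, scale = fit$scale)
}

#' NFHAS-difference target
#'
#' `NFHAS(followup) - NFHAS(baseline)` per patient: positive values mean
#' the global mobility score improved over rehabilitation.
#'
#' @param baseline,followup aligned single-time-point cohort subsets (same
#'   patients, same order), e.g. from [baselineRecords()] /
#'   [followupRecords()].
#' @param nfhasFn scoring function applied to the six normalized ROMs
#'   (default [nfhasScore()]).
#' @return named numeric vector of NFHAS differences in \[-100, 100\].
#' @export
buildTarget <- function(baseline, followup, nfhasFn = nfhasScore) {
  idB <- SummarizedExperiment::colData(baseline)$patient_id
  idF <- SummarizedExperiment::colData(followup)$patient_id
  if (!identical(idB, idF)) {
    stop("pairing error: baseline and follow-up patients do not match")
  }
  sB <- apply(metricMatrix(baseline, "rom_norm"), 2, nfhasFn)
  sF <- apply(metricMatrix(followup, "rom_norm"), 2, nfhasFn)
  stats::setNames(as.numeric(sF - sB), idB)
}
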