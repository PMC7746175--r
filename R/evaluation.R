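# Held-out performance assessment: regression R of real on predicted
# NFHAS change, quadrant agreement of change direction, error histogram,
# and per-quadrant paired pre/post tests of the kinematic variables.

QUADRANT_LEVELS <- c("1 1", "1 -1", "-1 1", "-1 -1")

#' Regression of real on predicted change
#'
#' Least-squares line of the real NFHAS change (dependent) on the
#' predicted change (independent); R is the Pearson correlation, sign
#' preserved. An R closer to 1 indicates a better fit.
#'
#' @param predicted,actual equal-length numeric vectors, `n >= 3`,
#'   non-zero variance on both sides.
#' @return list with `r`, `slope`, `intercept` and `n`.
#' @examples
#' fitPerformanceRegression(c(1, 2, 3), c(1, 3, 2))$r # 0.5
#' @export
fitPerformanceRegression <- function(predicted, actual) {
  if (length(predicted) != length(actual) || length(actual) < 3L) {
    stop("need at least 3 prediction/observation pairs")
  }
  if (stats::sd(predicted) == 0 || stats::sd(actual) == 0) {
    stop("degenerate input: zero variance")
  }
  fit <- stats::lm(actual ~ predicted)
  list(
    r = stats::cor(predicted, actual),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n = length(actual)
  )
}

#' Quadrant grouping of real vs predicted change direction
#'
#' Improvement means a strictly positive NFHAS change; zero change counts
#' as "not improve" (and is reported via a message). Labels follow the
#' "real predicted" convention: `"1 1"` real and predicted improvement,
#' `"1 -1"` real improvement predicted not to improve, `"-1 1"` real
#' deterioration predicted to improve, `"-1 -1"` both non-improving.
#'
#' @param real,predicted equal-length numeric vectors of NFHAS changes.
#' @return list with `labels` (factor over the four quadrants) and
#'   `percentages` (named, summing to 100).
#' @examples
#' assignQuadrants(c(5, -2), c(3, 1))$labels # "1 1", "-1 1"
#' @export
assignQuadrants <- function(real, predicted) {
  if (length(real) != length(predicted) || !length(real)) {
    stop("real and predicted must have equal positive length")
  }
  nzero <- sum(real == 0) + sum(predicted == 0)
  if (nzero > 0) {
    message(sprintf("%d zero change(s) counted as 'not improve'", nzero))
  }
  dirR <- ifelse(real > 0, "1", "-1")
  dirP <- ifelse(predicted > 0, "1", "-1")
  labels <- factor(paste(dirR, dirP), levels = QUADRANT_LEVELS)
  counts <- table(labels)
  pct <- stats::setNames(100 * as.numeric(counts) / length(real),
                         QUADRANT_LEVELS)
  list(labels = labels, percentages = pct)
}

#' Paired t-test on pre/post values
#'
#' Two-sided paired test computed from the closed form: with differences
#' `d = post - pre`, `t = mean(d) / (sd(d)/sqrt(n))` on `n - 1` degrees of
#' freedom, with a `1 - alpha` confidence interval on the mean difference.
#' The post-minus-pre difference is primary (positive = increase after
#' rehabilitation); the pre-minus-post mean is reported alongside for
#' comparability with table layouts using the opposite convention. A
#' constant non-zero difference has zero variance; it is flagged and
#' reported with `t = +/-Inf`, `p = 0`.
#'
#' @param pre,post equal-length numeric vectors, `n >= 2`.
#' @param alpha significance level (default 0.05).
#' @param variable optional variable name carried into the result.
#' @return one-row data.frame: `variable`, `n`, `mean_diff` (post - pre),
#'   `mean_diff_pre_post`, `se`, `t`, `df`, `p`, `ci_low`, `ci_high`.
#' @examples
#' pairedTTest(c(1, 2, 3), c(2, 4, 6)) # t = 3.46, p = 0.074
#' @export
pairedTTest <- function(pre, post, alpha = 0.05, variable = NA_character_) {
  n <- length(pre)
  if (length(post) != n || n < 2L) {
    stop("insufficient data: paired test needs n >= 2 equal-length vectors")
  }
  d <- post - pre
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1L
  if (s == 0) {
    if (m == 0) {
      tstat <- 0
      p <- 1
    } else {
      warning("zero-variance differences: p reported as 0")
      tstat <- sign(m) * Inf
      p <- 0
    }
    se <- 0
    ci <- c(m, m)
  } else {
    se <- s / sqrt(n)
    tstat <- m / se
    p <- 2 * stats::pt(-abs(tstat), df)
    half <- stats::qt(1 - alpha / 2, df) * se
    ci <- c(m - half, m + half)
  }
  data.frame(
    variable = variable, n = n,
    mean_diff = m, mean_diff_pre_post = -m,
    se = se, t = tstat, df = df, p = p,
    ci_low = ci[1], ci_high = ci[2],
    stringsAsFactors = FALSE
  )
}

#' Histogram of prediction errors
#'
#' Errors are `prediction - target`; bins are equal-width over the
#' observed range (shared edges can be passed for overlaying several
#' splits).
#'
#' @param predictions,targets equal-length numeric vectors.
#' @param nBins number of bins (default 20).
#' @param edges optional explicit bin edges (overrides `nBins`).
#' @return list with `edges` (length bins + 1) and `counts` (summing to
#'   the number of samples).
#' @export
errorHistogram <- function(predictions, targets, nBins = 20L, edges = NULL) {
  if (length(predictions) != length(targets) || !length(targets)) {
    stop("predictions and targets must have equal positive length")
  }
  if (is.null(edges)) {
    if (nBins < 1L) stop("nBins must be >= 1")
    err <- predictions - targets
    rng <- range(err)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = nBins + 1L)
  }
  err <- predictions - targets
  h <- graphics::hist(err, breaks = edges, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  list(edges = h$breaks, counts = h$counts)
}

#' Per-quadrant paired pre/post tables
#'
#' For each quadrant group, paired t-tests comparing baseline and
#' follow-up values of ROM (per movement, plus the NFHAS score), speed to
#' peak and ROM CV, mirroring the per-group table layout of the clinical
#' report. A Holm-adjusted p column is appended as an extra aid; the
#' primary `p` column is unadjusted at the per-test alpha.
#'
#' @param cohort a [NeckCohort-class].
#' @param labels factor of quadrant labels named by patient id (from
#'   [assignQuadrants()]), typically covering the held-out patients.
#' @param alpha per-test significance level.
#' @return named list (one entry per non-empty quadrant) of lists with
#'   data.frames `rom`, `speed`, `cv`.
#' @export
quadrantTables <- function(cohort, labels, alpha = 0.05) {
  bl <- baselineRecords(cohort)
  fu <- followupRecords(cohort)
  ids <- SummarizedExperiment::colData(bl)$patient_id
  stopifnot(!is.null(names(labels)))
  out <- list()
  for (q in QUADRANT_LEVELS) {
    members <- names(labels)[labels == q & !is.na(labels)]
    members <- intersect(members, ids)
    if (length(members) < 2L) next
    sel <- match(members, ids)
    tables <- list()
    for (fam in c("rom_deg", "speed", "cv")) {
      pre <- metricMatrix(bl, fam)[, sel, drop = FALSE]
      post <- metricMatrix(fu, fam)[, sel, drop = FALSE]
      rows <- lapply(MOVEMENTS, function(m) {
        pairedTTest(pre[m, ], post[m, ], alpha, variable = m)
      })
      tab <- do.call(rbind, rows)
      if (fam == "rom_deg") {
        sPre <- nfhasScores(bl[, sel])
        sPost <- nfhasScores(fu[, sel])
        tab <- rbind(tab, pairedTTest(sPre, sPost, alpha, variable = "NFHAS"))
      }
      tab$p_holm <- stats::p.adjust(tab$p, method = "holm")
      key <- switch(fam, rom_deg = "rom", speed = "speed", cv = "cv")
      tables[[key]] <- tab
    }
    out[[q]] <- tables
  }
  out
}

#' Build a full evaluation report
#'
#' Combines the regression check, held-out MSE, quadrant percentages, the
#' error histogram and (when a cohort is supplied) the per-quadrant paired
#' pre/post tables into an [EvaluationReport-class].
#'
#' @param predicted,actual NFHAS changes on the held-out patients; for the
#'   tables, `actual` must be named by patient id.
#' @param cohort optional [NeckCohort-class] for the paired tables.
#' @param nBins histogram bins.
#' @param alpha per-test significance level for the tables.
#' @return an [EvaluationReport-class].
#' @export
evaluatePredictions <- function(predicted, actual, cohort = NULL,
                                nBins = 20L, alpha = 0.05) {
  reg <- fitPerformanceRegression(predicted, actual)
  quad <- assignQuadrants(actual, predicted)
  hist <- errorHistogram(predicted, actual, nBins)
  tables <- list()
  if (!is.null(cohort)) {
    labels <- stats::setNames(quad$labels, names(actual))
    tables <- quadrantTables(cohort, labels, alpha)
  }
  counts <- table(quad$labels)
  methods::new("EvaluationReport",
    r = reg$r, slope = reg$slope, intercept = reg$intercept,
    mse = mse(predicted, actual), n = length(actual),
    quadrants = data.frame(
      label = QUADRANT_LEVELS,
      count = as.integer(counts),
      percent = unname(quad$percentages),
      stringsAsFactors = FALSE
    ),
    histogram = hist, tables = tables
  )
}
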