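# Performance regression, quadrant grouping, paired t-test and the error
# histogram.

test_that("the performance regression recovers R, slope and intercept", {
  p <- c(1, 2, 3, 4)
  r1 <- fitPerformanceRegression(p, p)
  expect_equal(r1$r, 1)
  expect_equal(r1$slope, 1)
  expect_equal(r1$intercept, 0, tolerance = 1e-12)
  expect_equal(fitPerformanceRegression(p, -p)$r, -1)
  expect_equal(fitPerformanceRegression(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  expect_error(fitPerformanceRegression(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(fitPerformanceRegression(1:2, 1:2), "at least 3")
})

test_that("R is invariant to positive affine rescaling of predictions", {
  set.seed(6)
  p <- rnorm(30); a <- p + rnorm(30, 0, 0.5)
  base <- fitPerformanceRegression(p, a)$r
  expect_equal(fitPerformanceRegression(3.2 * p + 7, a)$r, base,
               tolerance = 1e-12)
})

test_that("quadrant labels follow the real/predicted sign convention", {
  q <- assignQuadrants(c(5, -2), c(3, 1))
  expect_equal(as.character(q$labels), c("1 1", "-1 1"))
  q2 <- assignQuadrants(c(1, 1, -1, -1), c(1, -1, 1, -1))
  expect_equal(unname(q2$percentages), rep(25, 4))
  expect_equal(sum(q2$percentages), 100)
  expect_message(q0 <- assignQuadrants(c(0, 2), c(1, 1)), "not improve")
  expect_equal(as.character(q0$labels)[1], "-1 1") # zero -> non-improvement
  # order invariance
  set.seed(13)
  r <- rnorm(50); p <- rnorm(50)
  perm <- sample(50)
  expect_equal(assignQuadrants(r, p)$percentages,
               assignQuadrants(r[perm], p[perm])$percentages)
})

test_that("the paired t-test matches its df=2 closed form", {
  res <- pairedTTest(c(1, 2, 3), c(2, 4, 6))
  expect_equal(res$mean_diff, 2)
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-4)
  expect_equal(res$t, 3.4641, tolerance = 1e-4)
  expect_equal(res$p, 0.0742, tolerance = 1e-3)
  expect_equal(res$mean_diff_pre_post, -2)
  same <- pairedTTest(c(1, 2), c(1, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_warning(zv <- pairedTTest(c(1, 2, 3), c(2, 3, 4)), "zero-variance")
  expect_equal(zv$p, 0)
  expect_error(pairedTTest(1, 1), "n >= 2")
})

test_that("the paired t-test agrees with the reference implementation", {
  set.seed(15)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    pre <- rnorm(n, 50, 10)
    post <- pre + rnorm(n, 2, 5)
    mine <- pairedTTest(pre, post)
    ref <- t.test(post, pre, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
    expect_equal(c(mine$ci_low, mine$ci_high), as.numeric(ref$conf.int),
                 tolerance = 1e-9)
    expect_true(mine$ci_low <= mine$mean_diff & mine$mean_diff <= mine$ci_high)
  }
})

test_that("error histograms conserve counts and centre perfect predictions", {
  t0 <- c(1, 2, 3, 4)
  h <- errorHistogram(t0, t0, nBins = 5)
  expect_equal(sum(h$counts), 4)
  zeroBin <- which(h$edges[-length(h$edges)] <= 0 & h$edges[-1] >= 0)
  expect_equal(sum(h$counts[zeroBin]), 4)
  h2 <- errorHistogram(c(0, 2), c(1, 1), nBins = 2)
  expect_equal(h2$counts, c(1, 1))
  set.seed(16)
  p <- rnorm(200); a <- rnorm(200)
  expect_equal(sum(errorHistogram(p, a, nBins = 20)$counts), 200)
})

test_that("the evaluation report assembles all pieces consistently", {
  co <- smallCohort(n = 80, seed = 19)
  actual <- buildTarget(baselineRecords(co), followupRecords(co))
  set.seed(20)
  predicted <- actual + rnorm(length(actual), 0, 4)
  rep <- evaluatePredictions(stats::setNames(predicted, names(actual)),
                             actual, cohort = co)
  expect_s4_class(rep, "EvaluationReport")
  expect_equal(sum(rep@quadrants$percent), 100, tolerance = 1e-9)
  expect_equal(sum(rep@histogram$counts), rep@n)
  expect_equal(rep@r, cor(predicted, actual))
  expect_true(length(rep@tables) >= 1)
  tab <- rep@tables[[1]]$rom
  expect_true(all(c("variable", "mean_diff", "se", "t", "p", "ci_low",
                    "ci_high", "p_holm") %in% colnames(tab)))
  expect_true("NFHAS" %in% tab$variable)
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_output(show(rep), "EvaluationReport")
})
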