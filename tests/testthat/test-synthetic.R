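# Synthetic generator: determinism, severity structure, ground-truth
# contracts and the kinematics round trip.

test_that("trace generation is deterministic and honors the no-jitter case", {
  pr <- list(rom_mean = 60, cv_mean = 0, speed_mean = 62.832)
  a <- generateTrace("F", pr, duration = 45, rate = 100, seed = 5)
  b <- generateTrace("F", pr, duration = 45, rate = 100, seed = 5)
  expect_identical(a@angle, b@angle)
  expect_identical(a@time, b@time)
  expect_equal(max(a@angle) - min(a@angle), 60, tolerance = 0.05)
  reps <- segmentRepetitions(a)
  expect_lt(100 * sd(reps$rom) / mean(reps$rom), 0.05) # downstream CV ~ 0
  expect_error(generateTrace("F", pr, duration = -1, rate = 100), "positive")
  expect_error(generateTrace("F", pr, duration = 45, rate = 0), "positive")
})

test_that("generated traces round-trip through the kinematics module", {
  pr <- list(rom_mean = 50, cv_mean = 8, speed_mean = 70)
  roms <- c(); speeds <- c()
  for (s in 1:12) {
    reps <- segmentRepetitions(generateTrace("Lrt", pr, seed = s))
    roms <- c(roms, reps$rom)
    speeds <- c(speeds, reps$peak_speed)
  }
  expect_gte(length(roms), 200)
  expect_lt(abs(mean(roms) - 50) / 50, 0.05)
  expect_lt(abs(mean(speeds) - 70) / 70, 0.05)
})

test_that("cohort generation is deterministic and respects type proportions", {
  co1 <- smallCohort(n = 10, seed = 33)
  co2 <- smallCohort(n = 10, seed = 33)
  expect_identical(SummarizedExperiment::assay(co1, "kinematics"),
                   SummarizedExperiment::assay(co2, "kinematics"))
  expect_identical(trueChange(co1), trueChange(co2))

  n <- 1000
  co <- smallCohort(n = n, seed = 7)
  types <- SummarizedExperiment::colData(baselineRecords(co))$nfhas_type
  p <- recoveryModelSpec()$group_proportions
  counts <- tabulate(types, 5)
  for (k in 1:5) {
    tol <- 3 * sqrt(n * p[k] * (1 - p[k]))
    expect_lt(abs(counts[k] - n * p[k]), tol)
  }
})

test_that("zero generator noise makes the stored truth exactly the model output", {
  co <- smallCohort(n = 40, seed = 9, noise = 0)
  truth <- S4Vectors::metadata(co)$truth
  expect_equal(unname(trueChange(co)), unname(truth$deterministic_change))
  # and the follow-up is built so the realized NFHAS difference equals it
  d <- buildTarget(baselineRecords(co), followupRecords(co))
  expect_equal(unname(d), unname(trueChange(co)[names(d)]), tolerance = 1e-9)
})

test_that("severity structure is monotone across types and speeds are ordered", {
  co <- smallCohort(n = 1500, seed = 21)
  bl <- baselineRecords(co)
  cd <- SummarizedExperiment::colData(bl)
  types <- cd$nfhas_type
  romM <- romnet:::metricMatrix(bl, "rom_deg")
  cvM <- romnet:::metricMatrix(bl, "cv")
  spM <- romnet:::metricMatrix(bl, "speed")
  seTol <- function(x, g) {
    m <- tapply(x, g, mean); s <- tapply(x, g, function(v) sd(v) / sqrt(length(v)))
    list(m = m, s = s)
  }
  for (mv in romnet:::MOVEMENTS) {
    r <- seTol(romM[mv, ], types)
    cvs <- seTol(cvM[mv, ], types)
    for (k in 1:4) {
      tol3 <- 3 * sqrt(r$s[k]^2 + r$s[k + 1]^2)
      expect_lte(r$m[k + 1], r$m[k] + tol3)
      tolc <- 3 * sqrt(cvs$s[k]^2 + cvs$s[k + 1]^2)
      expect_gte(cvs$m[k + 1], cvs$m[k] - tolc)
    }
  }
  for (ty in 1:5) {
    sel <- types == ty
    rot <- mean(spM[c("Lrt", "Rrt"), sel])
    fe <- mean(spM[c("F", "E"), sel])
    lat <- mean(spM[c("Llb", "Rlb"), sel])
    expect_gte(rot, fe)
    expect_gte(fe, lat)
  }
})

test_that("configuration invariants are enforced", {
  expect_error(syntheticConfig(nPatients = 0), ">= 1")
  expect_error(recoveryModelSpec(group_proportions = c(0.5, 0.2, 0.1, 0.1, 0.2)),
               "sum")
  expect_error(recoveryModelSpec(noise_sd = -1), ">= 0")
  bad <- severityProfiles()
  bad$rom_mean[bad$type == 5] <- 100 # breaks monotonicity
  expect_error(syntheticConfig(profiles = bad), "non-increasing")
})

test_that("cohort CSV round trip preserves the data", {
  co <- smallCohort(n = 8, seed = 14)
  dir <- withr::local_tempdir()
  writeCohortCSV(co, dir)
  back <- readCohortCSV(dir)
  expect_equal(
    SummarizedExperiment::assay(back, "kinematics"),
    SummarizedExperiment::assay(co, "kinematics"),
    tolerance = 1e-12
  )
  expect_equal(trueChange(back), trueChange(co), tolerance = 1e-12)
  tr <- generateTrace("F", list(rom_mean = 50, cv_mean = 5, speed_mean = 60),
                      seed = 2)
  p <- file.path(dir, "trace.csv")
  writeTraceCSV(tr, p)
  back2 <- readTraceCSV(p, "F")
  expect_equal(back2@angle, tr@angle, tolerance = 1e-12)
})
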