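# Repetition segmentation and movement summaries against sinusoid closed
# forms: ROM = 2A and peak speed = A * omega for angle = A sin(omega t).

test_that("a 45-s sine at period 3 yields 15 repetitions with ROM 60", {
  tr <- makeSineTrace(A = 30, period = 3, duration = 45, rate = 100)
  reps <- segmentRepetitions(tr)
  expect_equal(nrow(reps), 15)
  expect_true(all(abs(reps$rom - 60) <= 0.1))
})

test_that("per-repetition peak speed matches A * omega within discretization", {
  tr <- makeSineTrace(A = 30, period = 3, duration = 45, rate = 100)
  reps <- segmentRepetitions(tr)
  expected <- 30 * 2 * pi / 3 # 62.83 deg/s
  expect_true(all(abs(reps$peak_speed - expected) / expected <= 0.02))
})

test_that("constant and sub-prominence traces produce no repetitions", {
  t <- seq(0, 10, by = 0.01)
  expect_equal(nrow(segmentRepetitions(AngleTrace("F", t, rep(12, length(t))))), 0)
  wiggle <- AngleTrace("F", t, 1.5 * sin(2 * pi * t / 2))
  expect_equal(nrow(segmentRepetitions(wiggle, prominence = 5)), 0)
})

test_that("segmentation is scale-equivariant and time-shift invariant", {
  set.seed(21)
  tr <- generateTrace("Lrt", list(rom_mean = 50, cv_mean = 8, speed_mean = 65),
                      seed = 13)
  reps <- segmentRepetitions(tr)
  k <- 2.5
  scaled <- AngleTrace(tr@movement, tr@time, pmin(k * tr@angle, 180))
  repsK <- segmentRepetitions(scaled)
  expect_equal(repsK$rom, k * reps$rom, tolerance = 1e-9)
  expect_equal(repsK$peak_speed, k * reps$peak_speed, tolerance = 1e-9)
  shifted <- AngleTrace(tr@movement, tr@time + 100, tr@angle)
  expect_equal(segmentRepetitions(shifted)$rom, reps$rom)
  sumA <- summarizeMovement(reps, "Lrt", 70)
  sumK <- summarizeMovement(repsK, "Lrt", 70)
  expect_equal(sumK$mean_rom, k * sumA$mean_rom, tolerance = 1e-9)
  expect_equal(sumK$cv, sumA$cv, tolerance = 1e-9)
})

test_that("movement summary averages repetitions and normalizes ROM", {
  reps <- data.frame(rom = c(8, 10, 12), peak_speed = c(60, 61, 62),
                     duration = 3, peak_angle = c(4, 5, 6), time_to_peak = 1)
  s <- summarizeMovement(reps, "F", normativeRom = 50)
  expect_equal(s$mean_rom, 10)
  expect_equal(s$cv, 20) # sd(8,10,12) = 2 exactly
  expect_equal(s$rom_normalized, 20)
  expect_equal(s$speed_to_peak, 61)
  expect_equal(s$n_repetitions, 3)

  const <- data.frame(rom = rep(10, 3), peak_speed = 60, duration = 3,
                      peak_angle = 5, time_to_peak = 1)
  expect_equal(summarizeMovement(const, "F", 50)$cv, 0)

  single <- data.frame(rom = 40, peak_speed = 55, duration = 3,
                       peak_angle = 40, time_to_peak = 1)
  expect_message(s1 <- summarizeMovement(single, "E", 80), "single repetition")
  expect_equal(s1$mean_rom, 40)
  expect_equal(s1$rom_normalized, 50)
  expect_equal(s1$cv, 0)
})

test_that("summary rejects empty repetitions and bad normative values", {
  empty <- data.frame(rom = numeric(0), peak_speed = numeric(0),
                      duration = numeric(0), peak_angle = numeric(0),
                      time_to_peak = numeric(0))
  expect_error(summarizeMovement(empty, "F", 50), "insufficient")
  reps <- data.frame(rom = 1:3, peak_speed = 1, duration = 1,
                     peak_angle = 1, time_to_peak = 1)
  expect_error(summarizeMovement(reps, "F", 0), "positive")
})

test_that("the alternative speed definition is available and differs", {
  tr <- makeSineTrace(A = 30, period = 3)
  reps <- segmentRepetitions(tr)
  a <- summarizeMovement(reps, "F", 60)
  b <- summarizeMovement(reps, "F", 60, speedMethod = "peak_over_time")
  expect_gt(a$speed_to_peak, b$speed_to_peak) # peak |v| exceeds mean slope
  expect_gt(b$speed_to_peak, 0)
})

test_that("AngleTrace validity enforces the contract", {
  expect_error(AngleTrace("F", c(0, 0.1), c(10, 200)), "180")
  expect_error(AngleTrace("F", c(0.1, 0), c(1, 2)), "increasing")
  expect_error(AngleTrace("X", c(0, 0.1), c(1, 2)), "movement")
  expect_error(AngleTrace("F", 0, 1), "2 samples")
})

test_that("normative lookup selects the right age band", {
  tab <- normativeROM()
  expect_equal(lookupNormative(tab, 25, "F"), 60)
  expect_equal(lookupNormative(tab, 45, "Lrt"), 67.5)
  expect_equal(lookupNormative(tab, 80, "E"), 52.5)
  expect_gt(lookupNormative(tab, 25, "Lrt"), lookupNormative(tab, 25, "Llb"))
})
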