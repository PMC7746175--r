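# Shared fixtures and independent oracles, all built in code.

makeSineTrace <- function(A = 30, period = 3, duration = 45, rate = 100,
                          movement = "F", phase = 0, offset = 0) {
  t <- seq(0, duration, by = 1 / rate)
  AngleTrace(movement, t, offset + A * sin(2 * pi * t / period + phase))
}

# Finite-difference Jacobian oracle (central differences), independent of
# the backpropagated implementation.
fdJacobian <- function(model, X, h = 1e-5) {
  th <- paramVector(model)
  cols <- lapply(seq_along(th), function(k) {
    up <- th; up[k] <- up[k] + h
    dn <- th; dn[k] <- dn[k] - h
    (forwardPass(setParamVector(model, up), X) -
       forwardPass(setParamVector(model, dn), X)) / (2 * h)
  })
  do.call(cbind, cols)
}

# Brute-force scaled-MAD outlier oracle written from the rule itself,
# without stats::mad.
bruteOutliers <- function(x) {
  srt <- sort(x)
  n <- length(srt)
  med <- if (n %% 2 == 1) srt[(n + 1) / 2] else mean(srt[n / 2 + 0:1])
  dev <- abs(x - med)
  sdev <- sort(dev)
  madRaw <- if (n %% 2 == 1) sdev[(n + 1) / 2] else mean(sdev[n / 2 + 0:1])
  scaledMad <- 1.4826 * madRaw
  if (scaledMad > 0) return(dev > 3 * scaledMad)
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  dev > 0 & dev > 3 * ((q[2] - q[1]) / 1.349)
}

# Minimal single-time-point assessment block: a SummarizedExperiment with
# the 24 kinematics rows, rom_norm set per movement, other metrics filled
# with plausible constants unless given.
makeAssessmentSE <- function(romNorm, ids = "P1", cv = 5, speed = 60,
                             romDeg = NULL, timePoint = "baseline") {
  romNorm <- matrix(romNorm, nrow = 6)
  n <- ncol(romNorm)
  if (length(ids) != n) ids <- sprintf("P%d", seq_len(n))
  if (is.null(romDeg)) romDeg <- romNorm * 0.6
  cv <- matrix(cv, 6, n)
  speed <- matrix(speed, 6, n)
  m <- matrix(NA_real_, 24, n,
              dimnames = list(romnet:::kinRowNames(),
                              paste0(ids, ".", timePoint)))
  for (j in seq_along(romnet:::MOVEMENTS)) {
    mv <- romnet:::MOVEMENTS[j]
    m[paste0(mv, ".rom_deg"), ] <- romDeg[j, ]
    m[paste0(mv, ".rom_norm"), ] <- romNorm[j, ]
    m[paste0(mv, ".cv"), ] <- cv[j, ]
    m[paste0(mv, ".speed"), ] <- speed[j, ]
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(kinematics = m),
    colData = S4Vectors::DataFrame(
      patient_id = ids, time_point = rep(timePoint, n),
      age = rep(35, n), sex = rep("F", n),
      height_m = rep(1.7, n), mass_kg = rep(70, n),
      nfhas = rep(NA_real_, n), nfhas_type = rep(NA_integer_, n),
      row.names = colnames(m)
    )
  )
}

smallCohort <- function(n = 60, seed = 1, noise = NULL, ...) {
  rec <- if (is.null(noise)) recoveryModelSpec() else recoveryModelSpec(noise_sd = noise)
  generateCohort(syntheticConfig(nPatients = n, seed = seed, recovery = rec, ...))
}
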