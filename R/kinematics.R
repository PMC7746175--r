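# Repetition segmentation and per-movement kinematic summaries.
#
# A recording is a self-paced oscillation between the ROM limits of a
# movement pair. Each repetition is one full excursion to the peak angle
# and back; per repetition we measure the ROM (max - min angle within the
# cycle), the peak angular speed on the way to the peak, and the cycle
# duration.

# Finite-difference angular velocity: central differences in the interior,
# one-sided at the endpoints.
angularVelocity <- function(time, angle) {
  n <- length(angle)
  v <- numeric(n)
  if (n < 2L) return(v)
  v[1] <- (angle[2] - angle[1]) / (time[2] - time[1])
  v[n] <- (angle[n] - angle[n - 1]) / (time[n] - time[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    v[i] <- (angle[i + 1] - angle[i - 1]) / (time[i + 1] - time[i - 1])
  }
  v
}

# Alternating extrema with a prominence filter (reversal filtering, as in
# turning-point extraction): keep only swings of at least `prominence`
# degrees separated by at least `minHalfPeriod` seconds. Returns a
# data.frame with sample index and type ("max"/"min").
findAlternatingExtrema <- function(time, angle, prominence, minHalfPeriod) {
  n <- length(angle)
  d <- diff(angle)
  s <- sign(d)
  # plateau-safe slope signs: carry the last non-zero sign forward
  for (i in seq_along(s)) {
    if (s[i] == 0) s[i] <- if (i > 1) s[i - 1] else 0
  }
  cand_idx <- integer(0)
  cand_type <- character(0)
  for (i in seq_len(n - 2L)) {
    if (s[i] != 0 && s[i + 1] != 0 && s[i] != s[i + 1]) {
      cand_idx <- c(cand_idx, i + 1L)
      cand_type <- c(cand_type, if (s[i] > 0) "max" else "min")
    }
  }
  keep_idx <- integer(0)
  keep_type <- character(0)
  for (k in seq_along(cand_idx)) {
    i <- cand_idx[k]
    ty <- cand_type[k]
    if (!length(keep_idx)) {
      keep_idx <- i
      keep_type <- ty
      next
    }
    last <- length(keep_idx)
    if (ty == keep_type[last]) {
      # same type twice: keep the more extreme turning point
      better <- if (ty == "max") {
        angle[i] > angle[keep_idx[last]]
      } else {
        angle[i] < angle[keep_idx[last]]
      }
      if (better) keep_idx[last] <- i
    } else {
      swing <- abs(angle[i] - angle[keep_idx[last]])
      dt <- time[i] - time[keep_idx[last]]
      if (swing >= prominence && dt >= minHalfPeriod) {
        keep_idx <- c(keep_idx, i)
        keep_type <- c(keep_type, ty)
      }
      # otherwise: a sub-threshold wiggle, ignored
    }
  }
  data.frame(idx = keep_idx, type = keep_type, stringsAsFactors = FALSE)
}

#' Segment an oscillatory trace into repetitions
#'
#' Detects alternating angle extrema whose swing exceeds `prominence`
#' degrees and whose spacing exceeds `minHalfPeriod` seconds, then forms
#' one repetition per peak excursion: the window between the surrounding
#' opposite extrema (the trace ends serve as boundaries for the first and
#' last cycle). Within each window, `rom` is the max minus min angle,
#' `peak_speed` the largest absolute finite-difference angular velocity
#' between window start and the peak sample, `peak_angle`/`time_to_peak`
#' support the alternative speed definition, and `duration` the window
#' length.
#'
#' @param trace an [AngleTrace-class].
#' @param prominence minimum swing (degrees) for a turning point to count.
#' @param minHalfPeriod minimum time (s) between successive extrema.
#' @return data.frame with one row per repetition (`rom`, `peak_speed`,
#'   `duration`, `peak_angle`, `time_to_peak`); zero rows when no complete
#'   cycle is found (e.g. a constant trace).
#' @examples
#' t <- seq(0, 45, by = 0.01)
#' tr <- AngleTrace("F", t, 30 * sin(2 * pi * t / 3))
#' nrow(segmentRepetitions(tr)) # 15 repetitions in 45 s at period 3 s
#' @export
segmentRepetitions <- function(trace, prominence = 5, minHalfPeriod = 0.3) {
  stopifnot(methods::is(trace, "AngleTrace"))
  if (prominence <= 0 || minHalfPeriod < 0) {
    stop("prominence must be positive and minHalfPeriod non-negative")
  }
  time <- trace@time
  angle <- trace@angle
  ext <- findAlternatingExtrema(time, angle, prominence, minHalfPeriod)
  empty <- data.frame(
    rom = numeric(0), peak_speed = numeric(0), duration = numeric(0),
    peak_angle = numeric(0), time_to_peak = numeric(0)
  )
  if (!nrow(ext) || !any(ext$type == "max") || !any(ext$type == "min")) {
    return(empty)
  }
  med <- stats::median(angle)
  devMax <- mean(abs(angle[ext$idx[ext$type == "max"]] - med))
  devMin <- mean(abs(angle[ext$idx[ext$type == "min"]] - med))
  # orient so that the farther excursion from the resting level is "the peak"
  a <- if (devMax >= devMin) angle else -angle
  ext2 <- findAlternatingExtrema(time, a, prominence, minHalfPeriod)
  peaks <- ext2$idx[ext2$type == "max"]
  valleys <- ext2$idx[ext2$type == "min"]
  if (!length(peaks)) return(empty)
  bounds <- sort(unique(c(1L, valleys, length(a))))
  v <- angularVelocity(time, angle)
  reps <- lapply(peaks, function(p) {
    lo <- max(bounds[bounds < p])
    hi <- min(bounds[bounds > p])
    w <- lo:hi
    pk <- w[which.max(a[w])]
    up <- lo:pk
    data.frame(
      rom = max(angle[w]) - min(angle[w]),
      peak_speed = max(abs(v[up])),
      duration = time[hi] - time[lo],
      peak_angle = abs(angle[pk]),
      time_to_peak = time[pk] - time[lo]
    )
  })
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  out
}

#' Summarise the repetitions of one movement
#'
#' Averages the per-repetition metrics of one recording: `mean_rom` and
#' `speed_to_peak` are means over repetitions, `cv` is
#' `100 * sd(rom) / mean(rom)` (0 for a single repetition, flagged via a
#' message, so downstream z-scoring never receives missing values), and
#' `rom_normalized` is `100 * mean_rom / normativeRom`.
#'
#' @param reps data.frame from [segmentRepetitions()].
#' @param movement movement identifier.
#' @param normativeRom normative ROM for this movement and the patient's
#'   age (degrees, `> 0`); see [normativeROM()].
#' @param speedMethod `"peak_velocity"` (default: mean of per-repetition
#'   peak absolute angular velocities) or `"peak_over_time"` (mean of peak
#'   angle divided by time to peak).
#' @return one-row data.frame: `movement`, `n_repetitions`, `mean_rom`,
#'   `rom_normalized`, `cv`, `speed_to_peak`.
#' @examples
#' reps <- data.frame(
#'   rom = c(8, 10, 12), peak_speed = c(60, 62, 64),
#'   duration = 3, peak_angle = c(4, 5, 6), time_to_peak = 0.75
#' )
#' summarizeMovement(reps, "F", normativeRom = 50)
#' @export
summarizeMovement <- function(reps, movement, normativeRom,
                              speedMethod = c("peak_velocity", "peak_over_time")) {
  speedMethod <- match.arg(speedMethod)
  if (is.null(reps) || !nrow(reps)) {
    stop("insufficient data: no complete repetition in this recording")
  }
  if (!is.numeric(normativeRom) || normativeRom <= 0) {
    stop("normativeRom must be a positive number of degrees")
  }
  meanRom <- mean(reps$rom)
  cv <- if (nrow(reps) > 1L) 100 * stats::sd(reps$rom) / meanRom else {
    message(sprintf("single repetition for %s: ROM CV set to 0", movement))
    0
  }
  speed <- switch(speedMethod,
    peak_velocity = mean(reps$peak_speed),
    peak_over_time = mean(reps$peak_angle / reps$time_to_peak)
  )
  data.frame(
    movement = movement,
    n_repetitions = nrow(reps),
    mean_rom = meanRom,
    rom_normalized = 100 * meanRom / normativeRom,
    cv = cv,
    speed_to_peak = speed,
    stringsAsFactors = FALSE
  )
}

#' Summarise a set of traces into the six-movement assessment block
#'
#' Convenience wrapper running [segmentRepetitions()] and
#' [summarizeMovement()] over a list of six traces.
#'
#' @param traces named list of [AngleTrace-class] objects covering all six
#'   movements.
#' @param age patient age in years (for the normative lookup).
#' @param normTable normative table as returned by [normativeROM()].
#' @param ... passed to [segmentRepetitions()].
#' @return data.frame with one row per movement.
#' @export
summarizeTraces <- function(traces, age, normTable = normativeROM(), ...) {
  missing <- setdiff(MOVEMENTS, names(traces))
  if (length(missing)) {
    stop("incomplete assessment: missing traces for ",
         paste(missing, collapse = ", "))
  }
  rows <- lapply(MOVEMENTS, function(m) {
    reps <- segmentRepetitions(traces[[m]], ...)
    summarizeMovement(reps, m, lookupNormative(normTable, age, m))
  })
  do.call(rbind, rows)
}
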