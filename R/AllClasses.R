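#' AngleTrace: one movement-pair recording
#'
#' A sampled neck-angle time series for one movement direction pair
#' (flexion/extension, left/right lateral bending, left/right rotation).
#' Time is in seconds and strictly increasing; angles are in degrees between
#' the head and the thoracic spine.
#'
#' @slot movement single movement identifier, one of `"F"`, `"E"`, `"Llb"`,
#'   `"Rlb"`, `"Lrt"`, `"Rrt"`.
#' @slot time numeric vector of sampling times (s), strictly increasing.
#' @slot angle numeric vector of angles (deg), same length as `time`,
#'   bounded by +/-180.
#'
#' @seealso [AngleTrace()], [segmentRepetitions()], [generateTrace()]
#' @export
setClass("AngleTrace",
  representation(movement = "character", time = "numeric", angle = "numeric")
)

setValidity("AngleTrace", function(object) {
  msg <- character()
  if (length(object@movement) != 1L || !object@movement %in% MOVEMENTS) {
    msg <- c(msg, sprintf(
      "movement must be one of %s", paste(MOVEMENTS, collapse = ", ")
    ))
  }
  if (length(object@time) < 2L) {
    msg <- c(msg, "a trace needs at least 2 samples")
  }
  if (length(object@time) != length(object@angle)) {
    msg <- c(msg, "time and angle must have equal length")
  }
  if (anyNA(object@time) || anyNA(object@angle) ||
      any(!is.finite(object@time)) || any(!is.finite(object@angle))) {
    msg <- c(msg, "time and angle must be finite")
  } else {
    if (length(object@time) >= 2L && any(diff(object@time) <= 0)) {
      msg <- c(msg, "time must be strictly increasing")
    }
    if (any(abs(object@angle) > 180)) {
      msg <- c(msg, "angles must lie within [-180, 180] degrees")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AngleTrace
#'
#' @param movement movement identifier (`"F"`, `"E"`, `"Llb"`, `"Rlb"`,
#'   `"Lrt"`, `"Rrt"`).
#' @param time numeric vector of sample times in seconds, strictly increasing.
#' @param angle numeric vector of angles in degrees.
#' @return an [AngleTrace-class] object.
#' @examples
#' t <- seq(0, 45, by = 0.02)
#' tr <- AngleTrace("F", t, 30 * sin(2 * pi * t / 3))
#' tr
#' @export
AngleTrace <- function(movement, time, angle) {
  methods::new("AngleTrace",
    movement = as.character(movement),
    time = as.numeric(time), angle = as.numeric(angle)
  )
}

setMethod("show", "AngleTrace", function(object) {
  dur <- diff(range(object@time))
  cat(sprintf(
    "AngleTrace [%s]: %d samples over %.1f s, angle range [%.1f, %.1f] deg\n",
    object@movement, length(object@time), dur,
    min(object@angle), max(object@angle)
  ))
})

#' NeckCohort: paired baseline/follow-up assessment container
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' column per patient x time point. The `"kinematics"` assay has 24 rows
#' (`<movement>.<metric>` for the six movements and metrics `rom_deg`,
#' `rom_norm`, `cv`, `speed`); `colData` carries `patient_id`, `time_point`
#' (`"baseline"`/`"followup"`), demographics, the NFHAS score and severity
#' type, and — for synthetic cohorts — the ground-truth NFHAS change.
#'
#' @seealso [generateCohort()], [baselineRecords()], [followupRecords()],
#'   [trueChange()]
#' @export
setClass("NeckCohort", contains = "SummarizedExperiment")

setValidity("NeckCohort", function(object) {
  msg <- character()
  if (!"kinematics" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'kinematics' is required")
  } else if (!all(kinRowNames() %in% rownames(object))) {
    msg <- c(msg, "kinematics assay must contain all 24 <movement>.<metric> rows")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("patient_id", "time_point")
  if (!all(need %in% colnames(cd))) {
    msg <- c(msg, "colData needs patient_id and time_point")
  } else {
    if (!all(cd$time_point %in% c("baseline", "followup"))) {
      msg <- c(msg, "time_point must be 'baseline' or 'followup'")
    }
    tab <- table(cd$patient_id, cd$time_point)
    if (ncol(tab) == 2 && !all(tab == 1)) {
      msg <- c(msg, "each patient must appear exactly once per time point")
    }
  }
  if (length(msg)) msg else TRUE
})

#' NetModel: feed-forward regression network
#'
#' Weights and biases of a fully connected feed-forward network with
#' bounded sigmoidal (tanh) or identity hidden activations and a linear
#' single-output layer, as used for NFHAS-change regression.
#'
#' @slot nInputs number of input neurons.
#' @slot hidden integer vector of hidden-layer widths (length 0, 1 or 2).
#' @slot weights list of weight matrices, one per layer,
#'   `dim = c(fan_in, fan_out)`.
#' @slot biases list of bias vectors, one per layer.
#' @slot activation `"tanh"` or `"identity"` (hidden layers; the output is
#'   always linear).
#' @slot seed integer seed used for initialization.
#'
#' @seealso [netModel()], [trainLM()], [netJacobian()]
#' @export
setClass("NetModel",
  representation(
    nInputs = "integer", hidden = "integer",
    weights = "list", biases = "list",
    activation = "character", seed = "integer"
  )
)

setValidity("NetModel", function(object) {
  msg <- character()
  sizes <- c(object@nInputs, object@hidden, 1L)
  nl <- length(sizes) - 1L
  if (length(object@weights) != nl || length(object@biases) != nl) {
    msg <- c(msg, "one weight matrix and bias vector per layer required")
  } else {
    for (l in seq_len(nl)) {
      w <- object@weights[[l]]
      b <- object@biases[[l]]
      if (!is.matrix(w) || nrow(w) != sizes[l] || ncol(w) != sizes[l + 1L]) {
        msg <- c(msg, sprintf("weight matrix %d has wrong shape", l))
      }
      if (length(b) != sizes[l + 1L]) {
        msg <- c(msg, sprintf("bias vector %d has wrong length", l))
      }
      if (anyNA(w) || any(!is.finite(w)) || anyNA(b) || any(!is.finite(b))) {
        msg <- c(msg, sprintf("layer %d parameters must be finite", l))
      }
    }
  }
  if (!object@activation %in% c("tanh", "identity")) {
    msg <- c(msg, "activation must be 'tanh' or 'identity'")
  }
  if (any(object@hidden < 1L)) msg <- c(msg, "hidden widths must be >= 1")
  if (length(object@hidden) > 2L) msg <- c(msg, "at most 2 hidden layers")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NetModel", function(object) {
  arch <- paste(c(object@nInputs, object@hidden, 1L), collapse = "-")
  cat(sprintf(
    "NetModel %s (%s hidden, linear output), %d parameters, init seed %d\n",
    arch, object@activation, nParams(object), object@seed
  ))
})

#' EvaluationReport: held-out performance summary
#'
#' Regression R of real on predicted NFHAS change, held-out MSE, quadrant
#' agreement of change direction, an error histogram, and per-quadrant
#' paired pre/post test tables for ROM, speed and ROM CV.
#'
#' @slot r Pearson correlation of predicted vs. real change.
#' @slot slope,intercept least-squares line of real on predicted change.
#' @slot mse held-out mean squared error (NFHAS points squared).
#' @slot n number of held-out patients.
#' @slot quadrants data.frame with quadrant label, count and percentage.
#' @slot histogram list with `edges` and `counts` of prediction errors.
#' @slot tables named list (one per quadrant) of paired-test data.frames.
#'
#' @seealso [evaluatePredictions()], [quadrantTables()]
#' @export
setClass("EvaluationReport",
  representation(
    r = "numeric", slope = "numeric", intercept = "numeric",
    mse = "numeric", n = "integer",
    quadrants = "data.frame", histogram = "list", tables = "list"
  )
)

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf(
    "EvaluationReport (n = %d held-out patients)\n  R = %.3f, MSE = %.2f, real ~ %.3f + %.3f * predicted\n",
    object@n, object@r, object@mse, object@intercept, object@slope
  ))
  q <- object@quadrants
  cat("  quadrants (real predicted):",
      paste(sprintf("%s: %.1f%%", q$label, q$percent), collapse = ", "), "\n")
  if (length(object@tables)) {
    cat("  paired pre/post tables for", length(object@tables), "quadrant groups\n")
  }
})
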