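#' @include AllClasses.R
NULL

#' Construct a NeckCohort from assay matrix and column metadata
#'
#' Low-level constructor; most users obtain cohorts from [generateCohort()]
#' or [readCohortCSV()].
#'
#' @param kinematics 24 x (2 n) numeric matrix, rows named
#'   `<movement>.<metric>`.
#' @param colData data.frame (or DataFrame) with one row per column of
#'   `kinematics`; must contain `patient_id` and `time_point`.
#' @param metadata list of run metadata (configuration, ground truth, ...).
#' @return a [NeckCohort-class].
#' @export
NeckCohort <- function(kinematics, colData, metadata = list()) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(kinematics = kinematics),
    colData = S4Vectors::DataFrame(colData, check.names = FALSE)
  )
  S4Vectors::metadata(se) <- metadata
  methods::new("NeckCohort", se)
}

#' Accessors for NeckCohort
#'
#' `baselineRecords()`/`followupRecords()` subset a cohort to one time
#' point, ordered by patient id so the two subsets align column-for-column.
#' `patientIds()` returns the unique patient identifiers and
#' `trueChange()` the stored ground-truth NFHAS change of a synthetic
#' cohort (named by patient).
#'
#' @param x a [NeckCohort-class].
#' @return a `NeckCohort` subset, a character vector, or a named numeric
#'   vector respectively.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("baselineRecords", function(x) standardGeneric("baselineRecords"))

#' @rdname cohort-accessors
#' @export
setGeneric("followupRecords", function(x) standardGeneric("followupRecords"))

#' @rdname cohort-accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname cohort-accessors
#' @export
setGeneric("trueChange", function(x) standardGeneric("trueChange"))

.timeSubset <- function(x, tp) {
  cd <- SummarizedExperiment::colData(x)
  sub <- x[, cd$time_point == tp]
  sub[, order(SummarizedExperiment::colData(sub)$patient_id)]
}

#' @rdname cohort-accessors
setMethod("baselineRecords", "NeckCohort", function(x) .timeSubset(x, "baseline"))

#' @rdname cohort-accessors
setMethod("followupRecords", "NeckCohort", function(x) .timeSubset(x, "followup"))

#' @rdname cohort-accessors
setMethod("patientIds", "NeckCohort", function(x) {
  sort(unique(SummarizedExperiment::colData(x)$patient_id))
})

#' @rdname cohort-accessors
setMethod("trueChange", "NeckCohort", function(x) {
  bl <- baselineRecords(x)
  cd <- SummarizedExperiment::colData(bl)
  if (!"true_change" %in% colnames(cd)) {
    stop("this cohort carries no ground-truth change (not synthetic?)")
  }
  stats::setNames(as.numeric(cd$true_change), cd$patient_id)
})

setMethod("show", "NeckCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  n <- length(unique(cd$patient_id))
  cat(sprintf(
    "NeckCohort: %d patients x %d time points (%d assay rows)\n",
    n, length(unique(cd$time_point)), nrow(object)
  ))
  if ("nfhas" %in% colnames(cd)) {
    bl <- cd$nfhas[cd$time_point == "baseline"]
    cat(sprintf("  baseline NFHAS: median %.1f [%.1f, %.1f]\n",
                stats::median(bl), min(bl), max(bl)))
  }
})

# Pull one metric (e.g. "rom_norm") for all six movements out of a
# single-time-point cohort; returns 6 x n matrix with movement rownames.
metricMatrix <- function(se, metric) {
  rows <- paste(MOVEMENTS, metric, sep = ".")
  missing <- setdiff(rows, rownames(se))
  if (length(missing)) {
    stop("incomplete record: missing kinematics rows ",
         paste(missing, collapse = ", "))
  }
  m <- SummarizedExperiment::assay(se, "kinematics")[rows, , drop = FALSE]
  rownames(m) <- MOVEMENTS
  m
}
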