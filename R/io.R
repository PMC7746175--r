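# CSV/JSON interchange. All tabular artifacts are headered CSV with
# documented column names; metadata travels as JSON. Writers are
# deterministic (no timestamps), so a rerun under the same configuration
# reproduces every file byte for byte.

.cohortWideColumns <- function() {
  metrics <- c("rom_deg", "rom_normalized_pct", "cv_pct", "speed_deg_s")
  as.vector(t(outer(MOVEMENTS, metrics, paste, sep = "_")))
}

.seToWide <- function(se) {
  cd <- SummarizedExperiment::colData(se)
  wide <- data.frame(
    patient_id = cd$patient_id,
    age = cd$age, sex = cd$sex,
    height_m = cd$height_m, mass_kg = cd$mass_kg,
    stringsAsFactors = FALSE
  )
  metricOf <- c(
    rom_deg = "rom_deg", rom_normalized_pct = "rom_norm",
    cv_pct = "cv", speed_deg_s = "speed"
  )
  for (m in MOVEMENTS) {
    for (suffix in names(metricOf)) {
      row <- paste(m, metricOf[[suffix]], sep = ".")
      wide[[paste(m, suffix, sep = "_")]] <-
        as.numeric(SummarizedExperiment::assay(se, "kinematics")[row, ])
    }
  }
  wide$nfhas <- cd$nfhas
  wide$nfhas_type <- cd$nfhas_type
  wide[order(wide$patient_id), ]
}

#' Write / read a cohort as CSV tables
#'
#' `writeCohortCSV()` emits `cohort_baseline.csv` and
#' `cohort_followup.csv` (one row per patient: id, demographics,
#' `<movement>_{rom_deg, rom_normalized_pct, cv_pct, speed_deg_s}`, NFHAS
#' and severity type) plus `cohort_truth.json` carrying the generating
#' configuration and ground-truth change of synthetic cohorts.
#' `readCohortCSV()` reverses this.
#'
#' @param cohort a [NeckCohort-class].
#' @param dir output directory (created if missing).
#' @return the directory (write) or a [NeckCohort-class] (read),
#'   invisibly/visibly.
#' @export
writeCohortCSV <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(.seToWide(baselineRecords(cohort)),
                   file.path(dir, "cohort_baseline.csv"), row.names = FALSE)
  utils::write.csv(.seToWide(followupRecords(cohort)),
                   file.path(dir, "cohort_followup.csv"), row.names = FALSE)
  meta <- S4Vectors::metadata(cohort)
  if (length(meta)) {
    jsonlite::write_json(
      list(config = meta$config, truth = lapply(meta$truth, as.list)),
      file.path(dir, "cohort_truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(dir)
}

.wideToBlock <- function(wide) {
  m <- matrix(NA_real_, 24L, nrow(wide), dimnames = list(kinRowNames(), NULL))
  metricOf <- c(
    rom_deg = "rom_deg", rom_normalized_pct = "rom_norm",
    cv_pct = "cv", speed_deg_s = "speed"
  )
  for (mv in MOVEMENTS) {
    for (suffix in names(metricOf)) {
      m[paste(mv, metricOf[[suffix]], sep = "."), ] <-
        wide[[paste(mv, suffix, sep = "_")]]
    }
  }
  m
}

#' @rdname writeCohortCSV
#' @export
readCohortCSV <- function(dir) {
  bPath <- file.path(dir, "cohort_baseline.csv")
  fPath <- file.path(dir, "cohort_followup.csv")
  if (!file.exists(bPath) || !file.exists(fPath)) {
    stop("no cohort CSVs in ", dir)
  }
  bl <- utils::read.csv(bPath, stringsAsFactors = FALSE)
  fu <- utils::read.csv(fPath, stringsAsFactors = FALSE)
  bl <- bl[order(bl$patient_id), ]
  fu <- fu[order(fu$patient_id), ]
  if (!identical(bl$patient_id, fu$patient_id)) {
    stop("pairing error: baseline and follow-up patient ids differ")
  }
  assay <- cbind(.wideToBlock(bl), .wideToBlock(fu))
  n <- nrow(bl)
  colnames(assay) <- c(paste0(bl$patient_id, ".baseline"),
                       paste0(fu$patient_id, ".followup"))
  cd <- data.frame(
    patient_id = c(bl$patient_id, fu$patient_id),
    time_point = rep(c("baseline", "followup"), each = n),
    age = c(bl$age, fu$age), sex = c(bl$sex, fu$sex),
    height_m = c(bl$height_m, fu$height_m),
    mass_kg = c(bl$mass_kg, fu$mass_kg),
    nfhas = c(bl$nfhas, fu$nfhas),
    nfhas_type = c(bl$nfhas_type, fu$nfhas_type),
    row.names = colnames(assay),
    stringsAsFactors = FALSE
  )
  meta <- list()
  tPath <- file.path(dir, "cohort_truth.json")
  if (file.exists(tPath)) {
    truth <- jsonlite::read_json(tPath, simplifyVector = TRUE)
    meta <- list(config = truth$config, truth = truth$truth)
    if (!is.null(truth$truth$true_change)) {
      tc <- unlist(truth$truth$true_change)
      cd$true_change <- tc[cd$patient_id]
    }
  }
  NeckCohort(assay, cd, meta)
}

#' Write / read an angle trace as CSV
#'
#' Columns `time_s`, `angle_deg`; one file per patient and movement.
#'
#' @param trace an [AngleTrace-class].
#' @param path CSV file path.
#' @param movement movement id of the trace being read.
#' @return the path (write) or an [AngleTrace-class] (read).
#' @export
writeTraceCSV <- function(trace, path) {
  utils::write.csv(
    data.frame(time_s = trace@time, angle_deg = trace@angle),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname writeTraceCSV
#' @export
readTraceCSV <- function(path, movement) {
  tab <- utils::read.csv(path)
  if (!all(c("time_s", "angle_deg") %in% colnames(tab))) {
    stop("trace CSV needs columns time_s, angle_deg")
  }
  AngleTrace(movement, tab$time_s, tab$angle_deg)
}
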