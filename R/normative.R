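# Age-banded normative ROM table. "Normalized ROM" is the percentage of the
# normative value for the patient's age band and movement. No normative
# table is printed with the assessment protocol, so the table is
# user-supplied configuration; the packaged default (shipped as
# inst/extdata/normative_rom_default.csv) uses adult reference values in
# the range reported across cervical goniometry literature, declining 5%
# per decade after the twenties. It is a package default for the synthetic
# pipeline, not a published normative dataset.

#' Normative ROM table
#'
#' Reads a normative table with columns `age_band` (e.g. `"30-39"` or
#' `"70+"`), `movement` and `normative_deg`. With no argument the packaged
#' default table is returned.
#'
#' @param path optional CSV path to a user-supplied table.
#' @return data.frame with columns `age_band`, `movement`, `normative_deg`.
#' @examples
#' head(normativeROM())
#' @export
normativeROM <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "normative_rom_default.csv",
                        package = "romnet", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_band", "movement", "normative_deg")
  if (!all(need %in% colnames(tab))) {
    stop("normative table needs columns age_band, movement, normative_deg")
  }
  if (any(tab$normative_deg <= 0)) stop("normative ROM values must be positive")
  tab
}

# Parse "a-b" / "a+" age bands into lower bounds.
.bandLower <- function(bands) {
  as.numeric(sub("[-+].*$", "", bands))
}

#' Look up the normative ROM for an age and movement
#'
#' @param normTable table from [normativeROM()].
#' @param age age in years.
#' @param movement movement identifier.
#' @return normative ROM in degrees.
#' @export
lookupNormative <- function(normTable, age, movement) {
  rows <- normTable[normTable$movement == movement, , drop = FALSE]
  if (!nrow(rows)) stop("no normative entry for movement ", movement)
  lower <- .bandLower(rows$age_band)
  ord <- order(lower)
  rows <- rows[ord, , drop = FALSE]
  lower <- lower[ord]
  i <- findInterval(age, lower)
  if (i < 1L) i <- 1L
  rows$normative_deg[i]
}
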