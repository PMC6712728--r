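#' Per-patient scores and extravascular lung water of the validation cohort
#'
#' The packaged score table of the 12-patient ARDS validation cohort: the
#' automatic QLUSS, the four semi-quantitative scores (qLUSS, %LUSS, cLUSS,
#' nLUSS) and thermo-dilution extravascular lung water (EVLW, mL/kg) for
#' each patient. This is the canonical fixture on which the regression,
#' correlation and comparison analyses run offline.
#'
#' @return A 12-row data.frame with columns `patient`, `QLUSS`, `qLUSS`,
#'   `percent_LUSS`, `cLUSS`, `nLUSS`, `EVLW`.
#' @examples
#' head(lusTable1())
#' @export
lusTable1 <- function() {
  utils::read.csv(system.file("extdata", "table1.csv", package = "qluss"),
                  stringsAsFactors = FALSE)
}
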