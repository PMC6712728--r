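## Semi-quantitative scores computed from clinician annotations, and the
## patient-level aggregation of the automatic per-frame percentages.

.patterns <- c("a_lines", "spaced_blines", "coalescent", "tissue_like",
               "white_lung")

#' Validate a per-patient annotation table
#'
#' One clinician annotation per intercostal region: the observed pattern,
#' the maximum B-line count over the respiratory cycle (fused B-lines count
#' as one), the visual percentage of the rib space filled with confluent
#' B-lines, and the count of additional discrete (non-confluent) B-lines.
#'
#' @param annotations data.frame with columns `patient_id`, `region_id`,
#'   `pattern`, `bline_count`, `confluent_percent`,
#'   `discrete_extra_blines`.
#' @param regions expected region vocabulary; scoring normally requires the
#'   full 12-region exam but a reduced vocabulary is accepted for research
#'   use (scores are then reported with the region count).
#' @return The validated data.frame, invisibly usable downstream.
#' @export
validateAnnotations <- function(annotations, regions = lusRegions()) {
  need <- c("patient_id", "region_id", "pattern", "bline_count",
            "confluent_percent", "discrete_extra_blines")
  if (!all(need %in% names(annotations)))
    stop("annotations must have columns ", paste(need, collapse = ", "))
  a <- annotations
  missing <- setdiff(regions, a$region_id)
  if (length(missing))
    stop("incomplete-exam error: missing region(s) ",
         paste(missing, collapse = ", "))
  extra <- setdiff(a$region_id, regions)
  if (length(extra))
    stop("unknown region(s) ", paste(extra, collapse = ", "))
  if (anyDuplicated(a$region_id))
    stop("more than one annotation for region(s) ",
         paste(unique(a$region_id[duplicated(a$region_id)]), collapse = ", "))
  if (!all(a$pattern %in% .patterns))
    stop("unknown pattern(s) ",
         paste(setdiff(a$pattern, .patterns), collapse = ", "))
  if (any(a$bline_count < 0) || any(a$discrete_extra_blines < 0))
    stop("B-line counts must be non-negative")
  if (any(a$confluent_percent < 0 | a$confluent_percent > 100))
    stop("confluent_percent must lie in [0, 100]")
  bad <- a$pattern == "a_lines" & a$confluent_percent > 0
  if (any(bad))
    stop("inconsistent-annotation error: confluent_percent > 0 with ",
         "a_lines pattern in region(s) ",
         paste(a$region_id[bad], collapse = ", "))
  if (any(a$pattern == "white_lung" & a$confluent_percent != 100))
    stop("white_lung implies confluent_percent = 100")
  if (any(a$pattern == "a_lines" & a$bline_count > 1))
    stop("inconsistent-annotation error: a_lines pattern with more than ",
         "one B-line")
  a
}

#' Total B-line count (nLUSS)
#'
#' Sum over regions of the maximum number of B-lines seen in the
#' intercostal space, fused B-lines counted as one.
#'
#' @inheritParams validateAnnotations
#' @return Integer score.
#' @export
scoreNLUSS <- function(annotations, regions = lusRegions()) {
  a <- validateAnnotations(annotations, regions)
  as.integer(sum(a$bline_count))
}

#' Percentage-based B-line-equivalent score (%LUSS)
#'
#' Per region: the visual percentage of the rib space filled with confluent
#' B-lines divided by 10, plus any other discrete B-line seen at the same
#' time; a white-lung region counts as 10 B-lines. The patient score is the
#' sum over regions.
#'
#' @inheritParams validateAnnotations
#' @return Numeric score (0--120 for a full exam).
#' @export
scorePercentLUSS <- function(annotations, regions = lusRegions()) {
  a <- validateAnnotations(annotations, regions)
  v <- ifelse(a$pattern == "white_lung", 10,
              a$confluent_percent / 10 + a$discrete_extra_blines)
  sum(v)
}

## one region's aeration-loss grade; `splitCoalescent` distinguishes cLUSS
## (all coalescence graded 2) from qLUSS (graded by pleural involvement).
## The published anchors leave "exactly 2 B-lines" between grade 0
## ("A-lines or < 2 B-lines") and grade 1 ("3 or more spaced B-lines");
## aeration loss is present, so 2 spaced B-lines are graded 1 here. The
## alternative (grade 0) is this single `>= 2`.
.gradeRegion <- function(pattern, bline_count, confluent_percent,
                         splitCoalescent) {
  if (pattern == "tissue_like") return(3L)
  if (pattern %in% c("coalescent", "white_lung")) {
    if (!splitCoalescent) return(2L)
    return(if (confluent_percent > 50) 2L else 1L)
  }
  if (bline_count >= 2) 1L else 0L           # a_lines / spaced_blines
}

#' Aeration-loss coalescence score (cLUSS)
#'
#' Each region is graded 0--3: 0 for A-lines or fewer than 2 B-lines, 1 for
#' spaced B-lines, 2 for coalescent B-lines (including white lung), 3 for a
#' tissue-like (consolidation) pattern; the patient score is the sum.
#'
#' @inheritParams validateAnnotations
#' @return Integer score (0--36 for a full exam).
#' @export
scoreCLUSS <- function(annotations, regions = lusRegions()) {
  a <- validateAnnotations(annotations, regions)
  as.integer(sum(mapply(.gradeRegion, a$pattern, a$bline_count,
                        a$confluent_percent, splitCoalescent = FALSE)))
}

#' Modified coalescence score (qLUSS)
#'
#' Identical to [scoreCLUSS()] except that coalescent regions are graded 1
#' when the confluent B-lines occupy at most 50% of the intercostal space
#' and 2 when more (white lung remains 2). Consequently qLUSS <= cLUSS for
#' every annotation set.
#'
#' @inheritParams validateAnnotations
#' @return Integer score (0--36 for a full exam).
#' @export
scoreQLUSSSemiquant <- function(annotations, regions = lusRegions()) {
  a <- validateAnnotations(annotations, regions)
  as.integer(sum(mapply(.gradeRegion, a$pattern, a$bline_count,
                        a$confluent_percent, splitCoalescent = TRUE)))
}

#' Patient-level automatic score (QLUSS)
#'
#' Arithmetic mean of the per-frame B-line percentages over the patient's
#' regions. Frames from consolidated regions are included, but the result
#' carries a reliability warning attribute when any region is annotated
#' `tissue_like`: the column scan is not a valid B-line measure over
#' consolidated lung.
#'
#' @param frameResults list of [FrameResult-class], one per region.
#' @param annotations optional annotation table used only to raise the
#'   consolidation reliability warning.
#' @param regions expected region vocabulary.
#' @return Numeric percentage in \[0, 100\]; attribute
#'   `reliability_warning` is `TRUE` when a tissue-like region is present.
#' @export
aggregateQLUSS <- function(frameResults, annotations = NULL,
                           regions = lusRegions()) {
  stopifnot(all(vapply(frameResults, is, logical(1), "FrameResult")))
  got <- vapply(frameResults, regionId, character(1))
  if (!anyNA(got)) {
    missing <- setdiff(regions, got)
    if (length(missing))
      stop("incomplete-exam error: missing frame(s) for region(s) ",
           paste(missing, collapse = ", "))
  } else if (length(frameResults) != length(regions)) {
    stop("incomplete-exam error: expected ", length(regions),
         " frames, got ", length(frameResults))
  }
  q <- mean(vapply(frameResults, blinePercent, numeric(1)))
  warn <- !is.null(annotations) && any(annotations$pattern == "tissue_like")
  attr(q, "reliability_warning") <- warn
  q
}

#' Assemble a per-patient score panel
#'
#' Computes all four semi-quantitative scores from the annotations and, when
#' frame results are supplied, the automatic QLUSS, in the layout of the
#' study's per-patient score table.
#'
#' @inheritParams aggregateQLUSS
#' @param annotations annotation table for one patient.
#' @param evlw optional extravascular lung water (mL/kg) from
#'   thermo-dilution.
#' @return One-row data.frame with columns `patient`, `QLUSS`, `qLUSS`,
#'   `percent_LUSS`, `cLUSS`, `nLUSS`, `EVLW`.
#' @export
scorePanel <- function(annotations, frameResults = NULL, evlw = NA_real_,
                       regions = lusRegions()) {
  a <- validateAnnotations(annotations, regions)
  data.frame(
    patient = a$patient_id[1L],
    QLUSS = if (is.null(frameResults)) NA_real_ else
      round(as.numeric(aggregateQLUSS(frameResults, a, regions)), 2),
    qLUSS = scoreQLUSSSemiquant(a, regions),
    percent_LUSS = scorePercentLUSS(a, regions),
    cLUSS = scoreCLUSS(a, regions),
    nLUSS = scoreNLUSS(a, regions),
    EVLW = evlw,
    stringsAsFactors = FALSE)
}
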