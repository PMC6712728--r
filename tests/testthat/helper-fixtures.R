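# Fixtures are built in code; nothing binary ships with the tests.

# ROI wrapper around a raw intensity matrix
makeRoi <- function(px, pleuralRow = 1L, offset = 0L) {
  new("SubPleuralROI", pixels = matrix(as.integer(px), nrow = nrow(px)),
      pleuralRow = as.integer(pleuralRow), offset = as.integer(offset))
}

makeMask <- function(m, stage = "kmeans") {
  new("BinaryMask", pixels = m, stage = stage)
}

# frame with a single bright pleural row over a dark background
makeLineFrame <- function(h = 64L, w = 40L, lineRow = 20L, lineVal = 220L,
                          bg = 15L) {
  px <- matrix(bg, h, w)
  px[lineRow, ] <- lineVal
  new("UltrasoundFrame", pixels = matrix(as.integer(px), h, w))
}

# complete 12-region annotation table, all A-lines unless overridden
makeAnnotations <- function(patient = "p1",
                            pattern = "a_lines",
                            bline_count = 0L,
                            confluent_percent = 0,
                            discrete_extra_blines = 0L) {
  regions <- lusRegions()
  data.frame(patient_id = patient, region_id = regions,
             pattern = rep_len(pattern, length(regions)),
             bline_count = rep_len(bline_count, length(regions)),
             confluent_percent = rep_len(confluent_percent, length(regions)),
             discrete_extra_blines = rep_len(discrete_extra_blines,
                                             length(regions)),
             stringsAsFactors = FALSE)
}

# set one region's annotation
setRegion <- function(ann, region, pattern = NULL, bline_count = NULL,
                      confluent_percent = NULL,
                      discrete_extra_blines = NULL) {
  i <- match(region, ann$region_id)
  if (!is.null(pattern)) ann$pattern[i] <- pattern
  if (!is.null(bline_count)) ann$bline_count[i] <- bline_count
  if (!is.null(confluent_percent)) ann$confluent_percent[i] <- confluent_percent
  if (!is.null(discrete_extra_blines))
    ann$discrete_extra_blines[i] <- discrete_extra_blines
  ann
}

# exhaustive-threshold oracle for the 1-D 2-means step: minimizes
# within-cluster sum of squares over every integer cut point, straight from
# the raw pixel vector (independent of the histogram implementation)
thresholdOracle <- function(values) {
  best <- Inf
  bestThr <- NA_integer_
  for (thr in 0:254) {
    lo <- values[values <= thr]
    hi <- values[values > thr]
    if (!length(lo) || !length(hi)) next
    wss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (wss < best) {
      best <- wss
      bestThr <- thr
    }
  }
  bestThr
}

# midrank oracle written independently of base rank(): average the
# positions of tied values explicitly
midrankOracle <- function(x) {
  s <- sort(x)
  pos <- seq_along(s)
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    ties <- which(s == x[i])
    r[i] <- mean(pos[ties])
  }
  r
}
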