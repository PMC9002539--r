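#' PROP taster-status classification from paper-disk LMS ratings
#'
#' Subjects rate a PROP-impregnated disk and a 1 mol/L NaCl reference disk on
#' the 100-mm labeled magnitude scale. PROP ratings below 15 mm classify a
#' subject as a non-taster (NT), above 67 mm as a super-taster (ST), and
#' anything between as a medium taster (MT). Because NaCl ratings do not vary
#' with taster status, they break ties near the cutoffs: within a borderline
#' band of +/- \code{band} mm of either threshold, a subject rating NaCl
#' higher than PROP is pushed to the non-taster side of that threshold and a
#' subject rating PROP higher than NaCl to the taster side. Equal ratings in
#' the band resolve to MT (and are flagged).
#'
#' @param prop_rating_mm PROP disk rating(s), mm on the LMS, in [0,100].
#' @param nacl_rating_mm NaCl disk rating(s), mm on the LMS, in [0,100].
#' @param band half-width (mm) of the borderline band around each threshold.
#' @param thresholds length-2 numeric, NT and ST cutoffs (default 15 and 67).
#' @return character vector in \{"NT","MT","ST"\} with attribute
#'   \code{"tie"}: logical, TRUE where an in-band NaCl tie forced MT.
#' @examples
#' classifyProp(10, 40)  # "NT"
#' classifyProp(80, 40)  # "ST"
#' classifyProp(40, 41)  # "MT"
#' classifyProp(16, 50)  # borderline, NaCl >> PROP -> "NT"
#' @export
classifyProp <- function(prop_rating_mm, nacl_rating_mm, band = 5,
                         thresholds = c(NT = 15, ST = 67)) {
  p <- as.numeric(prop_rating_mm)
  s <- as.numeric(nacl_rating_mm)
  if (length(s) == 1L) s <- rep(s, length(p))
  if (length(p) != length(s)) stop("ratings must have equal length")
  if (any(!is.finite(p)) || any(!is.finite(s)) ||
      any(p < 0 | p > 100) || any(s < 0 | s > 100))
    stop("ratings must lie in [0,100] mm")
  lo <- thresholds[[1L]]; hi <- thresholds[[2L]]
  out <- character(length(p))
  tie <- logical(length(p))
  for (i in seq_along(p)) {
    nearLo <- abs(p[i] - lo) <= band
    nearHi <- abs(p[i] - hi) <= band
    if (nearLo) {
      if (s[i] > p[i]) out[i] <- "NT"
      else if (s[i] < p[i]) out[i] <- "MT"
      else { out[i] <- "MT"; tie[i] <- TRUE }
    } else if (nearHi) {
      if (p[i] > s[i]) out[i] <- "ST"
      else if (p[i] < s[i]) out[i] <- "MT"
      else { out[i] <- "MT"; tie[i] <- TRUE }
    } else if (p[i] < lo) out[i] <- "NT"
    else if (p[i] > hi) out[i] <- "ST"
    else out[i] <- "MT"
  }
  attr(out, "tie") <- tie
  out
}

#' Drop rare ASVs by total-abundance fraction
#'
#' Removes ASVs whose summed count across all samples falls below
#' \code{minTotalFraction} of the grand total. The sample set and retained
#' counts are unchanged. With the default threshold 0 the table passes
#' through untouched (the filter is opt-in plumbing for spurious-ASV removal).
#'
#' @param counts samples-by-ASVs count matrix.
#' @param minTotalFraction proportion in [0,1).
#' @return filtered count matrix.
#' @export
filterLowAbundance <- function(counts, minTotalFraction = 0) {
  counts <- validateCountMatrix(counts)
  if (minTotalFraction < 0 || minTotalFraction >= 1)
    stop("minTotalFraction must be in [0,1)")
  tot <- colSums(counts)
  keep <- tot >= minTotalFraction * sum(tot)
  if (minTotalFraction == 0) keep <- rep(TRUE, ncol(counts))
  if (!any(keep)) stop("empty table: all ASVs removed")
  counts[, keep, drop = FALSE]
}
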