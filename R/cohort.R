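#' Published subject-characteristics summary of the motivating trial
#'
#' The cranberry-polyphenol oral-rinse trial enrolled 20 subjects in four
#' gender-by-taster-status subgroups; their published per-subgroup counts
#' and mean age/BMI ship with the package as a plain-text table. These
#' subgroup summaries are inputs (the subject-level data are not public);
#' [pooledMean] recovers the overall cohort means from them.
#'
#' @return data.frame(gender, taster_status, n, mean_age_years, mean_bmi).
#' @export
subjectCharacteristics <- function() {
  utils::read.delim(system.file("extdata", "subject_characteristics.tsv",
                                package = "OralGuilds"),
                    stringsAsFactors = FALSE)
}

#' Pool subgroup means into an overall mean
#'
#' Sample-size-weighted mean: \eqn{\sum n_i m_i / \sum n_i}.
#'
#' @param means subgroup means.
#' @param n subgroup sizes.
#' @return scalar pooled mean.
#' @export
pooledMean <- function(means, n) {
  stopifnot(length(means) == length(n), all(n > 0))
  sum(n * means) / sum(n)
}

#' Sequencing-reads bookkeeping
#'
#' Total usable reads implied by a per-sample average over the retained
#' samples (a paired design of \code{nSubjects} subjects at two timepoints
#' minus \code{nDropped} failed samples).
#'
#' @param meanReadsPerSample average usable reads per retained sample.
#' @param nSubjects subjects, each sampled at two timepoints.
#' @param nDropped samples lost (default 1).
#' @return list(n_samples, total_reads, total_reads_millions).
#' @export
readsBookkeeping <- function(meanReadsPerSample, nSubjects = 20L,
                             nDropped = 1L) {
  nSamples <- 2L * nSubjects - nDropped
  total <- meanReadsPerSample * nSamples
  list(n_samples = nSamples, total_reads = total,
       total_reads_millions = total / 1e6)
}
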