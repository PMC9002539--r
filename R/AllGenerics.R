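#' @include AllClasses.R
NULL

#' Rarefy samples to a common read depth
#'
#' Subsamples each sample's reads without replacement to exactly \code{depth}
#' reads. Samples with fewer total reads than \code{depth} are dropped with a
#' warning. Deterministic given \code{seed}.
#'
#' @param x samples-by-ASVs count matrix, or an [AsvExperiment].
#' @param depth target reads per sample.
#' @param seed integer seed.
#' @param ... passed to methods.
#' @return an object of the same kind as \code{x}, rarefied.
#' @export
setGeneric("rarefy", function(x, depth, seed = 1L, ...) standardGeneric("rarefy"))

#' Alpha diversity per sample
#'
#' @param x samples-by-ASVs count matrix, or an [AsvExperiment].
#' @param metrics subset of \code{c("observed_asvs","shannon",
#'   "pielou_evenness","faith_pd")}.
#' @param tree rooted \code{phylo}; required iff \code{"faith_pd"} requested
#'   (for [AsvExperiment] the attached tree is used).
#' @param base logarithm base for Shannon (default 2, i.e. bits).
#' @param ... passed to methods.
#' @return long-format data.frame (sample_id, metric, value).
#' @export
setGeneric("alphaDiversity",
  function(x, metrics = c("observed_asvs", "shannon", "pielou_evenness",
                          "faith_pd"),
           tree = NULL, base = 2, ...)
    standardGeneric("alphaDiversity"))

#' UniFrac distances
#'
#' Weighted (raw by default, abundance-weighted) or unweighted
#' (presence/absence) UniFrac over a rooted phylogeny, computed with a single
#' post-order accumulation of per-branch descendant mass.
#'
#' @param x samples-by-ASVs count matrix, or an [AsvExperiment].
#' @param tree rooted \code{phylo} covering all ASVs with counts.
#' @param weighted logical; abundance-weighted variant.
#' @param normalized logical; for the weighted variant, divide each pairwise
#'   distance by its standard normaliser
#'   \eqn{\sum_b len(b) (p_A(b)+p_B(b))}. Ignored when \code{weighted=FALSE}.
#' @param ... passed to methods.
#' @return a \code{\link[stats]{dist}} with attribute \code{method} set to
#'   \code{"weighted_unifrac"} or \code{"unweighted_unifrac"}.
#' @export
setGeneric("uniFrac",
  function(x, tree = NULL, weighted = FALSE, normalized = FALSE, ...)
    standardGeneric("uniFrac"))

#' Prevalence filter
#'
#' Retains ASVs present (count > 0) in strictly more than
#' \code{minPrevalence} of samples.
#'
#' @param x samples-by-ASVs count matrix, or an [AsvExperiment].
#' @param minPrevalence strict prevalence threshold in (0,1); default 0.5
#'   ("more than half of the samples").
#' @param ... passed to methods.
#' @return list with \code{table} (the filtered object) and \code{prevalence}
#'   (named per-ASV prevalence fractions, all ASVs).
#' @export
setGeneric("prevalenceFilter",
  function(x, minPrevalence = 0.5, ...) standardGeneric("prevalenceFilter"))

#' @rdname networkSummary
#' @export
setGeneric("networkSummary", function(net) standardGeneric("networkSummary"))
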