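#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' AsvExperiment: counts, sample metadata and a phylogeny in one object
#'
#' Extends \linkS4class{SummarizedExperiment}: ASVs are rows, samples are
#' columns, the single assay \code{"counts"} holds non-negative integer read
#' counts, \code{colData} holds the study design (subject, taster status,
#' timepoint, covariates), and the \code{tree} slot optionally carries a
#' rooted \code{\link[ape]{phylo}} whose tips cover the ASVs.
#'
#' @slot tree a rooted \code{ape::phylo} with branch lengths, or \code{NULL}.
#'
#' @seealso [AsvExperiment()] for the user-facing constructor,
#'   [asvCounts()], [sampleData()], [asvTree()] for accessors.
#' @export
setClass("AsvExperiment",
  contains = "SummarizedExperiment",
  slots = c(tree = "ANY")
)

.validCounts <- function(m) {
  if (is.null(m)) return("assay 'counts' is missing")
  if (any(!is.finite(m))) return("counts contain NA/NaN/Inf")
  if (any(m < 0)) return("negative count")
  if (any(m != round(m))) return("counts must be integers")
  NULL
}

setValidity("AsvExperiment", function(object) {
  msgs <- character()
  a <- SummarizedExperiment::assays(object)
  if (!"counts" %in% names(a)) {
    msgs <- c(msgs, "assay 'counts' required")
  } else {
    bad <- .validCounts(a[["counts"]])
    if (!is.null(bad)) msgs <- c(msgs, bad)
  }
  if (anyDuplicated(rownames(object))) msgs <- c(msgs, "duplicate ASV ids")
  if (anyDuplicated(colnames(object))) msgs <- c(msgs, "duplicate sample ids")
  if (nrow(object) < 2L) msgs <- c(msgs, "need at least 2 ASVs")
  if (ncol(object) < 2L) msgs <- c(msgs, "need at least 2 samples")
  tr <- object@tree
  if (!is.null(tr)) {
    if (!inherits(tr, "phylo")) {
      msgs <- c(msgs, "tree must be an ape 'phylo' object or NULL")
    } else {
      if (is.null(tr$edge.length)) {
        msgs <- c(msgs, "tree has no branch lengths")
      } else if (any(tr$edge.length < 0)) {
        msgs <- c(msgs, "negative branch length in tree")
      }
      if (anyDuplicated(tr$tip.label)) msgs <- c(msgs, "duplicate tree tip labels")
    }
  }
  cd <- SummarizedExperiment::colData(object)
  if (all(c("subject_id", "timepoint") %in% colnames(cd))) {
    key <- paste(cd$subject_id, cd$timepoint, sep = "\r")
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate (subject_id, timepoint) in design")
  }
  if (length(msgs)) msgs else TRUE
})

#' Ordination result (PCoA / adjusted PCoA)
#'
#' @slot coordinates samples x axes matrix (positive-eigenvalue axes only),
#'   axes ordered by descending eigenvalue.
#' @slot eigenvalues all eigenvalues of the (possibly covariate-projected)
#'   Gower matrix, descending; negatives are retained here but produce no
#'   coordinate axis.
#' @slot proportionExplained fraction of the positive-eigenvalue sum per
#'   coordinate axis.
#' @slot negativeEigenvalueMass absolute sum of negative eigenvalues.
#' @slot method "pcoa" or "apcoa".
#' @export
setClass("OrdinationResult",
  slots = c(
    coordinates = "matrix",
    eigenvalues = "numeric",
    proportionExplained = "numeric",
    negativeEigenvalueMass = "numeric",
    method = "character"
  )
)

setValidity("OrdinationResult", function(object) {
  msgs <- character()
  if (is.unsorted(rev(object@eigenvalues)))
    msgs <- c(msgs, "eigenvalues must be in descending order")
  pe <- object@proportionExplained
  if (length(pe) && (any(pe < -1e-12) || any(pe > 1 + 1e-12)))
    msgs <- c(msgs, "proportionExplained outside [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' Guild assignment: a disjoint partition of prevalent ASVs
#'
#' @slot membership named integer vector: guild number per assigned ASV.
#'   Guilds are numbered 1..G by descending summed abundance.
#' @slot unassigned ASV ids left out (undefined correlations, or accepted
#'   nodes smaller than the minimum guild size).
#' @slot audit list of split/accept decisions taken while descending the
#'   clustering tree (node id, size, minimum pairwise r, decision).
#' @slot parameters the clustering parameters used.
#' @export
setClass("GuildAssignment",
  slots = c(
    membership = "integer",
    unassigned = "character",
    audit = "list",
    parameters = "list"
  )
)

setValidity("GuildAssignment", function(object) {
  msgs <- character()
  if (is.null(names(object@membership)) && length(object@membership))
    msgs <- c(msgs, "membership must be named by ASV id")
  if (anyDuplicated(names(object@membership)))
    msgs <- c(msgs, "an ASV appears in more than one guild")
  if (length(intersect(names(object@membership), object@unassigned)))
    msgs <- c(msgs, "ASV both assigned and unassigned")
  if (length(msgs)) msgs else TRUE
})

#' Tripartite correlation network over guilds, proteins and sensory attributes
#'
#' @slot nodes data.frame with columns \code{id}, \code{type}
#'   (guild/protein/sensory); only nodes with degree >= 1 unless built with
#'   \code{keepIsolated = TRUE}.
#' @slot edges data.frame with columns \code{node_a}, \code{type_a},
#'   \code{node_b}, \code{type_b}, \code{estimate} (rm-correlation r or LMM
#'   slope), \code{q}, \code{sign} ("+"/"-"), \code{style} ("solid"/"dashed";
#'   dashed iff both endpoints are guilds).
#' @slot group taster group label the network was built for ("NT" or "ST").
#' @slot qThreshold the strict FDR threshold edges had to beat.
#' @export
setClass("CorrelationNetwork",
  slots = c(
    nodes = "data.frame",
    edges = "data.frame",
    group = "character",
    qThreshold = "numeric"
  )
)

setValidity("CorrelationNetwork", function(object) {
  msgs <- character()
  e <- object@edges
  if (nrow(e)) {
    if (any(e$node_a == e$node_b)) msgs <- c(msgs, "self-edge present")
    key <- apply(cbind(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b)),
                 1L, paste, collapse = "\r")
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate undirected edge")
    if (any(e$q >= object@qThreshold))
      msgs <- c(msgs, "edge with q >= threshold retained")
    dashed <- e$type_a == "guild" & e$type_b == "guild"
    if (any((e$style == "dashed") != dashed))
      msgs <- c(msgs, "edge style must be dashed iff both endpoints are guilds")
  }
  if (length(msgs)) msgs else TRUE
})

#' Synthetic study scenario
#'
#' Parameters of the paired-design generator: two PROP taster groups sampled
#' at two timepoints, a block ("guild") co-abundance structure among the
#' prevalent ASVs, a planted baseline compositional difference between the
#' groups, a planted intervention shift restricted to the non-taster group
#' post-intervention, and protein/sensory tables with subject-level random
#' effects plus planted couplings to guild factors.
#'
#' @slot nSubjectsPerGroup subjects per taster group (NT and ST).
#' @slot nAsvs total ASVs simulated.
#' @slot nPrevalent ASVs given high baseline abundance and guild membership.
#' @slot nGuilds number of co-abundance blocks among the prevalent ASVs.
#' @slot readDepth reads per sample (multinomial total).
#' @slot guildEffectBaseline log-scale factor-mean shift applied to one guild
#'   in ST samples at both timepoints.
#' @slot interventionEffectNT log-scale factor-mean shift applied to one guild
#'   in NT post-intervention samples only.
#' @slot loadingScale multiplier on the ASV loadings (recovery-sweep knob).
#' @slot subjectSd sd of the subject-level offset added to each guild factor.
#' @slot asvNoiseSd sd of ASV-level log-abundance noise.
#' @slot dropout data.frame (subject_id, timepoint) of samples to omit.
#' @slot nProteins,nSensory phenotype table widths.
#' @slot proteinCoupling strength of planted protein/guild-factor couplings.
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticScenario",
  slots = c(
    nSubjectsPerGroup = "integer",
    nAsvs = "integer",
    nPrevalent = "integer",
    nGuilds = "integer",
    readDepth = "integer",
    guildEffectBaseline = "numeric",
    interventionEffectNT = "numeric",
    loadingScale = "numeric",
    subjectSd = "numeric",
    asvNoiseSd = "numeric",
    dropout = "data.frame",
    nProteins = "integer",
    nSensory = "integer",
    proteinCoupling = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticScenario", function(object) {
  msgs <- character()
  if (object@nPrevalent > object@nAsvs)
    msgs <- c(msgs, "nPrevalent must not exceed nAsvs")
  if (object@nGuilds > object@nPrevalent)
    msgs <- c(msgs, "nGuilds must not exceed nPrevalent")
  if (object@readDepth <= 0L) msgs <- c(msgs, "readDepth must be positive")
  eff <- c(object@guildEffectBaseline, object@interventionEffectNT,
           object@loadingScale, object@subjectSd, object@asvNoiseSd)
  if (any(!is.finite(eff))) msgs <- c(msgs, "effects must be finite")
  if (length(msgs)) msgs else TRUE
})
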