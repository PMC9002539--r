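#' @include AllGenerics.R
NULL

# Single post-order pass over the tree: per-branch descendant mass for every
# sample. Returns the branch length vector and an edges x samples matrix of
# the fraction of each sample's reads descending from each branch.
.branchMass <- function(counts, tree, asProportions = TRUE) {
  present <- colnames(counts)[colSums(counts) > 0]
  .checkTreeCovers(tree, present)
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("empty sample: ", paste(rownames(counts)[tot == 0], collapse = ", "))
  P <- counts
  if (asProportions) P <- counts / tot
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  A <- matrix(0, nrow(counts), nnode)
  idx <- match(colnames(counts), tree$tip.label)
  A[, idx[!is.na(idx)]] <- as.matrix(P[, !is.na(idx), drop = FALSE])
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    A[, ord$edge[k, 1L]] <- A[, ord$edge[k, 1L]] + A[, ord$edge[k, 2L]]
  }
  list(
    lengths = ord$edge.length,
    mass = t(A[, ord$edge[, 2L], drop = FALSE]),  # edges x samples
    samples = rownames(counts)
  )
}

#' @rdname uniFrac
setMethod("uniFrac", "matrix", function(x, tree = NULL, weighted = FALSE,
                                        normalized = FALSE, ...) {
  if (is.null(tree)) stop("uniFrac needs a tree")
  bm <- .branchMass(x, tree)
  n <- length(bm$samples)
  len <- bm$lengths
  M <- bm$mass
  D <- matrix(0, n, n, dimnames = list(bm$samples, bm$samples))
  if (weighted) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      d <- sum(len * abs(M[, i] - M[, j]))
      if (normalized) {
        nrm <- sum(len * (M[, i] + M[, j]))
        d <- if (nrm > 0) d / nrm else 0
      }
      D[i, j] <- D[j, i] <- d
    }
  } else {
    I <- M > 0
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      un <- sum(len[xor(I[, i], I[, j])])
      tot <- sum(len[I[, i] | I[, j]])
      D[i, j] <- D[j, i] <- if (tot > 0) un / tot else 0
    }
  }
  d <- stats::as.dist(D)
  attr(d, "method") <- if (weighted) "weighted_unifrac" else "unweighted_unifrac"
  d
})

#' @rdname uniFrac
setMethod("uniFrac", "AsvExperiment", function(x, tree = NULL, weighted = FALSE,
                                               normalized = FALSE, ...) {
  uniFrac(asvCounts(x), tree = if (is.null(tree)) asvTree(x) else tree,
          weighted = weighted, normalized = normalized)
})

.alphaOne <- function(p, metric, base) {
  nz <- p[p > 0]
  switch(metric,
    observed_asvs = length(nz),
    shannon = -sum(nz * log(nz, base = base)),
    pielou_evenness = {
      s <- length(nz)
      if (s < 2L) 0 else (-sum(nz * log(nz, base = base))) / log(s, base = base)
    },
    stop("unknown metric: ", metric))
}

#' @rdname alphaDiversity
setMethod("alphaDiversity", "matrix", function(x, metrics = c("observed_asvs",
    "shannon", "pielou_evenness", "faith_pd"), tree = NULL, base = 2, ...) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  tot <- rowSums(x)
  if (any(tot == 0)) stop("empty sample")
  out <- list()
  if ("faith_pd" %in% metrics) {
    if (is.null(tree)) stop("faith_pd needs a tree")
    bm <- .branchMass(x, tree, asProportions = FALSE)
    fpd <- colSums(bm$lengths * (bm$mass > 0))
    out[["faith_pd"]] <- fpd
  }
  P <- x / tot
  for (m in setdiff(metrics, "faith_pd")) {
    out[[m]] <- apply(P, 1L, .alphaOne, metric = m, base = base)
  }
  out <- out[intersect(metrics, names(out))]
  do.call(rbind, lapply(names(out), function(m)
    data.frame(sample_id = rownames(x), metric = m, value = unname(out[[m]]),
               stringsAsFactors = FALSE)))
})

#' @rdname alphaDiversity
setMethod("alphaDiversity", "AsvExperiment", function(x, metrics = c("observed_asvs",
    "shannon", "pielou_evenness", "faith_pd"), tree = NULL, base = 2, ...) {
  alphaDiversity(asvCounts(x), metrics = metrics,
                 tree = if (is.null(tree)) asvTree(x) else tree, base = base)
})

#' Faith's phylogenetic diversity for a single community
#'
#' Total branch length of the minimal rooted subtree spanning the present
#' tips and the root (rooted convention: the path to the root counts).
#'
#' @param counts named count (or presence) vector over ASVs.
#' @param tree rooted \code{phylo}.
#' @return branch-length units.
#' @export
faithPD <- function(counts, tree) {
  m <- matrix(as.numeric(counts), nrow = 2, ncol = length(counts), byrow = TRUE,
              dimnames = list(c("s", "s2"), names(counts)))
  res <- alphaDiversity(m, metrics = "faith_pd", tree = tree)
  res$value[1L]
}

#' @rdname rarefy
setMethod("rarefy", "matrix", function(x, depth, seed = 1L, ...) {
  if (depth <= 0) stop("depth must be positive")
  tot <- rowSums(x)
  keep <- tot >= depth
  if (!any(keep)) stop("all samples below rarefaction depth")
  if (any(!keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(rownames(x)[!keep], collapse = ", "))
  x <- x[keep, , drop = FALSE]
  set.seed(as.integer(seed))
  out <- x
  for (i in seq_len(nrow(x))) {
    if (sum(x[i, ]) == depth) next  # already exactly at depth
    reads <- rep.int(seq_len(ncol(x)), x[i, ])
    drawn <- sample(reads, depth)
    out[i, ] <- tabulate(drawn, nbins = ncol(x))
  }
  storage.mode(out) <- "integer"
  out
})

#' @rdname rarefy
setMethod("rarefy", "AsvExperiment", function(x, depth, seed = 1L, ...) {
  r <- rarefy(asvCounts(x), depth, seed = seed)
  AsvExperiment(r, design = sampleData(x)[rownames(r), , drop = FALSE],
                tree = asvTree(x))
})
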