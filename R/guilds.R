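#' @include AllGenerics.R rmcorr.R
NULL

#' @rdname prevalenceFilter
setMethod("prevalenceFilter", "matrix", function(x, minPrevalence = 0.5, ...) {
  if (minPrevalence <= 0 || minPrevalence >= 1)
    stop("minPrevalence must be in (0,1)")
  prev <- colMeans(x > 0)
  keep <- prev > minPrevalence  # strict: "more than half of the samples"
  if (!any(keep)) stop("no ASV passes the prevalence filter")
  list(table = x[, keep, drop = FALSE], prevalence = prev)
})

#' @rdname prevalenceFilter
setMethod("prevalenceFilter", "AsvExperiment", function(x, minPrevalence = 0.5, ...) {
  res <- prevalenceFilter(asvCounts(x), minPrevalence = minPrevalence)
  res$table <- AsvExperiment(res$table, design = sampleData(x), tree = asvTree(x))
  res
})

#' Relative abundances, optionally arcsine-square-root transformed
#'
#' Proportions are always taken against the full per-sample total, so a
#' prevalent subset keeps whole-community proportions. The variance-
#' stabilising transform is \eqn{\arcsin(\sqrt p) \in [0, \pi/2]}.
#'
#' @param counts samples-by-ASVs count matrix.
#' @param transform "none" or "arcsine_sqrt".
#' @param subset optional ASV ids to keep (after computing proportions).
#' @return samples-by-ASVs numeric matrix with attribute
#'   \code{"transform"}.
#' @export
toRelative <- function(counts, transform = c("none", "arcsine_sqrt"),
                       subset = NULL) {
  transform <- match.arg(transform)
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("zero-total sample")
  p <- counts / tot
  if (!is.null(subset)) p <- p[, subset, drop = FALSE]
  if (transform == "arcsine_sqrt") p <- asin(sqrt(p))
  attr(p, "transform") <- transform
  p
}

.hclustMembers <- function(merge, node) {
  # tips under a node of an hclust merge matrix (node > 0: internal row)
  if (node < 0L) return(-node)
  c(.hclustMembers(merge, merge[node, 1L]),
    .hclustMembers(merge, merge[node, 2L]))
}

#' Dichotomic tree-based guild identification
#'
#' The co-abundance guild construction: (1) all pairwise repeated-measures
#' correlations r among the ASVs; (2) distance \eqn{d = (1-r)/2}, mapping
#' r in [-1,1] onto [0,1] so anticorrelated ASVs are maximally distant;
#' (3) agglomerative clustering tree (default average linkage); (4) top-down
#' dichotomic traversal from the root: a node is accepted as a guild when the
#' minimum pairwise r among its members exceeds \code{rThreshold}, otherwise
#' it splits into its two children and recursion continues; (5) accepted
#' nodes smaller than \code{minGuildSize} go to the unassigned set; (6)
#' guilds are numbered 1..G by descending summed abundance. ASVs with
#' undefined correlations (constant residuals) are set aside as unassigned
#' before clustering. Deterministic given input order; at equal merge
#' heights \code{stats::hclust}'s order (lower ASV index first) decides.
#'
#' @param abund samples-by-ASVs abundance matrix restricted to the prevalent
#'   ASVs (conventionally arcsine-square-root transformed proportions).
#' @param subjects subject id per row of \code{abund}.
#' @param minGuildSize minimum members for an accepted guild (default 2).
#' @param rThreshold minimum within-guild pairwise r. The default (NULL)
#'   uses the critical correlation for two-tailed significance at
#'   \code{alpha} with \eqn{df = N - k - 1}
#'   (\eqn{r_{crit} = t_{1-\alpha/2,df}/\sqrt{df + t^2}}): every pair inside
#'   an accepted guild must be individually significantly co-abundant. With
#'   the repeated-measures df of a small paired study, correlations below
#'   this scale are indistinguishable from estimation noise, and accepting
#'   nodes on them merges unrelated blocks. Set to a number (e.g. 0) to
#'   override.
#' @param alpha significance level for the adaptive threshold (default 0.05).
#' @param linkage hclust linkage (default "average").
#' @param abundanceWeights optional per-ASV weights used for guild numbering
#'   (default: column sums of \code{abund}).
#' @return a [GuildAssignment-class].
#' @export
guildCluster <- function(abund, subjects, minGuildSize = 2L, rThreshold = NULL,
                         linkage = "average", abundanceWeights = NULL,
                         alpha = 0.05) {
  abund <- as.matrix(abund)
  if (ncol(abund) < 3L) stop("need >= 3 prevalent ASVs")
  rm <- rmCorrelationMatrix(abund, subjects)
  if (is.null(rThreshold)) {
    tcrit <- stats::qt(1 - alpha / 2, rm$df)
    rThreshold <- tcrit / sqrt(rm$df + tcrit^2)
  }
  R <- rm$r
  undef <- vapply(seq_len(ncol(R)), function(i) all(is.na(R[i, -i])), TRUE)
  unassigned <- colnames(abund)[undef]
  if (length(unassigned))
    warning(length(unassigned), " ASV(s) with undefined correlation unassigned")
  ok <- !undef
  if (sum(ok) < 2L) stop("fewer than 2 ASVs with defined correlations")
  R <- R[ok, ok, drop = FALSE]
  ids <- colnames(abund)[ok]
  D <- stats::as.dist((1 - R) / 2)
  hc <- stats::hclust(D, method = linkage)

  audit <- list()
  guilds <- list()
  visit <- function(node) {
    m <- .hclustMembers(hc$merge, node)
    if (length(m) == 1L) {
      audit[[length(audit) + 1L]] <<- list(node = node, size = 1L,
                                           min_r = NA_real_, decision = "accept")
      guilds[[length(guilds) + 1L]] <<- m
      return(invisible())
    }
    sub <- R[m, m]
    minr <- min(sub[upper.tri(sub)])
    if (minr > rThreshold) {
      audit[[length(audit) + 1L]] <<- list(node = node, size = length(m),
                                           min_r = minr, decision = "accept")
      guilds[[length(guilds) + 1L]] <<- m
    } else {
      audit[[length(audit) + 1L]] <<- list(node = node, size = length(m),
                                           min_r = minr, decision = "split")
      visit(hc$merge[node, 1L])
      visit(hc$merge[node, 2L])
    }
  }
  visit(nrow(hc$merge))

  w <- if (is.null(abundanceWeights)) colSums(abund) else abundanceWeights
  keep <- vapply(guilds, length, 1L) >= minGuildSize
  unassigned <- c(unassigned, ids[unlist(guilds[!keep], use.names = FALSE)])
  guilds <- guilds[keep]
  if (length(guilds)) {
    gw <- vapply(guilds, function(m) sum(w[ids[m]]), numeric(1))
    guilds <- guilds[order(gw, decreasing = TRUE)]
    membership <- integer(0)
    for (g in seq_along(guilds)) {
      mm <- stats::setNames(rep(g, length(guilds[[g]])), ids[guilds[[g]]])
      membership <- c(membership, mm)
    }
  } else membership <- stats::setNames(integer(0), character(0))
  methods::new("GuildAssignment",
    membership = membership,
    unassigned = unassigned,
    audit = audit,
    parameters = list(minGuildSize = as.integer(minGuildSize),
                      rThreshold = rThreshold, linkage = linkage))
}

#' Accessors for GuildAssignment
#' @param x a [GuildAssignment-class].
#' @return \code{guildMembership}: named integer vector; \code{nGuilds}:
#'   number of guilds; \code{guildUnassigned}: unassigned ASV ids.
#' @export
guildMembership <- function(x) x@membership

#' @rdname guildMembership
#' @export
nGuilds <- function(x) if (length(x@membership)) max(x@membership) else 0L

#' @rdname guildMembership
#' @export
guildUnassigned <- function(x) x@unassigned

setMethod("show", "GuildAssignment", function(object) {
  g <- nGuilds(object)
  cat("GuildAssignment:", g, "guilds over", length(object@membership),
      "ASVs;", length(object@unassigned), "unassigned\n")
  if (g) print(table(guild = object@membership))
})

#' Per-sample guild abundance (arcsine-square-root scale)
#'
#' For each sample the \emph{untransformed} member proportions are summed
#' and then arcsine-square-root transformed, so the guild value is the
#' transform of the guild's total community share.
#'
#' @param relab samples-by-ASVs matrix of untransformed proportions
#'   (full-community scale; see [toRelative] with \code{transform="none"}).
#' @param assignment a [GuildAssignment-class].
#' @return samples-by-guilds matrix, columns "Guild_1".."Guild_G", values in
#'   \eqn{[0, \pi/2]}.
#' @export
guildAbundance <- function(relab, assignment) {
  if (!is.null(attr(relab, "transform")) &&
      attr(relab, "transform") != "none")
    stop("guildAbundance needs untransformed proportions")
  mem <- guildMembership(assignment)
  if (!length(mem)) stop("empty guild assignment")
  missing <- setdiff(names(mem), colnames(relab))
  if (length(missing))
    stop("assigned ASVs absent from table: ", paste(missing, collapse = ", "))
  G <- nGuilds(assignment)
  out <- sapply(seq_len(G), function(g) {
    ids <- names(mem)[mem == g]
    if (!length(ids)) stop("empty guild ", g)
    asin(sqrt(pmin(1, rowSums(relab[, ids, drop = FALSE]))))
  })
  out <- matrix(out, nrow = nrow(relab),
                dimnames = list(rownames(relab), paste0("Guild_", seq_len(G))))
  out
}

#' Guild-level group comparisons
#'
#' For each guild, either a two-tailed Wilcoxon matched-pairs signed-ranks
#' test of pre vs post within one taster group (complete subject pairs only)
#' or a two-tailed Mann-Whitney test of NT vs ST at one timepoint.
#' Significance is flagged at p < 0.05 and a trend at p < 0.1.
#'
#' @param gtable samples-by-guilds matrix from [guildAbundance].
#' @param design design data.frame with rownames = sample ids and columns
#'   subject_id, taster_status, timepoint.
#' @param contrast "pre_vs_post" or "NT_vs_ST".
#' @param group taster group for the paired contrast ("NT" or "ST").
#' @param timepoint timepoint for the group contrast ("pre" or "post").
#' @return data.frame(guild, test, statistic, p_value, n, significant, trend).
#' @export
compareGuilds <- function(gtable, design,
                          contrast = c("pre_vs_post", "NT_vs_ST"),
                          group = "NT", timepoint = "pre") {
  contrast <- match.arg(contrast)
  design <- design[rownames(gtable), , drop = FALSE]
  res <- lapply(colnames(gtable), function(gname) {
    v <- gtable[, gname]
    if (contrast == "pre_vs_post") {
      sel <- design$taster_status == group
      d <- design[sel, , drop = FALSE]; vv <- v[sel]
      pre <- vv[d$timepoint == "pre"]
      names(pre) <- d$subject_id[d$timepoint == "pre"]
      post <- vv[d$timepoint == "post"]
      names(post) <- d$subject_id[d$timepoint == "post"]
      common <- intersect(names(pre), names(post))
      if (!length(common)) stop("no complete subject pairs for paired contrast")
      tr <- suppressMessages(
        univariateCompare(pre[common], post[common], "wilcoxon_signed_rank"))
    } else {
      sel <- design$timepoint == timepoint
      d <- design[sel, , drop = FALSE]; vv <- v[sel]
      tr <- univariateCompare(vv[d$taster_status == "NT"],
                              vv[d$taster_status == "ST"], "mann_whitney")
    }
    cbind(guild = gname, tr)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_value < 0.05
  out$trend <- out$p_value < 0.1
  out
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted-for-chance agreement between two labelings of the
#' same items; 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b label vectors of equal length (names matched if both named).
#' @return numeric scalar.
#' @export
adjustedRand <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(1)
  (sumij - expected) / (maxidx - expected)
}

#' Export a guild assignment
#'
#' Writes a TSV (asv_id, guild_id; unassigned ASVs get NA) and a JSON audit
#' of the split/accept decisions.
#'
#' @param assignment a [GuildAssignment-class].
#' @param path TSV path; the audit goes to \code{paste0(path, ".audit.json")}.
#' @export
writeGuildAssignment <- function(assignment, path) {
  mem <- guildMembership(assignment)
  df <- data.frame(asv_id = c(names(mem), guildUnassigned(assignment)),
                   guild_id = c(mem, rep(NA_integer_,
                                         length(guildUnassigned(assignment)))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(assignment@audit, paste0(path, ".audit.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
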