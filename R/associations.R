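#' @include AllClasses.R rmcorr.R
NULL

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with monotonicity enforcement (delegates to
#' \code{stats::p.adjust(method = "BH")}).
#'
#' @param p p-values in (0,1].
#' @return q-values, same length/order.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.na(p) & (p <= 0 | p > 1))) stop("p-values must lie in (0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Guild-phenotype association via linear mixed models
#'
#' For every (guild, variable) pair fits
#' \deqn{asin\sqrt{guild} \sim variable + age + gender + bmi + (1 | subject)}
#' by REML (nlme) and reports the variable's slope, its standard error and
#' p-value, and a BH q-value computed within each variable family. Age and
#' BMI are standardised and gender enters as a binary indicator before
#' fitting. Variables with zero variance are skipped with a warning;
#' non-convergent fits are flagged and excluded from the FDR family.
#'
#' @param gtable samples-by-guilds matrix ([guildAbundance] scale).
#' @param phenotypes samples-by-variables data.frame (one family, e.g. the
#'   protein table).
#' @param design design data.frame with rownames = sample ids and columns
#'   subject_id, age, gender, bmi.
#' @param family label recorded in the output (e.g. "proteins").
#' @param adjustWithin "family" (default: BH over all fits of this call) or
#'   "none".
#' @return data.frame(guild, variable, family, estimate, se, p_value,
#'   q_value, n, converged).
#' @export
lmmAssociate <- function(gtable, phenotypes, design, family = "phenotype",
                         adjustWithin = c("family", "none")) {
  adjustWithin <- match.arg(adjustWithin)
  common <- intersect(rownames(gtable), rownames(phenotypes))
  common <- intersect(common, rownames(design))
  if (length(common) < 4L) stop("too few samples shared across tables")
  gtable <- gtable[common, , drop = FALSE]
  phenotypes <- phenotypes[common, , drop = FALSE]
  design <- design[common, , drop = FALSE]
  if (min(table(design$subject_id)) < 1L || length(unique(design$subject_id)) < 2L)
    stop("need >= 2 subjects")

  ageS <- if (is.null(design$age)) rep(NA_real_, nrow(design)) else
    as.numeric(scale(design$age))
  bmiS <- if (is.null(design$bmi)) rep(NA_real_, nrow(design)) else
    as.numeric(scale(design$bmi))
  genderI <- if (is.null(design$gender)) rep(NA_real_, nrow(design)) else
    as.numeric(design$gender == "M")
  # covariates constant in this sample subset carry no information and would
  # make the fixed-effect design singular
  covs <- c("age", "gender", "bmi")
  covDat <- list(age = ageS, gender = genderI, bmi = bmiS)
  usable <- vapply(covDat, function(v) isTRUE(stats::var(v) > 0), TRUE)
  # drop covariates that are collinear with the ones before them
  if (sum(usable) > 1L) {
    X <- cbind(1, do.call(cbind, covDat[usable]))
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      keepCols <- sort(qx$pivot[seq_len(qx$rank)])
      dropped <- setdiff(seq_len(ncol(X)), keepCols) - 1L  # minus intercept
      warning("collinear covariate(s) dropped: ",
              paste(covs[usable][dropped], collapse = ", "))
      usable[which(usable)[dropped]] <- FALSE
    }
  }
  form <- stats::as.formula(paste("y ~ x",
    if (any(usable)) paste("+", paste(covs[usable], collapse = " + ")) else ""))
  rows <- list()
  for (v in colnames(phenotypes)) {
    pv <- phenotypes[[v]]
    if (stats::var(pv, na.rm = TRUE) == 0 || all(is.na(pv))) {
      warning("variable with zero variance skipped: ", v)
      next
    }
    for (g in colnames(gtable)) {
      dat <- data.frame(y = gtable[, g], x = pv, subject = design$subject_id)
      for (cv in covs[usable]) dat[[cv]] <- covDat[[cv]]
      dat <- dat[stats::complete.cases(dat), ]
      fit <- tryCatch(
        nlme::lme(form, random = ~ 1 | subject,
                  data = dat, method = "REML",
                  control = nlme::lmeControl(opt = "optim", msMaxIter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          guild = g, variable = v, family = family, estimate = NA_real_,
          se = NA_real_, p_value = NA_real_, n = nrow(dat), converged = FALSE)
        next
      }
      tt <- summary(fit)$tTable
      rows[[length(rows) + 1L]] <- data.frame(
        guild = g, variable = v, family = family,
        estimate = tt["x", "Value"], se = tt["x", "Std.Error"],
        p_value = tt["x", "p-value"], n = nrow(dat), converged = TRUE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no fittable (guild, variable) pairs")
  bad <- !out$converged
  if (any(bad)) warning(sum(bad), " non-convergent fit(s) excluded from FDR")
  out$q_value <- NA_real_
  if (adjustWithin == "family") {
    out$q_value[!bad] <- bhAdjust(out$p_value[!bad])
  } else {
    out$q_value[!bad] <- out$p_value[!bad]
  }
  rownames(out) <- NULL
  out
}

.rmCorrEdges <- function(tabA, tabB, subjects, typeA, typeB) {
  # all pairwise rm correlations between columns of tabA and tabB
  # (tabB == NULL: within-tabA pairs)
  rows <- list()
  within <- is.null(tabB)
  if (within) tabB <- tabA
  va <- colnames(tabA); vb <- colnames(tabB)
  for (i in seq_along(va)) {
    jj <- if (within) seq.int(i + 1L, length.out = max(0L, length(vb) - i)) else seq_along(vb)
    for (j in jj) {
      rc <- suppressWarnings(
        rmCorrelation(tabA[, i], tabB[, j], subjects))
      if (!isTRUE(rc$valid)) next
      rows[[length(rows) + 1L]] <- data.frame(
        node_a = va[i], type_a = typeA, node_b = vb[j], type_b = typeB,
        estimate = rc$r, p_value = rc$p_value)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Build a per-taster-group tripartite correlation network
#'
#' Nodes are guilds, salivary proteins and sensory attributes; edges carry
#' the association estimate, its BH q-value, a sign and a style. Guild-
#' protein and guild-sensory edges come from [lmmAssociate] (mixed model
#' with age/gender/BMI covariates); protein-sensory and guild-guild edges
#' from [rmCorrelation]. BH adjustment runs separately within each
#' data-type pairing (the four edge families) unless
#' \code{globalFamily = TRUE}. Edges are retained iff q is strictly below
#' \code{qThreshold}; isolated nodes are excluded unless
#' \code{keepIsolated}. Dashed style marks guild-guild edges.
#'
#' @param gtable samples-by-guilds matrix (all samples; subset happens here).
#' @param proteins,sensory samples-by-variables data.frames.
#' @param design design data.frame (rownames = sample ids).
#' @param group taster group to build for ("NT" or "ST").
#' @param qThreshold strict FDR threshold (default 0.25).
#' @param globalFamily single BH family across all edge types.
#' @param keepIsolated keep degree-0 nodes.
#' @return a [CorrelationNetwork-class].
#' @export
buildNetwork <- function(gtable, proteins, sensory, design, group,
                         qThreshold = 0.25, globalFamily = FALSE,
                         keepIsolated = FALSE) {
  sel <- rownames(design)[design$taster_status == group]
  sel <- intersect(sel, rownames(gtable))
  if (length(sel) < 4L) stop("too few samples in group ", group)
  des <- design[sel, , drop = FALSE]
  if (length(unique(des$subject_id)) < 2L)
    stop("group needs >= 2 subjects")
  gt <- gtable[sel, , drop = FALSE]
  pr <- proteins[sel, , drop = FALSE]
  sn <- sensory[sel, , drop = FALSE]

  fam <- list()
  gp <- suppressWarnings(lmmAssociate(gt, pr, des, family = "guild_protein"))
  gp <- gp[gp$converged, , drop = FALSE]
  if (nrow(gp)) fam$guild_protein <- data.frame(
    node_a = gp$guild, type_a = "guild", node_b = gp$variable,
    type_b = "protein", estimate = gp$estimate, p_value = gp$p_value)
  gs <- suppressWarnings(lmmAssociate(gt, sn, des, family = "guild_sensory"))
  gs <- gs[gs$converged, , drop = FALSE]
  if (nrow(gs)) fam$guild_sensory <- data.frame(
    node_a = gs$guild, type_a = "guild", node_b = gs$variable,
    type_b = "sensory", estimate = gs$estimate, p_value = gs$p_value)
  fam$protein_sensory <- .rmCorrEdges(pr, sn, des$subject_id, "protein", "sensory")
  fam$guild_guild <- .rmCorrEdges(gt, NULL, des$subject_id, "guild", "guild")
  fam <- fam[!vapply(fam, is.null, TRUE)]

  if (globalFamily) {
    all <- do.call(rbind, fam)
    all$q <- bhAdjust(all$p_value)
  } else {
    all <- do.call(rbind, lapply(fam, function(f) {
      f$q <- bhAdjust(f$p_value); f
    }))
  }
  keep <- !is.na(all$q) & all$q < qThreshold
  edges <- all[keep, , drop = FALSE]
  if (nrow(edges)) {
    edges$sign <- ifelse(edges$estimate >= 0, "+", "-")
    edges$style <- ifelse(edges$type_a == "guild" & edges$type_b == "guild",
                          "dashed", "solid")
  } else {
    edges <- data.frame(node_a = character(), type_a = character(),
                        node_b = character(), type_b = character(),
                        estimate = numeric(), p_value = numeric(),
                        q = numeric(), sign = character(), style = character())
    message("no edges below q threshold; empty network for ", group)
  }
  rownames(edges) <- NULL

  allNodes <- rbind(
    data.frame(id = colnames(gtable), type = "guild"),
    data.frame(id = colnames(proteins), type = "protein"),
    data.frame(id = colnames(sensory), type = "sensory"))
  if (keepIsolated) nodes <- allNodes
  else nodes <- allNodes[allNodes$id %in% c(edges$node_a, edges$node_b), ,
                         drop = FALSE]
  rownames(nodes) <- NULL
  methods::new("CorrelationNetwork", nodes = nodes, edges = edges,
               group = group, qThreshold = qThreshold)
}

#' Summarise a correlation network
#'
#' @param net a [CorrelationNetwork-class].
#' @return list: n_nodes, n_edges, nodes_by_type, n_positive, n_negative,
#'   degree (named per node).
#' @export
setMethod("networkSummary", "CorrelationNetwork", function(net) {
  e <- net@edges
  deg <- table(factor(c(e$node_a, e$node_b), levels = net@nodes$id))
  list(
    group = net@group,
    n_nodes = nrow(net@nodes),
    n_edges = nrow(e),
    nodes_by_type = as.list(table(factor(net@nodes$type,
                                         levels = c("guild", "protein", "sensory")))),
    n_positive = sum(e$sign == "+"),
    n_negative = sum(e$sign == "-"),
    degree = as.list(deg)
  )
})

setMethod("show", "CorrelationNetwork", function(object) {
  cat("CorrelationNetwork [", object@group, "]: ", nrow(object@nodes),
      " nodes, ", nrow(object@edges), " edges (q < ", object@qThreshold,
      ")\n", sep = "")
})

#' Export a network as edge-list TSV and GraphML
#'
#' @param net a [CorrelationNetwork-class].
#' @param path base path; writes \code{<path>.tsv} and \code{<path>.graphml}.
#' @export
writeNetwork <- function(net, path) {
  utils::write.table(net@edges, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(net@edges)) {
    g <- igraph::graph_from_data_frame(
      net@edges[, c("node_a", "node_b", "estimate", "q", "sign", "style")],
      directed = FALSE, vertices = net@nodes)
    igraph::write_graph(g, paste0(path, ".graphml"), format = "graphml")
  }
  invisible(path)
}
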