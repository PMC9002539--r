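# Independent brute-force oracles used across the suite. These deliberately
# take different computational routes from the package implementation.

# Per-branch UniFrac / Faith PD oracle: for every edge, enumerate descendant
# tips via phangorn::Descendants and loop pair by pair.
oracleBranchTable <- function(tree) {
  desc <- phangorn::Descendants(tree, tree$edge[, 2L], type = "tips")
  list(lengths = tree$edge.length,
       tips = lapply(desc, function(i) tree$tip.label[i]))
}

oracleUniFrac <- function(counts, tree, weighted, normalized = FALSE) {
  bt <- oracleBranchTable(tree)
  P <- counts / rowSums(counts)
  n <- nrow(counts)
  D <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  massUnder <- function(sample, tips) {
    present <- intersect(tips, colnames(counts))
    if (!length(present)) 0 else sum(P[sample, present])
  }
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    num <- 0; den <- 0
    for (b in seq_along(bt$lengths)) {
      mi <- massUnder(i, bt$tips[[b]])
      mj <- massUnder(j, bt$tips[[b]])
      if (weighted) {
        num <- num + bt$lengths[b] * abs(mi - mj)
        den <- den + bt$lengths[b] * (mi + mj)
      } else {
        pi <- mi > 0; pj <- mj > 0
        if (xor(pi, pj)) num <- num + bt$lengths[b]
        if (pi || pj) den <- den + bt$lengths[b]
      }
    }
    D[i, j] <- D[j, i] <- if (weighted) {
      if (normalized) { if (den > 0) num / den else 0 } else num
    } else { if (den > 0) num / den else 0 }
  }
  D
}

oracleFaithPD <- function(counts, tree) {
  bt <- oracleBranchTable(tree)
  vapply(seq_len(nrow(counts)), function(s) {
    present <- colnames(counts)[counts[s, ] > 0]
    sum(vapply(seq_along(bt$lengths), function(b)
      if (length(intersect(bt$tips[[b]], present))) bt$lengths[b] else 0,
      numeric(1)))
  }, numeric(1))
}

# ANCOVA route to the repeated-measures correlation: fit y ~ subject + x and
# recover r from the x sum of squares, signed by the slope.
oracleRmCorr <- function(x, y, subjects) {
  subjects <- factor(subjects)
  full <- stats::lm(y ~ subjects + x)
  red <- stats::lm(y ~ subjects)
  ssRes <- sum(stats::residuals(full)^2)
  ssX <- sum(stats::residuals(red)^2) - ssRes
  r <- sqrt(ssX / (ssX + ssRes))
  if (stats::coef(full)[["x"]] < 0) r <- -r
  r
}

# Exhaustive two-group PERMANOVA p over distinct assignments (combn route).
oraclePermanovaExact <- function(D, groups) {
  D2 <- as.matrix(D)^2
  n <- nrow(D2)
  gs <- unique(groups)
  stopifnot(length(gs) == 2L)
  n1 <- sum(groups == gs[1])
  fstat <- function(g) {
    sst <- sum(D2[upper.tri(D2)]) / n
    ssw <- 0
    for (gg in gs) {
      idx <- which(g == gg)
      sub <- D2[idx, idx]
      ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
    }
    ((sst - ssw) / 1) / (ssw / (n - 2))
  }
  fobs <- fstat(groups)
  sets <- utils::combn(n, n1)
  fs <- apply(sets, 2L, function(ix) {
    g <- rep(gs[2], n); g[ix] <- gs[1]
    fstat(g)
  })
  mean(fs >= fobs - 1e-12)
}

# small random count matrix helper
randomCounts <- function(nSamples, nAsvs, lambda = 20, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(nSamples * nAsvs, lambda), nSamples, nAsvs,
              dimnames = list(paste0("s", seq_len(nSamples)),
                              paste0("ASV_", seq_len(nAsvs))))
  storage.mode(m) <- "integer"
  m
}
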