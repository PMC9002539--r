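#' @include AllClasses.R
NULL

.asSquare <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix not symmetric")
  if (any(diag(m) != 0)) stop("distance matrix diagonal must be zero")
  m
}

.gower <- function(D) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * J %*% (D^2) %*% J
}

.ordinate <- function(G, ids, method) {
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  vals <- e$values
  tol <- max(abs(vals)) * 1e-10
  pos <- which(vals > tol)
  if (length(pos)) {
    coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(vals[pos]), length(pos))
    rownames(coords) <- ids
    colnames(coords) <- paste0("PC", seq_along(pos))
    pe <- vals[pos] / sum(vals[pos])
  } else {
    coords <- matrix(0, length(ids), 0, dimnames = list(ids, NULL))
    pe <- numeric()
  }
  methods::new("OrdinationResult",
    coordinates = coords,
    eigenvalues = vals,
    proportionExplained = pe,
    negativeEigenvalueMass = sum(abs(vals[vals < -tol])),
    method = method)
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Gower-centers \eqn{-\frac{1}{2} J D^2 J} and eigendecomposes. Coordinates
#' are eigenvectors scaled by the square root of their (positive)
#' eigenvalues; negative eigenvalues are reported but yield no axis.
#'
#' @param d a \code{dist} or symmetric zero-diagonal matrix.
#' @return an [OrdinationResult-class].
#' @export
pcoaOrdination <- function(d) {
  D <- .asSquare(d)
  .ordinate(.gower(D), rownames(D), "pcoa")
}

#' Covariate-adjusted principal coordinates analysis
#'
#' Projects the Gower matrix onto the orthogonal complement of the covariate
#' space before eigendecomposition: with \eqn{X} the covariate design matrix
#' (intercept added), \eqn{H = I - X(X^\top X)^{-1}X^\top} and the
#' decomposition is of \eqn{H G H}. Covariate effects (for example stable
#' inter-subject differences in a paired design) are thereby removed from the
#' ordination.
#'
#' @param d a \code{dist} or symmetric zero-diagonal matrix.
#' @param covariates data.frame of per-sample covariates, rows aligned with
#'   the samples of \code{d} (factors allowed, expanded via model.matrix).
#' @return an [OrdinationResult-class].
#' @export
apcoaOrdination <- function(d, covariates) {
  D <- .asSquare(d)
  n <- nrow(D)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) stop("covariate rows must align with samples")
  # constant columns carry no information beyond the intercept
  constant <- vapply(covariates, function(v) length(unique(v)) < 2L, TRUE)
  covariates <- covariates[, !constant, drop = FALSE]
  X <- if (ncol(covariates)) stats::model.matrix(~ ., data = covariates)
       else stats::model.matrix(~ 1, data = data.frame(row.names = seq_len(n)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("collinear covariate columns: ", paste(dropped, collapse = ", "))
  }
  H <- diag(n) - X %*% solve(crossprod(X), t(X))
  .ordinate(H %*% .gower(D) %*% H, rownames(D), "apcoa")
}

#' Accessors for OrdinationResult
#' @param x an [OrdinationResult-class].
#' @return coordinates matrix / eigenvalues / proportion explained.
#' @export
ordCoordinates <- function(x) x@coordinates

#' @rdname ordCoordinates
#' @export
ordEigenvalues <- function(x) x@eigenvalues

#' @rdname ordCoordinates
#' @export
propExplained <- function(x) x@proportionExplained

setMethod("show", "OrdinationResult", function(object) {
  cat(toupper(object@method), "ordination:", nrow(object@coordinates),
      "samples,", ncol(object@coordinates), "positive axes\n")
  if (length(object@proportionExplained))
    cat("  first axes explain:",
        paste0(round(100 * utils::head(object@proportionExplained, 3L), 2), "%",
               collapse = ", "), "\n")
  if (object@negativeEigenvalueMass > 0)
    cat("  negative-eigenvalue mass:",
        signif(object@negativeEigenvalueMass, 4), "\n")
})

# Sums of squares from a squared-distance matrix under a grouping.
.permanovaSS <- function(D2, groups) {
  n <- nrow(D2)
  sst <- sum(D2[upper.tri(D2)]) / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ng <- length(idx)
    if (ng > 1L) {
      sub <- D2[idx, idx]
      ssw <- ssw + sum(sub[upper.tri(sub)]) / ng
    }
  }
  c(sst = sst, ssw = ssw)
}

.pseudoF <- function(D2, groups, a, n) {
  ss <- .permanovaSS(D2, groups)
  ssb <- ss[["sst"]] - ss[["ssw"]]
  (ssb / (a - 1)) / (ss[["ssw"]] / (n - a))
}

.allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .allPermutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[r + seq_len(nrow(sub)), 1L] <- k
    out[r + seq_len(nrow(sub)), -1L] <- matrix(rest[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

#' PERMANOVA with free or subject-stratified permutations
#'
#' Distance-based multivariate analysis of variance. The pseudo-F statistic
#' follows the standard decomposition: \eqn{SS_{total} = \sum_{i<j} d_{ij}^2/n},
#' \eqn{SS_{within}} from within-group pairs, and
#' \eqn{F = (SS_B/(a-1)) / (SS_W/(n-a))}. The p-value uses the add-one
#' convention \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})} and
#' can therefore never be exactly zero.
#'
#' Permutation schemes:
#' \describe{
#'   \item{free}{labels permuted across all samples. For a between-subject
#'     contrast restricted to one sample per subject this makes subjects the
#'     exchangeable unit.}
#'   \item{stratified_by_subject}{labels permuted independently within each
#'     stratum (subject) -- the exchangeability structure of a paired
#'     pre/post design. Strata with a single sample are held fixed.}
#' }
#'
#' @param d a \code{dist} or square distance matrix.
#' @param groups group labels, one per sample.
#' @param scheme "free" or "stratified_by_subject".
#' @param strata subject ids, required for the stratified scheme.
#' @param nPermutations Monte-Carlo permutations (default 9999).
#' @param seed integer seed.
#' @param exhaustive if TRUE (free scheme, small n), enumerate all label
#'   permutations instead of sampling; p is then the exact permutation
#'   p-value \eqn{\#\{F \ge F_{obs}\}/n!} (identity included).
#' @return list with pseudo_F, p_value, R2, n_permutations, scheme.
#' @export
permanova <- function(d, groups, scheme = c("free", "stratified_by_subject"),
                      strata = NULL, nPermutations = 9999L, seed = 1L,
                      exhaustive = FALSE) {
  scheme <- match.arg(scheme)
  D <- .asSquare(d)
  n <- nrow(D)
  groups <- as.character(groups)
  if (length(groups) != n) stop("one group label per sample required")
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need >= 2 groups with >= 2 samples each")
  a <- length(tab)
  D2 <- D^2
  ss <- .permanovaSS(D2, groups)
  ssb <- ss[["sst"]] - ss[["ssw"]]
  Fobs <- (ssb / (a - 1)) / (ss[["ssw"]] / (n - a))
  R2 <- ssb / ss[["sst"]]

  if (exhaustive) {
    if (scheme != "free") stop("exhaustive enumeration implemented for the free scheme")
    if (n > 8L) stop("exhaustive enumeration limited to n <= 8")
    perms <- .allPermutations(n)
    Fs <- apply(perms, 1L, function(ix) .pseudoF(D2, groups[ix], a, n))
    p <- mean(Fs >= Fobs - 1e-12)
    return(list(pseudo_F = Fobs, p_value = p, R2 = R2,
                n_permutations = nrow(perms), scheme = scheme,
                exhaustive = TRUE))
  }

  if (scheme == "stratified_by_subject") {
    if (is.null(strata)) stop("stratified scheme needs strata (subject ids)")
    strata <- as.character(strata)
    if (length(strata) != n) stop("one stratum per sample required")
    strataIdx <- split(seq_len(n), strata)
    single <- vapply(strataIdx, length, 1L) == 1L
    if (any(single))
      message(sum(single), " stratum/strata with a single sample held fixed")
  }

  set.seed(as.integer(seed))
  hits <- 0L
  for (b in seq_len(nPermutations)) {
    gp <- groups
    if (scheme == "free") {
      gp <- groups[sample.int(n)]
    } else {
      for (idx in strataIdx) {
        if (length(idx) > 1L) gp[idx] <- gp[idx][sample.int(length(idx))]
      }
    }
    if (.pseudoF(D2, gp, a, n) >= Fobs - 1e-12) hits <- hits + 1L
  }
  list(pseudo_F = Fobs, p_value = (1 + hits) / (1 + nPermutations), R2 = R2,
       n_permutations = nPermutations, scheme = scheme, exhaustive = FALSE)
}

# Exact tie-aware two-sided Wilcoxon signed-rank p by sign-flip enumeration
# (average ranks; symmetric null => p = min(1, 2*min(lower, upper) tail)).
.exactSignedRank <- function(dd) {
  r <- rank(abs(dd))
  v <- sum(r[dd > 0])
  n <- length(dd)
  flips <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  V <- as.vector(flips %*% r)
  pUp <- mean(V >= v - 1e-12)
  pDn <- mean(V <= v + 1e-12)
  min(1, 2 * min(pUp, pDn))
}

#' Paired and two-sample nonparametric comparisons
#'
#' \describe{
#'   \item{wilcoxon_signed_rank}{two-tailed matched-pairs test on
#'     \code{x - y}. Zero differences are dropped (Wilcoxon's original rule)
#'     with a message; if all differences are zero, p = 1 with a warning.
#'     For n <= 12 non-zero pairs an exact tie-aware sign-flip enumeration is
#'     used; larger n falls back to the normal approximation.}
#'   \item{mann_whitney}{two-tailed rank-sum test on two independent samples.}
#'   \item{friedman}{Friedman rank test; \code{x} is a subjects-by-conditions
#'     matrix.}
#' }
#'
#' @param x first sample / subjects-by-conditions matrix for friedman.
#' @param y second (paired or independent) sample; ignored for friedman.
#' @param test one of the above.
#' @return data.frame(test, statistic, p_value, n).
#' @export
univariateCompare <- function(x, y = NULL,
                              test = c("wilcoxon_signed_rank", "mann_whitney",
                                       "friedman")) {
  test <- match.arg(test)
  if (test == "friedman") {
    m <- as.matrix(x)
    ft <- stats::friedman.test(m)
    return(data.frame(test = test, statistic = unname(ft$statistic),
                      p_value = ft$p.value, n = nrow(m)))
  }
  if (is.null(y)) stop(test, " needs two samples")
  if (test == "mann_whitney") {
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    p <- wt$p.value
    if (is.nan(p)) p <- 1  # fully tied groups: no evidence either way
    return(data.frame(test = test, statistic = unname(wt$statistic),
                      p_value = p, n = length(x) + length(y)))
  }
  ok <- stats::complete.cases(x, y)
  dd <- (x - y)[ok]
  nz <- dd != 0
  if (sum(!nz) > 0) message(sum(!nz), " zero difference(s) dropped")
  if (!any(nz)) {
    warning("all differences zero; p = 1")
    return(data.frame(test = test, statistic = 0, p_value = 1, n = length(dd)))
  }
  dd <- dd[nz]
  v <- sum(rank(abs(dd))[dd > 0])
  p <- if (length(dd) <= 12L) .exactSignedRank(dd)
       else suppressWarnings(stats::wilcox.test(dd, alternative = "two.sided"))$p.value
  data.frame(test = test, statistic = v, p_value = min(1, p), n = length(dd))
}
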