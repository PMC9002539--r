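euclid <- function(X) {
  m <- as.matrix(stats::dist(X))
  dimnames(m) <- list(rownames(X), rownames(X))
  m
}

test_that("PCoA embeds Euclidean distances isometrically", {
  # collinear 1-D points: one positive eigenvalue, PC1 reproduces the input
  X <- matrix(c(0, 1, 3), dimnames = list(c("a", "b", "c"), NULL))
  ord <- pcoaOrdination(euclid(X))
  pos <- ordEigenvalues(ord)[ordEigenvalues(ord) > 1e-9]
  expect_length(pos, 1L)
  expect_equal(propExplained(ord)[1], 1)
  rec <- as.matrix(stats::dist(ordCoordinates(ord)[, 1]))
  expect_equal(unname(rec), unname(euclid(X)), tolerance = 1e-9)

  # random 3-D cloud: full isometry on the positive subspace
  set.seed(4)
  Y <- matrix(rnorm(15), 5, 3, dimnames = list(paste0("s", 1:5), NULL))
  ord2 <- pcoaOrdination(euclid(Y))
  rec2 <- as.matrix(stats::dist(ordCoordinates(ord2)))
  expect_equal(unname(rec2), unname(euclid(Y)), tolerance = 1e-9)

  # degenerate all-zero distances
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  ordz <- pcoaOrdination(z)
  expect_true(all(abs(ordEigenvalues(ordz)) < 1e-12))
  expect_equal(ncol(ordCoordinates(ordz)), 0L)

  expect_error(pcoaOrdination(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PCoA eigenvalues match the ape reference implementation", {
  set.seed(8)
  Y <- matrix(rnorm(24), 8, 3, dimnames = list(paste0("s", 1:8), NULL))
  d <- euclid(Y)
  mine <- pcoaOrdination(d)
  ref <- ape::pcoa(as.dist(d))
  k <- sum(!is.na(ref$values$Eigenvalues))
  expect_equal(ordEigenvalues(mine)[1:k], ref$values$Eigenvalues[1:k],
               tolerance = 1e-9)
})

test_that("adjusted PCoA removes covariate structure", {
  # intercept-only adjustment is plain PCoA up to axis sign
  set.seed(10)
  Y <- matrix(rnorm(18), 6, 3, dimnames = list(paste0("s", 1:6), NULL))
  d <- euclid(Y)
  plain <- pcoaOrdination(d)
  adj <- apcoaOrdination(d, data.frame(one = rep(1, 6)))
  expect_equal(abs(ordCoordinates(adj)), abs(ordCoordinates(plain)),
               tolerance = 1e-9)

  # subject-offset + treatment-shift geometry: adjusting for subject exposes
  # the treatment axis; unadjusted PC1 is dominated by subjects
  set.seed(11)
  subj <- rep(1:6, each = 2)
  treat <- rep(c(0, 1), 6)
  X <- cbind(10 * rnorm(6)[subj] + 3 * treat, rnorm(12, sd = 0.1))
  rownames(X) <- paste0("s", 1:12)
  d2 <- euclid(X)
  un <- pcoaOrdination(d2)
  ad <- apcoaOrdination(d2, data.frame(subject = factor(subj)))
  sepScore <- function(v) {
    pooled <- sqrt((var(v[treat == 1]) + var(v[treat == 0])) / 2)
    abs(mean(v[treat == 1]) - mean(v[treat == 0])) / pooled
  }
  expect_gt(sepScore(ordCoordinates(ad)[, 1]), 2)
  expect_lt(sepScore(ordCoordinates(un)[, 1]), 1)

  # adjusting for the grouping itself wipes out the separation
  ad2 <- apcoaOrdination(d2, data.frame(treat = factor(treat)))
  co <- ordCoordinates(ad2)
  for (k in seq_len(ncol(co)))
    expect_lt(abs(mean(co[treat == 1, k]) - mean(co[treat == 0, k])), 1e-6)

  # collinear covariates named in the error
  expect_error(
    apcoaOrdination(d2, data.frame(a = treat, b = 2 * treat)), "collinear")
})

test_that("PERMANOVA pseudo-F matches vegan and p matches exact enumeration", {
  skip_if_not_installed("vegan")
  set.seed(21)
  Y <- matrix(rnorm(12 * 3), 12, 3, dimnames = list(paste0("s", 1:12), NULL))
  g <- rep(c("x", "y"), each = 6)
  d <- euclid(Y)
  res <- permanova(d, g, nPermutations = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(res$R2, ref$R2[1], tolerance = 1e-10)

  # 6 samples: full enumeration equals the combn oracle exactly
  set.seed(22)
  Z <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), NULL))
  g6 <- rep(c("x", "y"), each = 3)
  d6 <- euclid(Z)
  exact <- permanova(d6, g6, exhaustive = TRUE)
  expect_equal(exact$p_value, oraclePermanovaExact(d6, g6), tolerance = 1e-12)
})

test_that("PERMANOVA is deterministic, label-invariant and add-one bounded", {
  set.seed(30)
  Y <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), NULL))
  d <- euclid(Y)
  g <- rep(c("a", "b"), 5)
  r1 <- permanova(d, g, nPermutations = 199, seed = 7)
  r2 <- permanova(d, g, nPermutations = 199, seed = 7)
  expect_identical(r1, r2)
  # renaming groups changes nothing
  g2 <- ifelse(g == "a", "Q", "W")
  r3 <- permanova(d, g2, nPermutations = 199, seed = 7)
  expect_equal(r1$p_value, r3$p_value)
  expect_gte(r1$p_value, 1 / 200)
})

test_that("stratified permutation detects a paired shift that free permutation misses", {
  set.seed(33)
  nsub <- 8
  subj <- rep(seq_len(nsub), each = 2)
  time <- rep(c("pre", "post"), nsub)
  off <- rnorm(nsub, sd = 6)
  X <- cbind(off[subj] + 1.2 * (time == "post") + rnorm(2 * nsub, sd = 0.4),
             rnorm(2 * nsub, sd = 0.4))
  rownames(X) <- paste0("s", seq_len(2 * nsub))
  d <- euclid(X)
  strat <- permanova(d, time, scheme = "stratified_by_subject",
                     strata = subj, nPermutations = 499, seed = 2)
  free <- permanova(d, time, scheme = "free", nPermutations = 499, seed = 2)
  expect_lt(strat$p_value, 0.05)
  expect_gt(free$p_value, strat$p_value)
})

test_that("single-sample strata are held fixed with a message", {
  set.seed(40)
  X <- matrix(rnorm(14), 7, 2, dimnames = list(paste0("s", 1:7), NULL))
  d <- euclid(X)
  g <- c("pre", "post", "pre", "post", "pre", "post", "pre")
  subj <- c(1, 1, 2, 2, 3, 3, 4)  # subject 4 has one sample
  expect_message(
    res <- permanova(d, g, scheme = "stratified_by_subject", strata = subj,
                     nPermutations = 99, seed = 1),
    "held fixed")
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("univariate comparisons reproduce exact reference values", {
  # friedman, k=2, n=5, unanimous ordering: Q = 5
  m <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 3, 4, 5, 6))
  fr <- univariateCompare(m, test = "friedman")
  expect_equal(fr$statistic, 5)
  expect_equal(fr$p_value, stats::friedman.test(m)$p.value)

  # identical groups: rank-sum test finds nothing
  mw <- univariateCompare(c(1, 2, 3), c(1, 2, 3), "mann_whitney")
  expect_equal(mw$p_value, 1)

  # constant positive shift, n = 6: smallest attainable exact two-sided p
  ws <- univariateCompare(2:7, 1:6, "wilcoxon_signed_rank")
  expect_equal(ws$p_value, 2 / 64)

  # agreement with wilcox.test exact p when differences are untied
  set.seed(50)
  x <- rnorm(9); y <- rnorm(9)
  mine <- univariateCompare(x, y, "wilcoxon_signed_rank")
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)

  # all-zero differences: p = 1 with a warning
  expect_warning(
    z <- suppressMessages(univariateCompare(1:4, 1:4, "wilcoxon_signed_rank")),
    "zero")
  expect_equal(z$p_value, 1)
})
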