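treeABC <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

test_that("alpha diversity closed forms hold", {
  cnt <- matrix(c(4L, 4L, 4L, 4L,
                  5L, 0L, 2L, 0L), 2, 4, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("A", "B", "C", "D")))
  res <- alphaDiversity(cnt, metrics = c("observed_asvs", "shannon",
                                         "pielou_evenness"))
  g <- function(m, s) res$value[res$metric == m & res$sample_id == s]
  expect_equal(g("shannon", "s1"), 2)          # 4 equal ASVs = 2 bits
  expect_equal(g("pielou_evenness", "s1"), 1)
  expect_equal(g("observed_asvs", "s1"), 4)
  expect_equal(g("observed_asvs", "s2"), 2)
  # shannon invariant to count rescaling
  res10 <- alphaDiversity(cnt * 10L, metrics = "shannon")
  expect_equal(res10$value, res$value[res$metric == "shannon"])
  # richness-1 sample: evenness defined as 0
  one <- matrix(c(7L, 0L, 3L, 2L), 2, 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("A", "B")))
  expect_equal(alphaDiversity(one, metrics = "pielou_evenness")$value[1], 0)
})

test_that("Faith PD equals the minimal rooted spanning subtree length", {
  tr <- treeABC()
  cnt <- matrix(c(1L, 1L, 0L,
                  1L, 1L, 1L,
                  0L, 0L, 5L), 3, 3, byrow = TRUE,
                dimnames = list(c("ab", "abc", "c"), c("A", "B", "C")))
  res <- alphaDiversity(cnt, metrics = "faith_pd", tree = tr)
  expect_equal(res$value[res$sample_id == "ab"], 3)   # A+B+shared stem
  expect_equal(res$value[res$sample_id == "abc"], 5)  # whole tree
  expect_equal(res$value[res$sample_id == "c"], 2)    # path C to root
  # matches picante (include.root) on random trees/communities
  skip_if_not_installed("picante")
  for (seed in 1:5) {
    tr2 <- generateTree(10, seed = seed)
    m <- randomCounts(4, 10, lambda = 1, seed = seed)
    colnames(m) <- tr2$tip.label
    m[rowSums(m) == 0, 1] <- 1L
    mine <- alphaDiversity(m, metrics = "faith_pd", tree = tr2)$value
    ref <- picante::pd(m, tr2, include.root = TRUE)$PD
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("Faith PD is monotone under adding taxa and maxes at total length", {
  tr <- generateTree(12, seed = 3)
  cnt <- matrix(0L, 2, 12, dimnames = list(c("s1", "s2"), tr$tip.label))
  cnt[2, ] <- 1L
  prev <- 0
  for (k in 1:12) {
    cnt[1, ] <- c(rep(1L, k), rep(0L, 12 - k))
    v <- alphaDiversity(cnt, metrics = "faith_pd", tree = tr)$value[1]
    expect_gte(v, prev)
    prev <- v
  }
  expect_equal(prev, sum(tr$edge.length))
})

test_that("UniFrac matches hand-computed branch arithmetic", {
  tr <- treeABC()
  cnt <- matrix(c(1L, 1L, 0L,
                  1L, 0L, 1L), 2, 3, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  du <- as.matrix(uniFrac(cnt, tr, weighted = FALSE))
  expect_equal(du["s1", "s2"], 3 / 5)  # unique B(1)+C(2) over union 5

  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  cnt2 <- matrix(c(10L, 0L, 0L, 7L), 2, 2,
                 dimnames = list(c("s1", "s2"), c("A", "B")))
  dw <- as.matrix(uniFrac(cnt2, tr2, weighted = TRUE))
  expect_equal(dw["s1", "s2"], 2)      # raw weighted, fully disjoint
  dwn <- as.matrix(uniFrac(cnt2, tr2, weighted = TRUE, normalized = TRUE))
  expect_equal(dwn["s1", "s2"], 1)

  # identical samples at distance zero under both variants
  same <- rbind(s1 = c(3L, 2L, 1L), s2 = c(3L, 2L, 1L))
  colnames(same) <- c("A", "B", "C")
  expect_equal(as.matrix(uniFrac(same, tr, weighted = FALSE))["s1", "s2"], 0)
  expect_equal(as.matrix(uniFrac(same, tr, weighted = TRUE))["s1", "s2"], 0)
})

test_that("UniFrac agrees with the per-branch brute-force oracle", {
  skip_if_not_installed("phangorn")
  for (seed in 1:10) {
    tr <- generateTree(8, seed = seed)
    cnt <- randomCounts(5, 8, lambda = 2, seed = seed + 100)
    colnames(cnt) <- tr$tip.label
    cnt[rowSums(cnt) == 0, 1] <- 1L
    for (w in c(TRUE, FALSE)) {
      mine <- as.matrix(uniFrac(cnt, tr, weighted = w))
      ref <- oracleUniFrac(cnt, tr, weighted = w)
      expect_equal(mine, ref, tolerance = 1e-10)
    }
    # distance-matrix axioms; unweighted bounded in [0,1]
    m <- as.matrix(uniFrac(cnt, tr, weighted = FALSE))
    expect_equal(m, t(m), tolerance = 1e-12)
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("unweighted UniFrac matches picante on random data", {
  skip_if_not_installed("picante")
  tr <- generateTree(15, seed = 9)
  cnt <- randomCounts(6, 15, lambda = 1, seed = 9)
  colnames(cnt) <- tr$tip.label
  cnt[rowSums(cnt) == 0, 1] <- 1L
  mine <- as.matrix(uniFrac(cnt, tr, weighted = FALSE))
  ref <- as.matrix(picante::unifrac(cnt, tr))
  ref <- ref[rownames(mine), colnames(mine)]
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("rarefaction conserves depth, drops shallow samples, obeys the seed", {
  cnt <- randomCounts(4, 10, lambda = 50, seed = 5)
  r1 <- rarefy(cnt, 300, seed = 11)
  expect_true(all(rowSums(r1) == 300))
  expect_identical(r1, rarefy(cnt, 300, seed = 11))
  expect_false(identical(r1, rarefy(cnt, 300, seed = 12)))
  # a sample exactly at depth passes through untouched
  exact <- cnt
  exact[1, ] <- 0L; exact[1, 1:3] <- c(100L, 100L, 100L)
  expect_identical(rarefy(exact, 300, seed = 1)[1, ],
                   exact[1, ])
  # shallow samples dropped with a warning
  shallow <- cnt; shallow[2, ] <- 0L; shallow[2, 1] <- 5L
  expect_warning(r2 <- rarefy(shallow, 300, seed = 1), "dropped")
  expect_false("s2" %in% rownames(r2))
  expect_error(rarefy(cnt, 1e7), "below")
})

test_that("rarefied counts match the hypergeometric expectation", {
  cnt <- rbind(s1 = c(A = 600L, B = 300L, C = 100L),
               s2 = c(A = 500L, B = 400L, C = 100L))
  depth <- 200
  draws <- vapply(1:1000, function(s) rarefy(cnt, depth, seed = s)[1, "A"],
                  numeric(1))
  exp_mean <- depth * 600 / 1000
  exp_sd <- sqrt(depth * 0.6 * 0.4 * (1000 - depth) / (1000 - 1))
  expect_lt(abs(mean(draws) - exp_mean), 4 * exp_sd / sqrt(1000))
  # variance also consistent with sampling without replacement
  expect_lt(abs(sd(draws) - exp_sd) / exp_sd, 0.15)
})
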