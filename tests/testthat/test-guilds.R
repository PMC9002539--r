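# compact co-abundance block generator: b blocks of size sz over paired
# samples; returns list(abund = arcsine-sqrt matrix, subjects, truth)
blockData <- function(b, sz, nSubj = 14, loading = 1, noise = 0.3, seed = 1) {
  set.seed(seed)
  subj <- rep(seq_len(nSubj), each = 2)
  n <- length(subj)
  nv <- b * sz
  f <- matrix(rnorm(n * b), n, b)
  logm <- sapply(seq_len(nv), function(i) {
    g <- ((i - 1) %/% sz) + 1
    loading * f[, g] + rnorm(n, sd = noise)
  })
  m <- exp(logm)
  p <- m / (rowSums(m) + 5)  # background mass keeps proportions < 1
  colnames(p) <- paste0("ASV_", seq_len(nv))
  list(abund = asin(sqrt(p)), subjects = subj,
       truth = setNames(rep(seq_len(b), each = sz), colnames(p)))
}

test_that("prevalence filter applies the strict more-than-half rule", {
  cnt <- matrix(0L, 5, 3, dimnames = list(paste0("s", 1:5), c("A", "B", "C")))
  cnt[1:3, "A"] <- 1L        # 60% -> retained
  cnt[1:2, "B"] <- 1L        # 40% -> dropped
  cnt[, "C"] <- 1L
  res <- prevalenceFilter(cnt, 0.5)
  expect_setequal(colnames(res$table), c("A", "C"))
  expect_equal(unname(res$prevalence["B"]), 0.4)

  # exactly half is dropped under the strict inequality
  cnt4 <- matrix(0L, 4, 2, dimnames = list(paste0("s", 1:4), c("A", "B")))
  cnt4[1:2, "A"] <- 1L; cnt4[, "B"] <- 1L
  expect_identical(colnames(prevalenceFilter(cnt4, 0.5)$table), "B")
  # nothing exceeds half -> error
  sparse <- matrix(0L, 4, 2, dimnames = list(paste0("s", 1:4), c("A", "B")))
  sparse[1:2, "A"] <- 1L; sparse[3:4, "B"] <- 1L
  expect_error(prevalenceFilter(sparse, 0.5), "no ASV")
})

test_that("relative abundance transform hits its closed-form anchors", {
  cnt <- matrix(c(1L, 3L, 0L, 4L), 2, 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("A", "B")))
  p <- toRelative(cnt, "none")
  expect_equal(rowSums(p), c(s1 = 1, s2 = 1), tolerance = 1e-9)
  t1 <- toRelative(cnt, "arcsine_sqrt")
  expect_equal(t1["s2", "A"], 0)           # p = 0 -> 0
  expect_equal(t1["s2", "B"], pi / 2)      # p = 1 -> pi/2
  expect_equal(t1["s1", "A"], pi / 6)      # p = 0.25 -> asin(1/2)
  # strictly increasing on a grid
  g <- asin(sqrt(seq(0, 1, by = 0.01)))
  expect_true(all(diff(g) > 0))
  # proportions stay on the whole-community scale under subsetting
  sub <- toRelative(cnt, "none", subset = "A")
  expect_equal(sub["s1", "A"], 0.25)
})

test_that("planted co-abundance blocks are recovered exactly", {
  bd <- blockData(2, 10, loading = 2, noise = 0.2, seed = 5)
  asg <- guildCluster(bd$abund, bd$subjects)
  expect_equal(nGuilds(asg), 2L)
  expect_equal(adjustedRand(guildMembership(asg), bd$truth), 1)
})

test_that("uncorrelated variables yield no multi-member guilds", {
  # df must be large enough that the maximum null pairwise r stays below
  # the threshold: with 200 subjects df = 199, null sd ~ 0.07
  set.seed(70)
  subj <- rep(1:200, each = 2)
  m <- matrix(rnorm(400 * 10), 400, 10,
              dimnames = list(NULL, paste0("ASV_", 1:10)))
  asg <- guildCluster(asin(sqrt(plogis(m) / 10)), subj, rThreshold = 0.2)
  expect_equal(nGuilds(asg), 0L)
  expect_length(guildUnassigned(asg), 10L)
})

test_that("guild assignment is stable under ASV input-order permutation", {
  bd <- blockData(3, 5, loading = 1.5, seed = 8)
  asg1 <- guildCluster(bd$abund, bd$subjects)
  perm <- sample(ncol(bd$abund))
  asg2 <- guildCluster(bd$abund[, perm], bd$subjects)
  m1 <- guildMembership(asg1)
  m2 <- guildMembership(asg2)[names(m1)]
  expect_equal(adjustedRand(m1, m2), 1)
})

test_that("constant ASVs go unassigned with a warning", {
  bd <- blockData(2, 4, loading = 1.5, seed = 9)
  ab <- cbind(bd$abund, ASV_flat = rep(0.1, nrow(bd$abund)))
  expect_warning(asg <- guildCluster(ab, bd$subjects), "undefined")
  expect_true("ASV_flat" %in% guildUnassigned(asg))
})

test_that("guild abundance sums member shares then transforms", {
  relab <- matrix(c(0.1, 0.15, 0.75,
                    0.5, 0.5, 0.0), 2, 3, byrow = TRUE,
                  dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  attr(relab, "transform") <- "none"
  asg <- methods::new("GuildAssignment",
                      membership = c(A = 1L, B = 1L, C = 2L),
                      unassigned = character(), audit = list(),
                      parameters = list())
  g <- guildAbundance(relab, asg)
  expect_equal(g["s1", "Guild_1"], asin(sqrt(0.25)))  # 0.1 + 0.15
  expect_equal(g["s1", "Guild_1"], pi / 6)
  expect_equal(g["s2", "Guild_2"], 0)
  # all ASVs in one guild -> pi/2 everywhere
  all1 <- methods::new("GuildAssignment",
                       membership = c(A = 1L, B = 1L, C = 1L),
                       unassigned = character(), audit = list(),
                       parameters = list())
  expect_equal(unname(guildAbundance(relab, all1)[, 1]), rep(pi / 2, 2))
  # conservation: untransformed guild shares sum to <= 1
  shares <- sin(g)^2
  expect_true(all(rowSums(shares) <= 1 + 1e-9))
  # transformed input is rejected
  tr <- relab; attr(tr, "transform") <- "arcsine_sqrt"
  expect_error(guildAbundance(tr, asg), "untransformed")
})

test_that("guild group comparisons flag planted differences and pass nulls", {
  sim <- simulateStudy(syntheticScenario(seed = 3))
  cnt <- asvCounts(sim$experiment)
  des <- sampleData(sim$experiment)
  pf <- prevalenceFilter(cnt)
  relab <- toRelative(cnt, "none")
  trans <- toRelative(cnt, "arcsine_sqrt", subset = colnames(pf$table))
  asg <- suppressWarnings(guildCluster(trans, des$subject_id))
  gt <- guildAbundance(relab, asg)
  res <- compareGuilds(gt, des, "NT_vs_ST", timepoint = "pre")
  expect_equal(nrow(res), nGuilds(asg))          # one row per guild
  expect_true(all(res$p_value > 0 & res$p_value <= 1))

  # identical pre and post tables -> all paired p = 1
  gtNull <- gt
  pre <- rownames(des)[des$timepoint == "pre"]
  post <- rownames(des)[des$timepoint == "post"]
  subjPost <- des[post, "subject_id"]
  matched <- pre[match(subjPost, des[pre, "subject_id"])]
  gtNull[post, ] <- gtNull[matched, ]
  resNull <- suppressWarnings(compareGuilds(gtNull, des, "pre_vs_post",
                                            group = "NT"))
  expect_true(all(resNull$p_value == 1))
})

test_that("the planted ST-elevated guild shows a baseline group difference", {
  hits <- vapply(1:12, function(sd) {
    sim <- generateCounts(syntheticScenario(seed = sd))
    relab <- toRelative(sim$counts, "none")
    ids <- names(sim$truth$guild)[sim$truth$guild == sim$truth$baseline_guild]
    share <- asin(sqrt(rowSums(relab[, ids])))
    des <- sim$design
    pre <- des$timepoint == "pre"
    p <- univariateCompare(share[pre & des$taster_status == "NT"],
                           share[pre & des$taster_status == "ST"],
                           "mann_whitney")$p_value
    # direction: higher in ST
    dir <- mean(share[pre & des$taster_status == "ST"]) >
      mean(share[pre & des$taster_status == "NT"])
    p < 0.05 && dir
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("adjustedRand matches mclust and the truth ledger suffices", {
  skip_if_not_installed("mclust")
  set.seed(77)
  for (i in 1:5) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjustedRand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjustedRand(c(x = 1, y = 1, z = 2), c(x = 5, y = 5, z = 9)), 1)
})
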