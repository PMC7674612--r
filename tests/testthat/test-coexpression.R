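# Network stage: adjacency, TOM (with brute-force oracle), soft-threshold
# selection, module detection and meta-genes.

test_that("soft-thresholded adjacency follows |r|^beta", {
  x <- rbind(1:10, 2 * (1:10) + 3)  # perfectly correlated pair
  rownames(x) <- c("g1", "g2"); colnames(x) <- sprintf("s%d", 1:10)
  expect_equal(softThresholdAdjacency(x, beta = 1)["g1", "g2"], 1)
  # correlation -0.5 at beta 2 -> 0.25
  expect_equal(abs(-0.5)^2, 0.25)
  set.seed(3)
  y <- matrix(rnorm(200), 20, 10)
  rownames(y) <- sprintf("g%d", 1:20); colnames(y) <- sprintf("s%d", 1:10)
  a2 <- softThresholdAdjacency(y, beta = 2)
  r <- cor(t(y))
  expect_equal(a2[2, 5], abs(r[2, 5])^2)
  # raising beta never increases off-diagonal entries
  a1 <- softThresholdAdjacency(y, beta = 1)
  a6 <- softThresholdAdjacency(y, beta = 6)
  off <- upper.tri(a1)
  expect_true(all(a6[off] <= a1[off] + 1e-15))
  # zero-variance gene handled with warning
  y[1, ] <- 5
  expect_warning(az <- softThresholdAdjacency(y, beta = 2), "zero-variance")
  expect_true(all(az[1, -1] == 0))
})

test_that("TOM matches closed forms and the brute-force oracle", {
  # 2-gene network: t12 = a12
  a <- matrix(c(1, 0.7, 0.7, 1), 2, 2)
  expect_equal(topologicalOverlap(a)[1, 2], 0.7)
  # 3 genes all 0.5: t = (0.25 + 0.5) / (1 + 1 - 0.5) = 0.5
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 1
  expect_equal(topologicalOverlap(a3)[1, 2], 0.5)
  # identity adjacency: zero overlap off-diagonal
  expect_true(all(topologicalOverlap(diag(4))[upper.tri(diag(4))] == 0))
  # oracle equivalence on random instances
  set.seed(7)
  for (rep in 1:5) {
    a <- randomAdjacency(15)
    expect_lt(max(abs(topologicalOverlap(a) - bruteForceTOM(a))), 1e-12)
  }
  # bounds
  set.seed(8)
  tt <- topologicalOverlap(randomAdjacency(25))
  expect_true(all(tt >= 0 & tt <= 1))
})

test_that("soft-threshold selection is deterministic and degrades gracefully", {
  co <- smallCohort(seed = 1L)
  b1 <- pickSoftThreshold(co)
  b2 <- pickSoftThreshold(co)
  expect_identical(as.numeric(b1), as.numeric(b2))
  expect_s3_class(attr(b1, "fits"), "data.frame")
  # pure-noise matrix: no error, some power returned
  set.seed(4)
  noise <- matrix(rnorm(100 * 30), 100, 30,
                  dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:30)))
  expect_no_error(pickSoftThreshold(noise))
  # too few distinct connectivities: fallback to 6 with warning
  tiny <- matrix(rnorm(5 * 30), 5, 30,
                 dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:30)))
  expect_warning(bf <- pickSoftThreshold(tiny), "beta = 6")
  expect_identical(as.numeric(bf), 6)
})

test_that("scale-free-like signal fits better than Gaussian noise at beta 1", {
  set.seed(9)
  n <- 300; ns <- 60
  # hub structure: loadings decay as a power law, so connectivity does too
  loadings <- (seq_len(n))^(-0.7)
  f <- rnorm(ns)
  signal <- outer(loadings, f) + matrix(rnorm(n * ns, 0, 0.6), n, ns)
  dimnames(signal) <- list(sprintf("g%d", 1:n), sprintf("s%d", 1:ns))
  noise <- matrix(rnorm(n * ns), n, ns, dimnames = dimnames(signal))
  rsqAt1 <- function(x) attr(pickSoftThreshold(x, candidatePowers = 1), "fits")$rsq[1]
  expect_gte(rsqAt1(signal), rsqAt1(noise))
})

test_that("two planted blocks are recovered exactly", {
  x <- twoBlockMatrix(nPerBlock = 50, withinCor = 0.9, seed = 10L)
  tom <- topologicalOverlap(softThresholdAdjacency(x, beta = 6))
  part <- detectModules(tom, minModuleSize = 30)
  expect_identical(length(unique(part[part > 0])), 2L)
  truth <- rep(1:2, each = 50)
  expect_equal(mclust::adjustedRandIndex(part, truth), 1.0)
})

test_that("pure noise stays predominantly unassigned", {
  greyFrac <- vapply(1:10, function(seed) {
    set.seed(seed + 100)
    x <- matrix(rnorm(200 * 50), 200, 50,
                dimnames = list(sprintf("g%d", 1:200), sprintf("s%d", 1:50)))
    tom <- topologicalOverlap(softThresholdAdjacency(x, beta = 6))
    part <- detectModules(tom, minModuleSize = 30)
    mean(part == 0)
  }, numeric(1))
  expect_gte(mean(greyFrac), 0.8)
})

test_that("module labels are invariant to gene order", {
  x <- twoBlockMatrix(nPerBlock = 40, nSamples = 50, withinCor = 0.85, seed = 12L)
  tom <- topologicalOverlap(softThresholdAdjacency(x, beta = 6))
  part <- detectModules(tom, minModuleSize = 25)
  set.seed(13)
  perm <- sample(nrow(x))
  tomP <- topologicalOverlap(softThresholdAdjacency(x[perm, ], beta = 6))
  partP <- detectModules(tomP, minModuleSize = 25)
  expect_identical(partP[names(part)], part)
})

test_that("meta-genes summarize modules as their first principal component", {
  # noiseless one-factor module: variance explained 1, sign-fixed correlation +1
  set.seed(14)
  act <- rnorm(30)
  x <- outer(runif(10, 0.5, 1), act)
  dimnames(x) <- list(sprintf("g%d", 1:10), sprintf("s%d", 1:30))
  part <- setNames(rep(1L, 10), rownames(x))
  mg <- moduleMetagene(x, part)
  expect_equal(unname(varianceExplained(mg)), 1)
  expect_equal(unname(cor(metageneScores(mg)[1, ], act)), 1)
  expect_equal(unname(sd(metageneScores(mg)[1, ])), 1, tolerance = 1e-12)
  # duplicating every gene leaves the meta-gene unchanged
  x2 <- rbind(x, x)
  rownames(x2) <- sprintf("g%d", 1:20)
  mg2 <- moduleMetagene(x2, setNames(rep(1L, 20), rownames(x2)))
  expect_lt(max(abs(metageneScores(mg2)[1, ] - metageneScores(mg)[1, ])), 1e-8)
  # single-gene module warns and returns the standardized profile
  p2 <- setNames(c(1L, rep(0L, 9)), rownames(x))
  expect_warning(mg3 <- moduleMetagene(x, p2), "single gene")
  expect_equal(unname(abs(cor(metageneScores(mg3)[1, ], x[1, ]))), 1)
})

test_that("planted modules beat random gene sets on variance explained", {
  sim <- simulateCohort(smallConfig(seed = 15L))
  co <- suppressWarnings(preprocessCohort(sim$studies, sim$metadata))
  mod <- sim$truth@geneModule[rownames(exprsMat(co))]
  mg <- moduleMetagene(co, mod)
  # size-matched random gene sets
  set.seed(16)
  fake <- mod
  fake[] <- 0L
  fake[sample(which(mod == 0), 40)] <- 1L
  fake[sample(which(fake == 0 & mod == 0), 35)] <- 2L
  mgF <- moduleMetagene(co, fake)
  expect_gt(median(varianceExplained(mg)), median(varianceExplained(mgF)))
  # first-PC dominance: second PC share is smaller for every planted module
  for (m in 1:3) {
    genes <- names(mod)[mod == m]
    sub <- t(scale(t(exprsMat(co)[genes, ])))
    d2 <- svd(t(sub))$d^2
    expect_gt(d2[1] / sum(d2), d2[2] / sum(d2))
  }
})

test_that("meta-gene grade comparison is calibrated and powered", {
  set.seed(17)
  # calibration: no grade effect -> uniform p over label permutations
  nMod <- 3; n <- 30
  scores <- matrix(rnorm(nMod * n), nMod, n,
                   dimnames = list(sprintf("ME%d", 1:nMod), sprintf("s%d", 1:n)))
  mg <- new("MetaGeneMatrix", scores = scores,
            varianceExplained = setNames(rep(0.5, nMod), rownames(scores)),
            moduleSizes = setNames(rep(10L, nMod), rownames(scores)))
  hits <- 0; total <- 0
  for (i in 1:334) {
    grades <- sample(rep(c(1, 3), each = n / 2))
    cmpI <- compareMetagenesByGrade(mg, grades)
    hits <- hits + sum(cmpI$p_value <= 0.05)
    total <- total + nMod
  }
  se <- sqrt(0.05 * 0.95 / total)
  expect_lt(abs(hits / total - 0.05), 3 * se)
  # power: planted difference 2 with noise 0.5 is flagged
  grades <- rep(c(1, 3), each = n / 2)
  scores2 <- scores
  scores2[1, grades == 3] <- scores2[1, grades == 3] * 0.5 + 2
  mg2 <- new("MetaGeneMatrix", scores = scores2,
             varianceExplained = mg@varianceExplained,
             moduleSizes = mg@moduleSizes)
  cmp <- compareMetagenesByGrade(mg2, grades)
  expect_true(cmp$significant[1])
  # swapping the pair negates the effect, p unchanged
  rev <- compareMetagenesByGrade(mg2, grades, pair = c(3, 1))
  expect_equal(rev$median_diff, -cmp$median_diff)
  expect_equal(rev$p_value, cmp$p_value)
})
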