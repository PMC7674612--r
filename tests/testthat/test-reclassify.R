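# Fuzzy C-means, the balanced sigmoidal cost, polarity, feature selection and
# grade 2 reclassification.

sepFeatures <- function(n = 40, gap = 10, noise = 0.1, seed = 1) {
  set.seed(seed)
  x <- matrix(c(rnorm(n / 2, -gap / 2, noise), rnorm(n / 2, gap / 2, noise)),
              ncol = 1, dimnames = list(sprintf("s%02d", 1:n), "f1"))
  x
}

test_that("well-separated clouds get near-hard memberships", {
  x <- sepFeatures(n = 40, gap = 10, noise = 0.1)
  res <- fcmCluster(x, seed = 2)
  u <- membershipMatrix(res)
  own <- pmax(u[, 1], u[, 2])
  expect_true(all(own > 0.99))
  expect_true(res@converged)
  expect_equal(unname(rowSums(u)), rep(1, 40), tolerance = 1e-9)
})

test_that("a sample midway between symmetric clusters has membership 0.5", {
  x <- matrix(c(rep(-1, 10), rep(1, 10), 0), ncol = 1,
              dimnames = list(sprintf("s%d", 1:21), "f1"))
  res <- fcmCluster(x, seed = 3)
  expect_equal(unname(membershipMatrix(res)[21, ]), c(0.5, 0.5),
               tolerance = 1e-6)
})

test_that("the FCM objective is non-increasing across iterations", {
  set.seed(4)
  x <- matrix(rnorm(60 * 3), 60, 3,
              dimnames = list(sprintf("s%d", 1:60), c("a", "b", "c")))
  res <- fcmCluster(x, seed = 5, nRestarts = 3)
  expect_true(all(diff(res@objectiveTrace) <= 1e-10))
})

test_that("FCM matches an independent reference of the update equations", {
  set.seed(6)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    x <- matrix(rnorm(n, sd = 2), ncol = 1,
                dimnames = list(sprintf("s%d", 1:n), "f1"))
    u0 <- matrix(runif(n * 2), n, 2)
    u0 <- u0 / rowSums(u0)
    mine <- fcmCluster(x, initMembership = u0, tol = 1e-10, maxIter = 500)
    ref <- referenceFCM(x, u0, tol = 1e-10, maxIter = 500)
    expect_lt(max(abs(membershipMatrix(mine) - ref)), 1e-6)
  }
})

test_that("FCM agrees with e1071::cmeans on separated data", {
  skip_if_not_installed("e1071")
  x <- sepFeatures(n = 30, gap = 8, noise = 0.3, seed = 7)
  mine <- fcmCluster(x, seed = 8)
  set.seed(9)
  ref <- e1071::cmeans(x, centers = 2, m = 2, iter.max = 500)
  # align clusters by centroid order
  oM <- order(mine@centroids[, 1]); oR <- order(ref$centers[, 1])
  expect_lt(max(abs(membershipMatrix(mine)[, oM] - ref$membership[, oR])), 1e-3)
})

test_that("FCM is deterministic given the seed", {
  set.seed(10)
  x <- matrix(rnorm(50 * 2), 50, 2,
              dimnames = list(sprintf("s%d", 1:50), c("a", "b")))
  a <- fcmCluster(x, seed = 11)
  b <- fcmCluster(x, seed = 11)
  expect_identical(membershipMatrix(a), membershipMatrix(b))
  expect_identical(a@objective, b@objective)
})

test_that("polarity is read off the membership-distribution ends", {
  # grade 3 concentrated in cluster 2's end
  u2 <- c(rep(0.05, 10), rep(0.95, 8))
  u <- cbind(1 - u2, u2)
  rownames(u) <- sprintf("s%d", 1:18)
  res <- new("MembershipResult", membership = u,
             centroids = matrix(c(0, 1), 2, 1), fuzzifier = 2, objective = 0,
             objectiveTrace = 0, iterations = 1L, converged = TRUE,
             polarity = "unset", pGrade3 = setNames(rep(NA_real_, 18), rownames(u)))
  grades <- c(rep(1, 10), rep(3, 8))
  pol <- clusterPolarity(res, grades)
  expect_identical(clusterPolarityOf(pol), "cluster2_is_grade3")
  expect_equal(unname(pGrade3(pol)), u2)
  # flipping memberships flips polarity but P_k is invariant
  resF <- res
  resF@membership <- u[, 2:1]
  polF <- clusterPolarity(resF, grades)
  expect_identical(clusterPolarityOf(polF), "cluster1_is_grade3")
  expect_equal(pGrade3(polF), pGrade3(pol))
})

test_that("polarity recovery matches planted truth across seeded runs", {
  sim <- simulateCohort(smallConfig(seed = 20L))
  co <- suppressWarnings(preprocessCohort(sim$studies, sim$metadata))
  grades <- sampleGrade(co)
  mod <- sim$truth@geneModule[rownames(exprsMat(co))]
  mg <- moduleMetagene(co, mod)
  cmp <- compareMetagenesByGrade(mg, grades)
  feats <- featureSetFrom(co, mg, cmp$module[cmp$significant])
  # planted direction: grade-3 samples have higher ME1 (effect -1 -> +1)
  ok <- vapply(1:50, function(s) {
    res <- clusterPolarity(fcmCluster(feats, seed = s, nRestarts = 3), grades)
    p <- pGrade3(res)
    median(p[grades == 3]) > median(p[grades == 1])
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("the balanced cost matches direct substitution", {
  sig <- function(z) 1 / (1 + exp(-z))
  # all memberships 0.5 -> C = 1 for every alpha
  p <- rep(0.5, 10); grades <- rep(c(1, 3), 5)
  for (a in c(1, 5, 10, 100))
    expect_identical(separationCost(p, grades, a), 1)
  # perfect separation, N1 = N3 = 2, alpha = 1 -> 2 / (1 + exp(0.5))
  p2 <- c(0, 0, 1, 1); g2 <- c(1, 1, 3, 3)
  expect_equal(separationCost(p2, g2, 1), 2 / (1 + exp(0.5)))
  expect_equal(separationCost(p2, g2, 1), 0.7550813, tolerance = 1e-6)
  # alpha = 100: essentially zero
  expect_lt(separationCost(p2, g2, 100), 1e-20)
  # worst case: completely inverted memberships
  p3 <- c(1, 1, 0, 0)
  expect_equal(separationCost(p3, g2, 1), 2 * sig(0.5), tolerance = 1e-7)
  expect_equal(separationCost(p3, g2, 1), 1.2449187, tolerance = 1e-6)
  expect_gte(separationCost(p3, g2, 100), 2 - 1e-15)
  # grade 2 samples never contribute
  p4 <- c(p2, 0.123, 0.987); g4 <- c(g2, 2, 2)
  expect_identical(separationCost(p4, g4, 5), separationCost(p2, g2, 5))
  expect_error(separationCost(c(0.1, 0.2), c(1, 1), 1), "must both be present")
})

test_that("cost is monotone decreasing in alpha when grades are separated", {
  set.seed(21)
  p <- c(runif(10, 0, 0.45), runif(10, 0.55, 1))
  grades <- rep(c(1, 3), each = 10)
  costs <- vapply(c(1, 5, 10, 100), function(a) separationCost(p, grades, a),
                  numeric(1))
  expect_true(all(diff(costs) < 0))
})

selectionPool <- function(seed = 22, nNoise = 5, n = 60) {
  set.seed(seed)
  grades <- rep(c(1, 2, 3), each = n / 3)
  signal <- ifelse(grades == 1, -1.5, ifelse(grades == 3, 1.5, 0)) + rnorm(n, 0, 0.4)
  m <- cbind(signal, matrix(rnorm(n * nNoise), n, nNoise))
  colnames(m) <- c("signal", sprintf("noise%d", seq_len(nNoise)))
  rownames(m) <- sprintf("s%02d", seq_len(n))
  m <- scale(m); attr(m, "scaled:center") <- NULL; attr(m, "scaled:scale") <- NULL
  list(pool = new("FeatureSet", data = m, featureIds = colnames(m),
                  featureType = rep("gene", ncol(m))),
       grades = grades)
}

test_that("forward selection finds the separating feature first", {
  hits <- vapply(1:20, function(s) {
    sp <- selectionPool(seed = 300 + s)
    fw <- forwardSelect(sp$pool, sp$grades, alpha = 10, nRestarts = 3, seed = s)
    fw$features[1] == "signal"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("duplicate features add nothing and greedy steps only improve", {
  sp <- selectionPool(seed = 23, nNoise = 0)
  m <- cbind(sp$pool@data, sp$pool@data, sp$pool@data)
  colnames(m) <- c("signal", "dup1", "dup2")
  pool <- new("FeatureSet", data = m, featureIds = colnames(m),
              featureType = rep("gene", 3))
  fw <- forwardSelect(pool, sp$grades, alpha = 10, nRestarts = 3, seed = 1)
  expect_identical(fw$features, "signal")
  # accepted-step monotonicity: final C <= first-step C
  sp2 <- selectionPool(seed = 24)
  fw2 <- forwardSelect(sp2$pool, sp2$grades, alpha = 10, nRestarts = 3, seed = 2)
  expect_lte(fw2$cost, fw2$trace$cost[1] + 1e-12)
})

test_that("backward elimination drops the noise feature", {
  hits <- vapply(1:20, function(s) {
    sp <- selectionPool(seed = 400 + s, nNoise = 1)
    bw <- backwardEliminate(sp$pool, sp$grades, alpha = 10, nRestarts = 3,
                            seed = s)
    identical(bw$features, "signal")
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # single-feature pool returned unchanged
  sp <- selectionPool(seed = 25, nNoise = 0)
  bw <- backwardEliminate(sp$pool, sp$grades, alpha = 10, nRestarts = 3, seed = 1)
  expect_identical(bw$features, "signal")
  # final cost never worse than the full pool
  sp2 <- selectionPool(seed = 26, nNoise = 3)
  bw2 <- backwardEliminate(sp2$pool, sp2$grades, alpha = 10, nRestarts = 3,
                           seed = 2)
  expect_lte(bw2$cost, bw2$trace$cost[1] + 1e-12)
})

test_that("signature selection is reproducible and spans the alpha grid", {
  sp <- selectionPool(seed = 27, nNoise = 2)
  a <- selectSignature(sp$pool, sp$grades, nRestarts = 3, seed = 5)
  b <- selectSignature(sp$pool, sp$grades, nRestarts = 3, seed = 5)
  expect_identical(a$costCurve, b$costCurve)
  expect_identical(a$features, b$features)
  expect_setequal(unique(a$costCurve$alpha), c(1, 5, 10, 100))
  expect_identical(a$alpha, 10)
})

test_that("reclassification applies the membership thresholds literally", {
  u2 <- c(0.95, 0.10, 0.50, 0.80, 0.20)
  u <- cbind(1 - u2, u2)
  rownames(u) <- sprintf("s%d", 1:5)
  res <- new("MembershipResult", membership = u,
             centroids = matrix(c(0, 1), 2, 1), fuzzifier = 2, objective = 0,
             objectiveTrace = 0, iterations = 1L, converged = TRUE,
             polarity = "cluster2_is_grade3",
             pGrade3 = setNames(u2, rownames(u)))
  grades <- rep(2, 5)
  rep1 <- reclassifyGrade2(res, grades)
  expect_identical(unname(reclassLabels(rep1)),
                   c("grade3_like", "grade1_like", "intermediate",
                     "grade3_like", "grade1_like"))
  expect_identical(unname(rep1@counts),
                   c(2L, 1L, 2L))
  # degenerate threshold 0.5: only an exact tie stays intermediate
  rep2 <- reclassifyGrade2(res, grades, threshold = 0.5)
  expect_identical(unname(reclassLabels(rep2)),
                   c("grade3_like", "grade1_like", "intermediate",
                     "grade3_like", "grade1_like"))
  # grade 1/3 samples are untouched
  rep3 <- reclassifyGrade2(res, c(1, 3, 2, 2, 2))
  expect_identical(length(reclassLabels(rep3)), 3L)
  expect_warning(reclassifyGrade2(res, rep(1, 5)), "no grade 2")
})

test_that("grade 2 samples never influence the selected signature", {
  sp <- selectionPool(seed = 28, nNoise = 2)
  fw <- forwardSelect(sp$pool, sp$grades, alpha = 10, nRestarts = 5, seed = 3)
  # permute the grade 2 rows among themselves: same point multiset
  idx2 <- which(sp$grades == 2)
  set.seed(29)
  permuted <- sp$pool@data
  permuted[idx2, ] <- permuted[sample(idx2), ]
  poolP <- new("FeatureSet", data = permuted, featureIds = sp$pool@featureIds,
               featureType = sp$pool@featureType)
  fwP <- forwardSelect(poolP, sp$grades, alpha = 10, nRestarts = 5, seed = 3)
  expect_identical(fwP$features, fw$features)
  expect_equal(fwP$cost, fw$cost, tolerance = 1e-6)
})

test_that("a saved signature can be applied to a cohort without grade 3", {
  sim <- simulateCohort(smallConfig(
    seed = 30L, samplesPerGrade = c(grade1 = 30L, grade2 = 20L, grade3 = 0L)))
  co <- suppressWarnings(preprocessCohort(sim$studies, sim$metadata))
  grades <- sampleGrade(co)
  mod <- sim$truth@geneModule[rownames(exprsMat(co))]
  mg <- moduleMetagene(co, mod)
  feats <- featureSetFrom(co, mg, c("ME1", "ME2"))
  out <- suppressWarnings(
    applySignature(feats, grades, c("ME1", "ME2"), seed = 31))
  expect_s4_class(out$report, "ReclassificationReport")
  expect_identical(length(reclassLabels(out$report)), sum(grades == 2))
  expect_true(is.na(out$report@cost))
  # calls still track planted truth
  lbl <- reclassLabels(out$report)
  truthCls <- sim$truth@sampleClass[names(lbl)]
  agree <- c(sum(lbl == "grade1_like" & truthCls == "G2_1like"),
             sum(lbl == "grade3_like" & truthCls == "G2_3like"))
  wrong <- c(sum(lbl == "grade3_like" & truthCls == "G2_1like"),
             sum(lbl == "grade1_like" & truthCls == "G2_3like"))
  expect_gt(sum(agree), sum(wrong))
})

test_that("end-to-end grade 2 recovery stays near the planted mixture", {
  fracs <- vapply(1:5, function(seed) {
    sim <- simulateCohort(synthConfig(seed = seed))
    co <- suppressWarnings(preprocessCohort(sim$studies, sim$metadata))
    grades <- sampleGrade(co)
    tom <- topologicalOverlap(softThresholdAdjacency(co, beta = 6))
    part <- detectModules(tom)
    mg <- moduleMetagene(co, part)
    cmp <- compareMetagenesByGrade(mg, grades)
    feats <- featureSetFrom(co, mg, cmp$module[cmp$significant])
    res <- clusterPolarity(fcmCluster(feats, seed = seed + 500), grades)
    rep <- reclassifyGrade2(res, grades)
    mean(reclassLabels(rep) != "intermediate")
  }, numeric(1))
  planted <- (13 + 21) / 46
  expect_lt(abs(mean(fracs) - planted), 0.15)
})
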