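# Fuzzy C-means soft clustering, the prevalence-balanced sigmoidal separation
# cost, cluster polarity, greedy feature selection, and grade 2
# reclassification. All samples (including grade 2) enter the FCM fit; only
# grades 1 and 3 enter the cost.

asFeatureMatrix <- function(features) {
  if (is(features, "FeatureSet")) return(features@data)
  m <- as.matrix(features)
  if (is.null(colnames(m))) colnames(m) <- sprintf("F%d", seq_len(ncol(m)))
  m
}

#' Assemble the candidate feature pool
#'
#' Candidate features are those significantly different between grades 1 and
#' 3: module meta-genes flagged by \code{\link{compareMetagenesByGrade}} and
#' single genes flagged by \code{\link{deTest}}. Single genes are capped at
#' the \code{maxGenes} smallest p-values to keep the pool comparable to the
#' handful of genes a sparse differential-expression screen yields. Every
#' feature column is standardized to mean 0, sd 1 across samples.
#'
#' @param cohort a \linkS4class{MergedCohort}.
#' @param deResult data.frame from \code{\link{deTest}} (or NULL to omit
#'   single genes).
#' @param metagenes a \linkS4class{MetaGeneMatrix} (or NULL to omit modules).
#' @param gradeComparison data.frame from
#'   \code{\link{compareMetagenesByGrade}} (required with \code{metagenes}).
#' @param maxGenes cap on single-gene candidates (default 25).
#' @param featureType \code{"both"}, \code{"metagene"} or \code{"gene"}.
#' @return a \linkS4class{FeatureSet} (samples x features).
#' @export
candidateFeatures <- function(cohort, deResult = NULL, metagenes = NULL,
                              gradeComparison = NULL, maxGenes = 25,
                              featureType = c("both", "metagene", "gene")) {
  featureType <- match.arg(featureType)
  cols <- list(); ids <- character(); types <- character()
  if (featureType != "gene" && !is.null(metagenes)) {
    stopifnot(!is.null(gradeComparison))
    keep <- gradeComparison$module[gradeComparison$significant]
    if (length(keep)) {
      sc <- metageneScores(metagenes)[keep, , drop = FALSE]
      cols <- c(cols, list(t(sc)))
      ids <- c(ids, keep)
      types <- c(types, rep("metagene", length(keep)))
    }
  }
  if (featureType != "metagene" && !is.null(deResult)) {
    sig <- deResult[deResult$direction != "ns", , drop = FALSE]
    sig <- sig[order(sig$p_value, sig$gene_id), , drop = FALSE]
    sig <- head(sig, maxGenes)
    if (nrow(sig)) {
      x <- exprsMat(cohort)[sig$gene_id, , drop = FALSE]
      cols <- c(cols, list(t(x)))
      ids <- c(ids, sig$gene_id)
      types <- c(types, rep("gene", nrow(sig)))
    }
  }
  if (!length(ids))
    stop("candidateFeatures: no significant candidate features", call. = FALSE)
  m <- do.call(cbind, cols)
  colnames(m) <- ids
  m <- scale(m)
  attr(m, "scaled:center") <- NULL; attr(m, "scaled:scale") <- NULL
  new("FeatureSet", data = m, featureIds = ids, featureType = types)
}

#' Build a feature set from explicit feature ids
#'
#' Assembles a standardized samples x features matrix from named module
#' meta-genes and/or gene ids without any significance filtering — the way a
#' pre-trained signature is materialized on a new cohort.
#'
#' @param cohort a \linkS4class{MergedCohort}.
#' @param metagenes a \linkS4class{MetaGeneMatrix} for the cohort (or NULL).
#' @param featureIds ids to include: meta-gene row names and/or gene ids.
#' @return a \linkS4class{FeatureSet}.
#' @export
featureSetFrom <- function(cohort, metagenes, featureIds) {
  mgIds <- if (!is.null(metagenes))
    intersect(featureIds, rownames(metageneScores(metagenes)))
  else character(0)
  gnIds <- setdiff(featureIds, mgIds)
  missing <- setdiff(gnIds, rownames(exprsMat(cohort)))
  if (length(missing))
    stop("featureSetFrom: unknown feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  cols <- list()
  if (length(mgIds))
    cols <- c(cols, list(t(metageneScores(metagenes)[mgIds, , drop = FALSE])))
  if (length(gnIds))
    cols <- c(cols, list(t(exprsMat(cohort)[gnIds, , drop = FALSE])))
  m <- do.call(cbind, cols)[, featureIds, drop = FALSE]
  m <- scale(m)
  attr(m, "scaled:center") <- NULL; attr(m, "scaled:scale") <- NULL
  new("FeatureSet", data = m,
      featureIds = featureIds,
      featureType = ifelse(featureIds %in% mgIds, "metagene", "gene"))
}

# One FCM run from a given initial membership matrix.
fcmRun <- function(x, u, m, tol, maxIter) {
  n <- nrow(x); k <- ncol(u)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  centroids <- matrix(0, k, ncol(x))
  for (iter in seq_len(maxIter)) {
    um <- u^m
    centroids <- (t(um) %*% x) / colSums(um)
    d2 <- vapply(seq_len(k), function(j)
      rowSums((x - matrix(centroids[j, ], n, ncol(x), byrow = TRUE))^2),
      numeric(n))
    zero <- d2 < 1e-24
    w <- d2^(-1 / (m - 1))  # d2^(-1/(m-1)) == d^(-2/(m-1))
    uNew <- w / rowSums(w)
    if (any(zero)) {
      rows <- which(rowSums(zero) > 0)
      for (r in rows) {
        uNew[r, ] <- 0
        uNew[r, which(zero[r, ])[1]] <- 1
      }
    }
    trace <- c(trace, sum(uNew^m * d2))
    delta <- max(abs(uNew - u))
    u <- uNew
    if (delta < tol) { converged <- TRUE; break }
  }
  list(u = u, centroids = centroids, objective = trace[length(trace)],
       trace = trace, iterations = iter, converged = converged)
}

#' Fuzzy C-means clustering with seeded restarts
#'
#' Standard FCM alternating minimization on Euclidean distances: centroid
#' update \code{c_j = sum_k u_jk^m x_k / sum_k u_jk^m} and membership update
#' \code{u_jk = 1 / sum_l (d_jk / d_lk)^(2/(m-1))}, iterated until the largest
#' membership change falls below \code{tol} or \code{maxIter} is reached. The
#' best of \code{nRestarts} random membership initializations (by the FCM
#' objective \code{sum u^m d^2}) is returned; a sample coinciding with a
#' centroid is hard-assigned to it. Deterministic given \code{seed}.
#'
#' @param features a \linkS4class{FeatureSet} or samples x features matrix.
#' @param nClusters number of clusters (default 2).
#' @param fuzzifier FCM fuzzifier m > 1 (default 2).
#' @param tol convergence tolerance on memberships (default 1e-6).
#' @param maxIter maximum iterations per restart (default 300).
#' @param nRestarts random restarts (default 10).
#' @param seed integer seed for the restart initializations.
#' @param initMembership optional explicit initial membership matrix
#'   (samples x clusters, rows summing to 1); overrides the restart scheme.
#' @return a \linkS4class{MembershipResult} with polarity \code{"unset"}.
#' @export
fcmCluster <- function(features, nClusters = 2L, fuzzifier = 2, tol = 1e-6,
                       maxIter = 300L, nRestarts = 10L, seed = 1L,
                       initMembership = NULL) {
  x <- asFeatureMatrix(features)
  stopifnot(nrow(x) >= nClusters, fuzzifier > 1)
  runs <- if (!is.null(initMembership)) {
    u0 <- as.matrix(initMembership)
    stopifnot(nrow(u0) == nrow(x), ncol(u0) == nClusters)
    list(fcmRun(x, u0 / rowSums(u0), fuzzifier, tol, maxIter))
  } else {
    withLocalSeed(seed, {
      lapply(seq_len(nRestarts), function(r) {
        u0 <- matrix(runif(nrow(x) * nClusters), nrow(x), nClusters)
        fcmRun(x, u0 / rowSums(u0), fuzzifier, tol, maxIter)
      })
    })
  }
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "objective"))]]
  if (!best$converged)
    warning("fcmCluster: not converged within ", maxIter, " iterations")
  u <- best$u
  rownames(u) <- rownames(x)
  new("MembershipResult", membership = u, centroids = best$centroids,
      fuzzifier = fuzzifier, objective = best$objective,
      objectiveTrace = best$trace, iterations = as.integer(best$iterations),
      converged = best$converged, polarity = "unset",
      pGrade3 = setNames(rep(NA_real_, nrow(u)), rownames(x)))
}

#' Determine which cluster is grade-3 enriched
#'
#' Looks at both ends of the membership distribution: among samples with
#' membership >= \code{hardThreshold} to a cluster, the ratio of grade 3 to
#' grade 1 counts is computed with a +0.5 continuity guard on both counts; the
#' cluster with the larger ratio is declared grade-3-enriched and \code{P_k}
#' refers to it from then on. If neither end contains any grade 1 or grade 3
#' sample (or the ratios tie), polarity falls back to comparing median
#' memberships of grade 3 versus grade 1 samples; without grade 3 samples the
#' cluster with the lower grade 1 median membership is taken (warning).
#'
#' @param result a \linkS4class{MembershipResult} with two clusters.
#' @param grades per-sample WHO grades aligned to the membership rows.
#' @param hardThreshold end-of-distribution cutoff (default 0.80).
#' @return the result with \code{polarity} and \code{pGrade3} filled in.
#' @export
clusterPolarity <- function(result, grades, hardThreshold = 0.80) {
  stopifnot(is(result, "MembershipResult"), ncol(result@membership) == 2)
  u <- result@membership
  stopifnot(length(grades) == nrow(u))
  counts <- function(j) {
    end <- u[, j] >= hardThreshold
    c(g1 = sum(end & grades == 1), g3 = sum(end & grades == 3))
  }
  c1 <- counts(1); c2 <- counts(2)
  useFallback <- (sum(c1) == 0 && sum(c2) == 0)
  if (!useFallback) {
    r1 <- (c1[["g3"]] + 0.5) / (c1[["g1"]] + 0.5)
    r2 <- (c2[["g3"]] + 0.5) / (c2[["g1"]] + 0.5)
    if (r1 == r2) useFallback <- TRUE
    else g3cluster <- if (r2 > r1) 2L else 1L
  }
  if (useFallback) {
    warning("clusterPolarity: distribution ends uninformative; ",
            "falling back to median memberships")
    if (any(grades == 3)) {
      med <- c(median(u[grades == 3, 1]), median(u[grades == 3, 2]))
      g3cluster <- which.max(med)
    } else if (any(grades == 1)) {
      med <- c(median(u[grades == 1, 1]), median(u[grades == 1, 2]))
      g3cluster <- which.min(med)
    } else stop("clusterPolarity: no grade 1 or grade 3 samples", call. = FALSE)
  }
  result@polarity <- if (g3cluster == 1L) "cluster1_is_grade3"
                     else "cluster2_is_grade3"
  result@pGrade3 <- setNames(u[, g3cluster], rownames(u))
  result
}

#' Balanced sigmoidal separation cost
#'
#' \deqn{C = \frac{1}{N_1}\sum_{i \in S_1}\frac{1}{1+e^{-\alpha(P_i-0.5)}} +
#'          \frac{1}{N_3}\sum_{j \in S_3}\frac{1}{1+e^{-\alpha(0.5-P_j)}}}
#' where \eqn{P} is the grade-3-cluster membership, \eqn{S_1}/\eqn{S_3} the
#' grade 1 / grade 3 index sets and \eqn{\alpha} the sigmoid steepness. Each
#' grade contributes its mean, so prevalence imbalance does not tilt the cost.
#' Grade 2 samples never enter the sum. \code{C} lies in (0, 2); lower is
#' better, and \code{C = 1} exactly when every membership is 0.5.
#'
#' @param p per-sample grade-3-cluster memberships.
#' @param grades per-sample WHO grades aligned to \code{p}.
#' @param alpha sigmoid steepness (> 0).
#' @return the scalar cost.
#' @export
separationCost <- function(p, grades, alpha) {
  stopifnot(length(p) == length(grades), alpha > 0)
  s1 <- p[grades == 1]; s3 <- p[grades == 3]
  if (!length(s1) || !length(s3))
    stop("separationCost: grades 1 and 3 must both be present", call. = FALSE)
  sig <- function(z) 1 / (1 + exp(-z))
  mean(sig(alpha * (s1 - 0.5))) + mean(sig(alpha * (0.5 - s3)))
}

# Fit FCM on a feature subset and return the separation cost.
evalSubsetCost <- function(pool, ids, grades, alpha, fuzzifier, tol, maxIter,
                           nRestarts, seed) {
  x <- pool@data[, ids, drop = FALSE]
  res <- fcmCluster(x, nClusters = 2L, fuzzifier = fuzzifier, tol = tol,
                    maxIter = maxIter, nRestarts = nRestarts, seed = seed)
  res <- suppressWarnings(clusterPolarity(res, grades))
  separationCost(pGrade3(res), grades, alpha)
}

#' Greedy forward feature selection under the separation cost
#'
#' Starts from the empty set and repeatedly adds the candidate whose inclusion
#' minimizes the cost (the FCM fit is re-run for every candidate under a fixed
#' seed), stopping when the best improvement drops below \code{minImprove} or
#' the pool is exhausted. Ties break by pool order.
#'
#' @param pool a \linkS4class{FeatureSet}.
#' @param grades per-sample WHO grades aligned to the pool rows.
#' @param alpha sigmoid steepness for the cost.
#' @param fuzzifier,tol,maxIter,nRestarts,seed FCM settings (see
#'   \code{\link{fcmCluster}}).
#' @param minImprove minimal cost improvement to accept a step (default 1e-6).
#' @param maxFeatures optional cap on the selected set size.
#' @return list: \code{features} (selected ids), \code{cost}, and
#'   \code{trace} data.frame (step, feature, cost).
#' @export
forwardSelect <- function(pool, grades, alpha, fuzzifier = 2, tol = 1e-6,
                          maxIter = 300L, nRestarts = 10L, seed = 1L,
                          minImprove = 1e-6, maxFeatures = Inf) {
  stopifnot(is(pool, "FeatureSet"), ncol(pool@data) >= 1)
  remaining <- pool@featureIds
  selected <- character(0)
  bestCost <- Inf
  trace <- data.frame(step = integer(), feature = character(),
                      cost = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  while (length(remaining) && length(selected) < maxFeatures) {
    costs <- vapply(remaining, function(f)
      evalSubsetCost(pool, c(selected, f), grades, alpha, fuzzifier, tol,
                     maxIter, nRestarts, seed), numeric(1))
    bestIdx <- which.min(costs)  # which.min keeps the earliest tie
    if (costs[bestIdx] < bestCost - minImprove) {
      step <- step + 1L
      selected <- c(selected, remaining[bestIdx])
      bestCost <- costs[bestIdx]
      trace <- rbind(trace, data.frame(step = step,
                                       feature = remaining[bestIdx],
                                       cost = bestCost))
      remaining <- remaining[-bestIdx]
    } else break
  }
  list(features = selected, cost = bestCost, trace = trace)
}

#' Greedy backward feature elimination under the separation cost
#'
#' Starts from the full pool and repeatedly drops the feature whose removal
#' minimizes the cost, stopping when no removal improves it by at least
#' \code{minImprove} (or a single feature remains).
#'
#' @inheritParams forwardSelect
#' @return list: \code{features}, \code{cost}, \code{trace}.
#' @export
backwardEliminate <- function(pool, grades, alpha, fuzzifier = 2, tol = 1e-6,
                              maxIter = 300L, nRestarts = 10L, seed = 1L,
                              minImprove = 1e-6) {
  stopifnot(is(pool, "FeatureSet"), ncol(pool@data) >= 1)
  selected <- pool@featureIds
  bestCost <- evalSubsetCost(pool, selected, grades, alpha, fuzzifier, tol,
                             maxIter, nRestarts, seed)
  trace <- data.frame(step = 0L, feature = NA_character_, cost = bestCost,
                      stringsAsFactors = FALSE)
  step <- 0L
  while (length(selected) > 1) {
    costs <- vapply(seq_along(selected), function(i)
      evalSubsetCost(pool, selected[-i], grades, alpha, fuzzifier, tol,
                     maxIter, nRestarts, seed), numeric(1))
    bestIdx <- which.min(costs)
    if (costs[bestIdx] < bestCost - minImprove) {
      step <- step + 1L
      trace <- rbind(trace, data.frame(step = step,
                                       feature = selected[bestIdx],
                                       cost = costs[bestIdx]))
      bestCost <- costs[bestIdx]
      selected <- selected[-bestIdx]
    } else break
  }
  list(features = selected, cost = bestCost, trace = trace)
}

#' Run feature selection over the alpha grid and pick the final signature
#'
#' Forward selection and backward elimination are run for every sigmoid
#' steepness in \code{alphas} (default the grid 1, 5, 10, 100) and all cost
#' curves are recorded; the final signature is the (direction, feature set)
#' pair minimizing the cost at \code{reportAlpha} (ties favor forward
#' selection).
#'
#' @inheritParams forwardSelect
#' @param alphas sigmoid steepness grid (default \code{c(1, 5, 10, 100)}).
#' @param reportAlpha the alpha at which the final signature is chosen
#'   (default 10).
#' @param directions selection directions to run.
#' @return list: \code{features}, \code{direction}, \code{alpha},
#'   \code{cost}, \code{runs} (per alpha/direction results) and
#'   \code{costCurve} data.frame (alpha, direction, step, n_features, cost).
#' @export
selectSignature <- function(pool, grades, alphas = c(1, 5, 10, 100),
                            reportAlpha = 10, fuzzifier = 2, tol = 1e-6,
                            maxIter = 300L, nRestarts = 10L, seed = 1L,
                            minImprove = 1e-6,
                            directions = c("forward", "backward")) {
  stopifnot(reportAlpha %in% alphas)
  runs <- list()
  curve <- data.frame()
  for (a in alphas) {
    if ("forward" %in% directions) {
      fw <- forwardSelect(pool, grades, a, fuzzifier, tol, maxIter, nRestarts,
                          seed, minImprove)
      runs[[sprintf("forward_a%g", a)]] <- fw
      if (nrow(fw$trace))
        curve <- rbind(curve, data.frame(alpha = a, direction = "forward",
                                         step = fw$trace$step,
                                         n_features = fw$trace$step,
                                         cost = fw$trace$cost))
    }
    if ("backward" %in% directions) {
      bw <- backwardEliminate(pool, grades, a, fuzzifier, tol, maxIter,
                              nRestarts, seed, minImprove)
      runs[[sprintf("backward_a%g", a)]] <- bw
      curve <- rbind(curve, data.frame(alpha = a, direction = "backward",
                                       step = bw$trace$step,
                                       n_features = length(pool@featureIds) -
                                         bw$trace$step,
                                       cost = bw$trace$cost))
    }
  }
  cands <- paste0(directions, sprintf("_a%g", reportAlpha))
  cands <- cands[cands %in% names(runs)]
  costs <- vapply(cands, function(nm) runs[[nm]]$cost, numeric(1))
  bestNm <- cands[which.min(costs)]
  best <- runs[[bestNm]]
  list(features = best$features,
       direction = sub("_a.*$", "", bestNm),
       alpha = reportAlpha, cost = best$cost, runs = runs, costCurve = curve)
}

#' Reclassify grade 2 samples by cluster membership
#'
#' Grade 2 samples with grade-3-cluster membership >= \code{threshold} become
#' \code{grade3_like}, those with membership <= \code{1 - threshold} become
#' \code{grade1_like}, the rest \code{intermediate} (an exact tie at a
#' degenerate 0.5/0.5 threshold is intermediate). Grade 1 and 3 samples are
#' untouched.
#'
#' @param result a \linkS4class{MembershipResult} with polarity set.
#' @param grades per-sample WHO grades aligned to the membership rows.
#' @param threshold upper membership cutoff (default 0.80).
#' @param lowerThreshold lower cutoff; defaults to \code{1 - threshold},
#'   rounded so that e.g. a membership of exactly 0.20 is grade-1-like under
#'   the default 0.80 cutoff.
#' @param features feature ids used (carried into the report).
#' @param alpha reporting sigmoid steepness (carried into the report).
#' @param cost final separation cost (carried into the report).
#' @return a \linkS4class{ReclassificationReport}.
#' @export
reclassifyGrade2 <- function(result, grades, threshold = 0.80,
                             lowerThreshold = round(1 - threshold, 12),
                             features = character(), alpha = NA_real_,
                             cost = NA_real_) {
  stopifnot(is(result, "MembershipResult"))
  p <- pGrade3(result)
  stopifnot(length(grades) == length(p))
  lower <- lowerThreshold
  idx <- which(grades == 2)
  if (!length(idx)) {
    warning("reclassifyGrade2: no grade 2 samples")
    return(new("ReclassificationReport", labels = character(0),
               pk = numeric(0), thresholds = c(lower = lower, upper = threshold),
               counts = setNames(integer(3), c("grade1_like", "intermediate",
                                               "grade3_like")),
               features = features, alpha = alpha, cost = cost))
  }
  pk <- p[idx]
  labels <- vapply(pk, function(v) {
    if (v >= threshold && v > lower) "grade3_like"
    else if (v <= lower && v < threshold) "grade1_like"
    else "intermediate"
  }, character(1))
  counts <- setNames(
    as.integer(table(factor(labels, levels = c("grade1_like", "intermediate",
                                               "grade3_like")))),
    c("grade1_like", "intermediate", "grade3_like"))
  new("ReclassificationReport", labels = labels, pk = pk,
      thresholds = c(lower = lower, upper = threshold), counts = counts,
      features = features, alpha = alpha, cost = cost)
}

#' Apply a fixed signature to a cohort
#'
#' Runs FCM on the given feature columns, determines polarity (using the
#' median-membership fallback automatically when the cohort has no grade 3
#' samples, the external-validation situation), and reclassifies the grade 2
#' samples. Used to carry a signature trained on one cohort onto another.
#'
#' @param features a \linkS4class{FeatureSet} for the new cohort.
#' @param grades per-sample WHO grades.
#' @param signatureFeatures feature ids of the trained signature.
#' @param threshold membership cutoff (default 0.80).
#' @param alpha reporting sigmoid steepness (cost is only computed when both
#'   grades 1 and 3 are present).
#' @param ... FCM settings passed to \code{\link{fcmCluster}}.
#' @return list: \code{membership} (\linkS4class{MembershipResult}) and
#'   \code{report} (\linkS4class{ReclassificationReport}).
#' @export
applySignature <- function(features, grades, signatureFeatures,
                           threshold = 0.80, alpha = 10, ...) {
  stopifnot(is(features, "FeatureSet"))
  missing <- setdiff(signatureFeatures, features@featureIds)
  if (length(missing))
    stop("applySignature: feature(s) absent from cohort: ",
         paste(missing, collapse = ", "), call. = FALSE)
  x <- features@data[, signatureFeatures, drop = FALSE]
  res <- fcmCluster(x, ...)
  res <- suppressWarnings(clusterPolarity(res, grades))
  cost <- if (any(grades == 1) && any(grades == 3))
    separationCost(pGrade3(res), grades, alpha) else NA_real_
  report <- reclassifyGrade2(res, grades, threshold = threshold,
                             features = signatureFeatures, alpha = alpha,
                             cost = cost)
  list(membership = res, report = report)
}
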