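# Weighted co-expression network stage: soft-thresholded adjacency,
# topological overlap, average-linkage clustering with a dynamic-hybrid-style
# tree cut, and first-principal-component module meta-genes.

asGeneMatrix <- function(x) {
  if (is(x, "MergedCohort")) exprsMat(x) else as.matrix(x)
}

#' Soft-thresholded adjacency matrix
#'
#' Unsigned network: \code{a_ij = |cor(x_i, x_j)|^beta} with unit diagonal.
#' Genes with zero variance get zero adjacency to all others (warning).
#'
#' @param x a \linkS4class{MergedCohort} or genes x samples matrix.
#' @param beta soft-thresholding power (>= 1).
#' @return symmetric gene x gene adjacency matrix in [0, 1].
#' @export
softThresholdAdjacency <- function(x, beta = 6) {
  stopifnot(beta >= 1)
  m <- asGeneMatrix(x)
  if (ncol(m) < 3) stop("softThresholdAdjacency: need >= 3 samples", call. = FALSE)
  v <- apply(m, 1L, var)
  r <- suppressWarnings(cor(t(m)))
  if (any(v == 0)) {
    warning("softThresholdAdjacency: ", sum(v == 0),
            " zero-variance gene(s); their correlations set to 0")
    r[v == 0, ] <- 0
    r[, v == 0] <- 0
  }
  a <- abs(r)^beta
  diag(a) <- 1
  a
}

# Scale-free topology fit: R^2 of log10(freq) ~ log10(k) over binned
# connectivities.
scaleFreeFit <- function(k, nBins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < nBins) return(NA_real_)
  cuts <- cut(k, breaks = nBins)
  freq <- tapply(k, cuts, length)
  meanK <- tapply(k, cuts, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- lm(log10(freq[keep] / sum(freq[keep])) ~ log10(meanK[keep]))
  summary(fit)$r.squared
}

#' Pick a soft-thresholding power by scale-free topology fit
#'
#' Returns the smallest candidate power whose scale-free model fit R^2
#' (regression of log10 connectivity-bin frequency on log10 mean connectivity
#' over >= 10 bins) reaches \code{rsqCut}; if none does, the power with the
#' maximal R^2. With fewer than 10 distinct connectivity values the default
#' power 6 is returned with a warning.
#'
#' @param x a \linkS4class{MergedCohort} or genes x samples matrix.
#' @param candidatePowers powers to scan.
#' @param rsqCut R^2 cutoff (default 0.80).
#' @return the chosen power, with the per-power fit table in attribute
#'   \code{"fits"}.
#' @export
pickSoftThreshold <- function(x, candidatePowers = c(1:10, 12, 14, 16, 18, 20),
                              rsqCut = 0.80) {
  stopifnot(length(candidatePowers) >= 1)
  m <- asGeneMatrix(x)
  r <- abs(suppressWarnings(cor(t(m))))
  r[is.na(r)] <- 0
  diag(r) <- 0
  fits <- vapply(candidatePowers, function(b) {
    k <- rowSums(r^b)
    if (length(unique(round(k, 12))) < 10) return(NA_real_)
    scaleFreeFit(k)
  }, numeric(1))
  tab <- data.frame(power = candidatePowers, rsq = fits)
  if (all(is.na(fits))) {
    warning("pickSoftThreshold: too few distinct connectivities; using beta = 6")
    beta <- 6
  } else if (any(fits >= rsqCut, na.rm = TRUE)) {
    beta <- candidatePowers[which(fits >= rsqCut)[1]]
  } else {
    beta <- candidatePowers[which.max(fits)]
  }
  attr(beta, "fits") <- tab
  beta
}

#' Topological overlap matrix
#'
#' \code{t_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)} with
#' \code{l_ij = sum_u a_iu a_uj} over \code{u != i, j} and connectivity
#' \code{k_i = sum_{u != i} a_iu}; unit diagonal.
#'
#' @param adj symmetric adjacency matrix in [0, 1] with unit diagonal.
#' @return symmetric TOM in [0, 1].
#' @export
topologicalOverlap <- function(adj) {
  adj <- as.matrix(adj)
  stopifnot(nrow(adj) == ncol(adj))
  if (max(abs(adj - t(adj))) > 1e-10)
    stop("topologicalOverlap: adjacency must be symmetric", call. = FALSE)
  if (any(adj < -1e-12 | adj > 1 + 1e-12))
    stop("topologicalOverlap: adjacency entries must lie in [0, 1]",
         call. = FALSE)
  a2 <- adj %*% adj
  # with unit diagonal, (A^2)_ij = l_ij + 2 a_ij off-diagonal
  l <- a2 - 2 * adj
  k <- rowSums(adj) - 1
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (l + adj) / pmax(denom, 1e-12)
  tom[denom < 1e-12] <- 0
  diag(tom) <- 1
  tom <- pmin(pmax(tom, 0), 1)
  dimnames(tom) <- dimnames(adj)
  tom
}

# Member leaves of every internal node of an hclust tree.
hclustMembers <- function(hc) {
  n <- length(hc$order)
  members <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    left <- hc$merge[i, 1]; right <- hc$merge[i, 2]
    lm <- if (left < 0) -left else members[[left]]
    rm_ <- if (right < 0) -right else members[[right]]
    members[[i]] <- c(lm, rm_)
  }
  members
}

#' Detect gene modules by dynamic tree cut of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering on dissimilarity \code{1 - TOM},
#' seeded by a fixed-height cut at the 0.99 quantile of merge heights, then a
#' recursive core-scatter cut of each seed cluster: a subtree is accepted as a
#' module when its core scatter (mean within-cluster dissimilarity) is at most
#' \code{min(height) + cohesionFrac * (max(height) - min(height))}; otherwise its two
#' children are examined recursively, which both separates correlated modules
#' that merge below the cut height and strips chained unassigned genes.
#' Expressing the criterion relative to the spread of merge heights keeps it
#' meaningful when TOM dissimilarities compress toward 1 at high
#' soft-thresholding powers. \code{deepSplit} (0..3, default 2) tightens
#' \code{cohesionFrac}, yielding more and purer modules. Clusters below
#' \code{minModuleSize} genes and non-cohesive remnants get label 0
#' (unassigned/grey). Modules are numbered 1..K by decreasing size (ties by
#' first gene id), so the labeling is invariant to gene order.
#'
#' @param tom TOM (or any gene x gene similarity in [0, 1]) with gene
#'   dimnames.
#' @param minModuleSize minimum module size (default 30).
#' @param deepSplit split sensitivity in 0..3 (default 2).
#' @return named integer vector gene -> module label (0 = unassigned).
#' @export
detectModules <- function(tom, minModuleSize = 30, deepSplit = 2) {
  stopifnot(deepSplit %in% 0:3, minModuleSize >= 2)
  tom <- as.matrix(tom)
  genes <- rownames(tom)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(tom)))
  n <- nrow(tom)
  d <- 1 - tom
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "average")
  h <- hc$height
  hCut <- as.numeric(quantile(h, 0.99))
  hMin <- min(h)
  hRange <- max(max(h) - hMin, .Machine$double.eps)
  members <- hclustMembers(hc)

  cohesionFrac <- c(0.65, 0.55, 0.45, 0.35)[deepSplit + 1]
  scatterCut <- hMin + cohesionFrac * hRange

  # per-node sum of pairwise dissimilarities (bottom-up, O(n^2) total)
  sumWithin <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    left <- hc$merge[i, 1]; right <- hc$merge[i, 2]
    lm <- if (left < 0) -left else members[[left]]
    rm_ <- if (right < 0) -right else members[[right]]
    sL <- if (left < 0) 0 else sumWithin[left]
    sR <- if (right < 0) 0 else sumWithin[right]
    sumWithin[i] <- sL + sR + 2 * sum(d[lm, rm_])
  }
  nodeSize <- function(node) if (node < 0) 1L else length(members[[node]])
  nodeScatter <- function(node) {
    k <- nodeSize(node)
    if (k < 2) return(0)
    sumWithin[node] / (k * (k - 1))
  }

  harvest <- function(node) {
    if (node < 0) return(list())
    mem <- members[[node]]
    if (length(mem) < minModuleSize) return(list())
    if (nodeScatter(node) <= scatterCut) return(list(mem))
    c(harvest(hc$merge[node, 1]), harvest(hc$merge[node, 2]))
  }

  # seed clusters: maximal subtrees fully merged below the cut height
  base <- cutree(hc, h = hCut)
  accepted <- list()
  for (cl in unique(base)) {
    idx <- which(base == cl)
    if (length(idx) < minModuleSize) next
    node <- NULL
    for (i in seq_along(members))
      if (length(members[[i]]) == length(idx) && all(members[[i]] %in% idx))
        node <- i
    if (is.null(node)) next
    accepted <- c(accepted, harvest(node))
  }

  labels <- setNames(integer(n), genes)
  if (length(accepted)) {
    sizes <- vapply(accepted, length, integer(1))
    firstGene <- vapply(accepted, function(cl) min(genes[cl]), character(1))
    ord <- order(-sizes, firstGene)
    for (j in seq_along(ord)) labels[accepted[[ord[j]]]] <- j
  }
  if (length(accepted) == 1 && length(accepted[[1]]) == n)
    warning("detectModules: all genes fell into a single module")
  labels
}

#' Module meta-genes (first principal component per module)
#'
#' For each module, member genes are standardized across samples and the
#' first principal component of the sample x gene submatrix is taken as the
#' module meta-gene. Scores are scaled to unit sample variance and
#' sign-oriented to correlate positively with the module's mean expression
#' profile; the first-PC variance share is recorded. Single-gene modules use
#' the gene's standardized profile (with a warning).
#'
#' @param cohort a \linkS4class{MergedCohort} or genes x samples matrix.
#' @param partition named gene -> module vector as from
#'   \code{\link{detectModules}}; label 0 is ignored.
#' @return a \linkS4class{MetaGeneMatrix} (rows \code{ME<label>}).
#' @export
moduleMetagene <- function(cohort, partition) {
  x <- asGeneMatrix(cohort)
  mods <- sort(unique(partition[partition > 0]))
  if (length(mods) == 0)
    stop("moduleMetagene: no modules in partition", call. = FALSE)
  scores <- matrix(0, length(mods), ncol(x),
                   dimnames = list(sprintf("ME%d", mods), colnames(x)))
  ve <- setNames(numeric(length(mods)), rownames(scores))
  sizes <- setNames(integer(length(mods)), rownames(scores))
  for (i in seq_along(mods)) {
    genes <- names(partition)[partition == mods[i]]
    sizes[i] <- length(genes)
    sub <- rowStandardize(x[genes, , drop = FALSE])
    if (length(genes) == 1) {
      warning("moduleMetagene: module ", mods[i], " has a single gene")
      sc <- as.numeric(sub)
      ve[i] <- 1
    } else {
      sv <- svd(t(sub))           # samples x genes
      sc <- sv$u[, 1] * sv$d[1]   # first-PC sample scores
      ve[i] <- sv$d[1]^2 / sum(sv$d^2)
    }
    if (sd(sc) > 0) sc <- sc / sd(sc)
    meanProfile <- colMeans(sub)
    if (cor(sc, meanProfile) < 0) sc <- -sc
    scores[i, ] <- sc
  }
  new("MetaGeneMatrix", scores = scores, varianceExplained = ve,
      moduleSizes = sizes)
}

#' Compare meta-gene expression between two grades
#'
#' Per-module Mann-Whitney test between the samples of \code{pair[1]} and
#' \code{pair[2]}, with the effect reported as
#' \code{median(pair[2]) - median(pair[1])} and a significance flag at
#' p <= \code{pCut}.
#'
#' @param metagenes a \linkS4class{MetaGeneMatrix}.
#' @param grades per-sample WHO grades aligned to the score columns.
#' @param pair length-2 grades to compare (default \code{c(1, 3)}).
#' @param pCut significance cutoff (default 0.05).
#' @return data.frame: \code{module}, \code{median_diff}, \code{p_value},
#'   \code{significant}.
#' @export
compareMetagenesByGrade <- function(metagenes, grades, pair = c(1L, 3L),
                                    pCut = 0.05) {
  stopifnot(is(metagenes, "MetaGeneMatrix"))
  s <- metageneScores(metagenes)
  stopifnot(length(grades) == ncol(s))
  a <- which(grades == pair[1]); b <- which(grades == pair[2])
  if (length(a) < 2 || length(b) < 2)
    stop("compareMetagenesByGrade: each grade of the pair needs >= 2 samples",
         call. = FALSE)
  out <- data.frame(module = rownames(s),
                    median_diff = NA_real_, p_value = NA_real_,
                    significant = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(s))) {
    out$median_diff[i] <- median(s[i, b]) - median(s[i, a])
    out$p_value[i] <- suppressWarnings(wilcox.test(s[i, b], s[i, a])$p.value)
  }
  out$significant <- out$p_value <= pCut
  out
}
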