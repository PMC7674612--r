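#' Configuration of the synthetic multi-study cohort generator
#'
#' Parameters of the linear factor model used to emulate the study design:
#' several microarray batches, planted co-expressed gene modules whose latent
#' activity differs between WHO grades 1 and 3, grade 2 samples drawn from a
#' mixture of grade-1-like / intermediate / grade-3-like latent states, and
#' recurrence outcomes whose probability depends on the latent state.
#'
#' @slot nGenes total number of genes.
#' @slot moduleSizes integer sizes of the planted modules.
#' @slot nBackgroundGenes number of pure-noise background genes;
#'   \code{sum(moduleSizes) + nBackgroundGenes == nGenes}.
#' @slot samplesPerGrade named integer vector \code{c(grade1=, grade2=, grade3=)}.
#' @slot grade2Mixture named fractions \code{c(grade1_like=, intermediate=,
#'   grade3_like=)} summing to 1.
#' @slot moduleEffects numeric matrix (modules x 2, columns \code{grade1},
#'   \code{grade3}): mean latent activity per module and grade; the
#'   intermediate state sits at the midpoint.
#' @slot withinModuleLoading factor loading in (0, 1] linking latent module
#'   activity to member-gene expression.
#' @slot activitySd sd of per-sample, per-module latent activity around its
#'   class mean.
#' @slot noiseSd sd of i.i.d. Gaussian expression noise.
#' @slot nBatches number of studies/batches.
#' @slot batchShiftSd sd of the per-batch, per-gene additive shift.
#' @slot batchScaleRange length-2 range of the per-batch multiplicative scale.
#' @slot recurrenceProbs named probabilities for latent classes
#'   \code{grade1, grade1_like, intermediate, grade3_like, grade3}.
#' @slot recurrenceMissingFrac fraction of samples whose recurrence status is
#'   masked to "unknown".
#' @slot seed integer RNG seed; identical configs give bit-identical cohorts.
#' @export
setClass("SynthConfig",
  slots = c(
    nGenes = "integer",
    moduleSizes = "integer",
    nBackgroundGenes = "integer",
    samplesPerGrade = "integer",
    grade2Mixture = "numeric",
    moduleEffects = "matrix",
    withinModuleLoading = "numeric",
    activitySd = "numeric",
    noiseSd = "numeric",
    nBatches = "integer",
    batchShiftSd = "numeric",
    batchScaleRange = "numeric",
    recurrenceProbs = "numeric",
    recurrenceMissingFrac = "numeric",
    seed = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (sum(object@moduleSizes) + object@nBackgroundGenes != object@nGenes)
    msg <- c(msg, "sum(moduleSizes) + nBackgroundGenes must equal nGenes")
  if (object@nBackgroundGenes < 0)
    msg <- c(msg, "sum(moduleSizes) must not exceed nGenes")
  if (abs(sum(object@grade2Mixture) - 1) > 1e-9)
    msg <- c(msg, "grade2Mixture must sum to 1 (tolerance 1e-9)")
  if (any(object@grade2Mixture < 0))
    msg <- c(msg, "grade2Mixture fractions must be non-negative")
  if (any(object@recurrenceProbs < 0 | object@recurrenceProbs > 1))
    msg <- c(msg, "recurrenceProbs must lie in [0, 1]")
  needed <- c("grade1", "grade1_like", "intermediate", "grade3_like", "grade3")
  if (!all(needed %in% names(object@recurrenceProbs)))
    msg <- c(msg, "recurrenceProbs must name all five latent classes")
  if (object@recurrenceMissingFrac < 0 || object@recurrenceMissingFrac > 1)
    msg <- c(msg, "recurrenceMissingFrac must lie in [0, 1]")
  if (object@withinModuleLoading <= 0 || object@withinModuleLoading > 1)
    msg <- c(msg, "withinModuleLoading must lie in (0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (object@activitySd < 0) msg <- c(msg, "activitySd must be non-negative")
  if (nrow(object@moduleEffects) != length(object@moduleSizes))
    msg <- c(msg, "moduleEffects must have one row per planted module")
  if (ncol(object@moduleEffects) != 2)
    msg <- c(msg, "moduleEffects must have two columns (grade1, grade3)")
  if (length(object@samplesPerGrade) != 3 ||
      !all(c("grade1", "grade2", "grade3") %in% names(object@samplesPerGrade)))
    msg <- c(msg, "samplesPerGrade must name grade1, grade2, grade3")
  if (object@nBatches < 1) msg <- c(msg, "nBatches must be >= 1")
  if (length(object@batchScaleRange) != 2 ||
      object@batchScaleRange[1] > object@batchScaleRange[2] ||
      any(object@batchScaleRange <= 0))
    msg <- c(msg, "batchScaleRange must be an increasing positive pair")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' One study's expression matrix
#'
#' @slot studyId study/batch label.
#' @slot exprs genes x samples numeric matrix with unique rownames (gene ids)
#'   and colnames (sample ids).
#' @slot scale \code{"linear"} or \code{"log2"}.
#' @export
setClass("StudyExpression",
  slots = c(studyId = "character", exprs = "matrix", scale = "character")
)

setValidity("StudyExpression", function(object) {
  msg <- character()
  if (!object@scale %in% c("linear", "log2"))
    msg <- c(msg, "scale must be 'linear' or 'log2'")
  if (is.null(rownames(object@exprs)) || anyDuplicated(rownames(object@exprs)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  if (is.null(colnames(object@exprs)) || anyDuplicated(colnames(object@exprs)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (!all(is.finite(object@exprs)))
    msg <- c(msg, "all expression values must be finite")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Merged multi-study cohort
#'
#' A \linkS4class{SummarizedExperiment} holding the merged (and, downstream,
#' globally standardized and batch-adjusted) log2 expression matrix in assay
#' \code{"exprs"}, with per-sample \code{batch}, \code{grade} (1/2/3) and
#' \code{recurrence} (\code{yes}/\code{no}/\code{unknown}) in \code{colData}.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("MergedCohort", contains = "SummarizedExperiment")

setValidity("MergedCohort", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  cd <- SummarizedExperiment::colData(object)
  for (col in c("batch", "grade", "recurrence"))
    if (!col %in% colnames(cd)) msg <- c(msg, paste0("colData column '", col, "' is required"))
  if ("grade" %in% colnames(cd) && !all(cd$grade %in% c(1L, 2L, 3L)))
    msg <- c(msg, "grade must be 1, 2 or 3")
  if ("recurrence" %in% colnames(cd) &&
      !all(cd$recurrence %in% c("yes", "no", "unknown")))
    msg <- c(msg, "recurrence must be yes/no/unknown")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Ground truth of a simulated cohort
#'
#' @slot sampleClass named latent class per sample
#'   (\code{G1, G2_1like, G2_int, G2_3like, G3}).
#' @slot geneModule named integer planted module id per gene (0 = background).
#' @slot activity modules x samples matrix of latent activities.
#' @slot config the generating \linkS4class{SynthConfig}.
#' @export
setClass("CohortTruth",
  slots = c(sampleClass = "character", geneModule = "integer",
            activity = "matrix", config = "SynthConfig")
)

setValidity("CohortTruth", function(object) {
  ok <- all(object@sampleClass %in% c("G1", "G2_1like", "G2_int", "G2_3like", "G3"))
  if (!ok) return("sampleClass must be one of G1, G2_1like, G2_int, G2_3like, G3")
  if (!identical(colnames(object@activity), names(object@sampleClass)))
    return("activity columns must align with sampleClass names")
  TRUE
})

#' Module meta-gene scores
#'
#' First-principal-component summaries of each module's gene submatrix:
#' one unit-variance, sign-fixed score per module and sample.
#'
#' @slot scores modules x samples matrix of standardized meta-gene scores.
#' @slot varianceExplained named per-module share of variance captured by the
#'   first principal component, in [0, 1].
#' @slot moduleSizes named integer number of genes per module.
#' @export
setClass("MetaGeneMatrix",
  slots = c(scores = "matrix", varianceExplained = "numeric",
            moduleSizes = "integer")
)

setValidity("MetaGeneMatrix", function(object) {
  msg <- character()
  if (any(object@varianceExplained < -1e-12 | object@varianceExplained > 1 + 1e-12))
    msg <- c(msg, "varianceExplained must lie in [0, 1]")
  if (length(object@varianceExplained) != nrow(object@scores))
    msg <- c(msg, "one varianceExplained entry per module row is required")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Standardized feature matrix for soft clustering
#'
#' @slot data samples x features matrix, each column standardized to mean 0,
#'   sd 1 across samples.
#' @slot featureIds feature identifiers (column names of \code{data}).
#' @slot featureType per-feature type, \code{"metagene"} or \code{"gene"}.
#' @export
setClass("FeatureSet",
  slots = c(data = "matrix", featureIds = "character", featureType = "character")
)

setValidity("FeatureSet", function(object) {
  msg <- character()
  if (ncol(object@data) != length(object@featureIds))
    msg <- c(msg, "featureIds must match the number of feature columns")
  if (length(object@featureType) != length(object@featureIds))
    msg <- c(msg, "featureType must be given per feature")
  if (!all(object@featureType %in% c("metagene", "gene")))
    msg <- c(msg, "featureType must be 'metagene' or 'gene'")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Fuzzy C-means clustering result
#'
#' @slot membership samples x clusters membership matrix; rows sum to 1.
#' @slot centroids clusters x features centroid matrix.
#' @slot fuzzifier FCM fuzzifier m (> 1).
#' @slot objective final FCM objective (sum of u^m d^2).
#' @slot objectiveTrace objective after each iteration of the best restart.
#' @slot iterations iterations used by the best restart.
#' @slot converged TRUE if the membership change fell below tolerance.
#' @slot polarity \code{"unset"}, \code{"cluster1_is_grade3"} or
#'   \code{"cluster2_is_grade3"}.
#' @slot pGrade3 named per-sample membership of the grade-3-enriched cluster
#'   (filled by \code{\link{clusterPolarity}}).
#' @export
setClass("MembershipResult",
  slots = c(membership = "matrix", centroids = "matrix", fuzzifier = "numeric",
            objective = "numeric", objectiveTrace = "numeric",
            iterations = "integer", converged = "logical",
            polarity = "character", pGrade3 = "numeric")
)

setValidity("MembershipResult", function(object) {
  u <- object@membership
  if (any(u < -1e-9 | u > 1 + 1e-9)) return("memberships must lie in [0, 1]")
  if (max(abs(rowSums(u) - 1)) > 1e-6)
    return("per-sample memberships must sum to 1")
  if (!object@polarity %in% c("unset", "cluster1_is_grade3", "cluster2_is_grade3"))
    return("invalid polarity")
  TRUE
})

#' Grade 2 reclassification report
#'
#' @slot labels named label per grade 2 sample: \code{grade1_like},
#'   \code{intermediate} or \code{grade3_like}.
#' @slot pk named grade-3-cluster membership per grade 2 sample.
#' @slot thresholds \code{c(lower=, upper=)} membership cutoffs (default
#'   0.20 / 0.80).
#' @slot counts named label counts.
#' @slot features feature ids of the signature used.
#' @slot alpha sigmoid steepness used for the reported cost.
#' @slot cost final balanced sigmoidal separation cost.
#' @export
setClass("ReclassificationReport",
  slots = c(labels = "character", pk = "numeric", thresholds = "numeric",
            counts = "integer", features = "character", alpha = "numeric",
            cost = "numeric")
)

setValidity("ReclassificationReport", function(object) {
  if (!all(object@labels %in% c("grade1_like", "intermediate", "grade3_like")))
    return("labels must be grade1_like/intermediate/grade3_like")
  if (length(object@labels) != length(object@pk))
    return("labels and pk must align")
  TRUE
})

## ---- constructors ----------------------------------------------------------

#' Create a StudyExpression object
#'
#' @param studyId study/batch label.
#' @param exprs genes x samples matrix with gene rownames and sample colnames.
#' @param scale \code{"linear"} or \code{"log2"}.
#' @return a \linkS4class{StudyExpression}.
#' @export
StudyExpression <- function(studyId, exprs, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  new("StudyExpression", studyId = as.character(studyId),
      exprs = as.matrix(exprs), scale = scale)
}

#' Create a MergedCohort from a matrix and per-sample metadata
#'
#' @param exprs genes x samples matrix.
#' @param batch per-sample batch/study label.
#' @param grade per-sample WHO grade (1, 2 or 3).
#' @param recurrence per-sample \code{yes}/\code{no}/\code{unknown}
#'   (default all unknown).
#' @return a \linkS4class{MergedCohort}.
#' @export
MergedCohort <- function(exprs, batch, grade,
                         recurrence = rep("unknown", ncol(exprs))) {
  exprs <- as.matrix(exprs)
  cd <- S4Vectors::DataFrame(batch = as.character(batch),
                             grade = as.integer(grade),
                             recurrence = as.character(recurrence),
                             row.names = colnames(exprs))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs), colData = cd)
  new("MergedCohort", se)
}

## ---- accessors -------------------------------------------------------------

#' @describeIn StudyExpression the expression matrix.
#' @param x object.
#' @export
setMethod("exprsMat", "StudyExpression", function(x) x@exprs)

#' @describeIn MergedCohort the expression assay.
#' @export
setMethod("exprsMat", "MergedCohort",
          function(x) SummarizedExperiment::assay(x, "exprs"))

#' @describeIn StudyExpression the study label.
#' @export
setMethod("studyId", "StudyExpression", function(x) x@studyId)

#' @describeIn StudyExpression the scale flag.
#' @export
setMethod("exprScale", "StudyExpression", function(x) x@scale)

#' @describeIn MergedCohort per-sample batch labels.
#' @export
setMethod("sampleBatch", "MergedCohort",
          function(x) SummarizedExperiment::colData(x)$batch)

#' @describeIn MergedCohort per-sample WHO grades.
#' @export
setMethod("sampleGrade", "MergedCohort",
          function(x) SummarizedExperiment::colData(x)$grade)

#' @describeIn MergedCohort per-sample recurrence status.
#' @export
setMethod("sampleRecurrence", "MergedCohort",
          function(x) SummarizedExperiment::colData(x)$recurrence)

#' @describeIn MetaGeneMatrix modules x samples score matrix.
#' @param x object.
#' @export
setMethod("metageneScores", "MetaGeneMatrix", function(x) x@scores)

#' @describeIn MetaGeneMatrix per-module first-PC variance share.
#' @export
setMethod("varianceExplained", "MetaGeneMatrix", function(x) x@varianceExplained)

#' @describeIn FeatureSet samples x features matrix.
#' @param x object.
#' @export
setMethod("featureMatrix", "FeatureSet", function(x) x@data)

#' @describeIn MembershipResult samples x clusters membership matrix.
#' @param x object.
#' @export
setMethod("membershipMatrix", "MembershipResult", function(x) x@membership)

#' @describeIn MembershipResult grade-3-cluster membership per sample
#'   (requires polarity to be set).
#' @export
setMethod("pGrade3", "MembershipResult", function(x) {
  if (x@polarity == "unset")
    stop("polarity has not been determined; run clusterPolarity() first",
         call. = FALSE)
  x@pGrade3
})

#' @describeIn MembershipResult the polarity flag.
#' @export
setMethod("clusterPolarityOf", "MembershipResult", function(x) x@polarity)

#' @describeIn ReclassificationReport named labels of the grade 2 samples.
#' @param x object.
#' @export
setMethod("reclassLabels", "ReclassificationReport", function(x) x@labels)

## ---- show ------------------------------------------------------------------

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig:", object@nGenes, "genes (",
      length(object@moduleSizes), "planted modules,",
      object@nBackgroundGenes, "background),",
      sum(object@samplesPerGrade), "samples across",
      object@nBatches, "batches\n")
  cat("  samples per grade:",
      paste(names(object@samplesPerGrade), object@samplesPerGrade,
            sep = "=", collapse = ", "), "\n")
  cat("  grade 2 mixture:",
      paste(names(object@grade2Mixture),
            signif(object@grade2Mixture, 3), sep = "=", collapse = ", "), "\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "StudyExpression", function(object) {
  cat("StudyExpression", object@studyId, ":", nrow(object@exprs), "genes x",
      ncol(object@exprs), "samples (", object@scale, "scale )\n")
})

setMethod("show", "MetaGeneMatrix", function(object) {
  cat("MetaGeneMatrix:", nrow(object@scores), "modules x",
      ncol(object@scores), "samples; median variance explained",
      signif(median(object@varianceExplained), 3), "\n")
})

setMethod("show", "MembershipResult", function(object) {
  cat("MembershipResult:", nrow(object@membership), "samples,",
      ncol(object@membership), "clusters; m =", object@fuzzifier,
      "; objective", signif(object@objective, 6),
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  cat("  polarity:", object@polarity, "\n")
})

setMethod("show", "ReclassificationReport", function(object) {
  cat("ReclassificationReport:", length(object@labels), "grade 2 samples\n")
  cat("  counts:", paste(names(object@counts), object@counts, sep = "=",
                         collapse = ", "), "\n")
  cat("  thresholds:", paste(signif(object@thresholds, 3), collapse = " / "),
      "; alpha =", object@alpha, "; cost =", signif(object@cost, 6), "\n")
  if (length(object@features))
    cat("  signature:", paste(object@features, collapse = ", "), "\n")
})
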