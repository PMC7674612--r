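# Per-study normalization, merging, global standardization and batch
# adjustment. Fixed pipeline order: log2 -> quantile -> merge -> global scale
# -> ComBat.

#' Log2-transform a linear-scale study
#'
#' Applies \code{log2(x + 1)}; the +1 offset accommodates zeros (e.g. RNA-seq
#' counts). Studies already flagged as log2 pass through unchanged.
#'
#' @param study a \linkS4class{StudyExpression}.
#' @return the study on log2 scale.
#' @examples
#' s <- StudyExpression("a", matrix(c(1, 3, 7, 15), 2, 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))), scale = "linear")
#' exprsMat(log2Transform(s))
#' @export
log2Transform <- function(study) {
  stopifnot(is(study, "StudyExpression"))
  if (study@scale == "log2") return(study)
  if (any(study@exprs <= -1))
    stop("log2Transform: values <= -1 present; log2(x + 1) undefined",
         call. = FALSE)
  StudyExpression(study@studyId, log2(study@exprs + 1), scale = "log2")
}

#' Quantile-normalize a study across samples
#'
#' Every sample's sorted value vector is replaced by the across-sample mean of
#' sorted vectors; ranks within each sample are preserved and ties receive the
#' mean of the tied reference quantiles (\code{limma::normalizeQuantiles} with
#' \code{ties = TRUE}).
#'
#' @param study a \linkS4class{StudyExpression}.
#' @return the quantile-normalized study. A single-sample study is returned
#'   unchanged with a warning.
#' @export
quantileNormalize <- function(study) {
  stopifnot(is(study, "StudyExpression"))
  if (ncol(study@exprs) < 2) {
    warning("quantileNormalize: single-sample study '", study@studyId,
            "' returned unchanged")
    return(study)
  }
  norm <- limma::normalizeQuantiles(study@exprs, ties = TRUE)
  dimnames(norm) <- dimnames(study@exprs)
  StudyExpression(study@studyId, norm, scale = study@scale)
}

#' Merge studies on their common genes
#'
#' Restricts every study to the intersection of gene ids (sorted
#' lexicographically), concatenates sample columns in study order, and
#' attaches per-sample metadata; the batch label is the study id.
#'
#' @param studies list of log2-scale \linkS4class{StudyExpression} objects.
#' @param metadata data.frame with columns \code{sample_id}, \code{who_grade},
#'   \code{recurrence} (optional; default unknown) covering every sample.
#' @return a \linkS4class{MergedCohort}.
#' @export
intersectAndMerge <- function(studies, metadata) {
  stopifnot(length(studies) >= 1)
  for (s in studies) {
    stopifnot(is(s, "StudyExpression"))
    if (s@scale != "log2")
      stop("intersectAndMerge: study '", s@studyId, "' is not on log2 scale",
           call. = FALSE)
  }
  genes <- Reduce(intersect, lapply(studies, function(s) rownames(s@exprs)))
  if (length(genes) == 0)
    stop("intersectAndMerge: empty gene intersection across studies",
         call. = FALSE)
  genes <- sort(genes)
  expr <- do.call(cbind, lapply(studies, function(s) s@exprs[genes, , drop = FALSE]))
  batch <- unlist(lapply(studies, function(s) rep(s@studyId, ncol(s@exprs))))
  missing <- setdiff(colnames(expr), metadata$sample_id)
  if (length(missing))
    stop("intersectAndMerge: sample(s) missing metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  md <- metadata[match(colnames(expr), metadata$sample_id), ]
  rec <- if ("recurrence" %in% names(md)) md$recurrence
         else rep("unknown", ncol(expr))
  MergedCohort(expr, batch = batch, grade = md$who_grade, recurrence = rec)
}

#' Scale a merged cohort to global mean 0 and sd 1
#'
#' Subtracts the grand mean and divides by the grand (population) standard
#' deviation over all matrix entries.
#'
#' @param cohort a \linkS4class{MergedCohort}.
#' @return the globally standardized cohort.
#' @export
globalScale <- function(cohort) {
  stopifnot(is(cohort, "MergedCohort"))
  x <- exprsMat(cohort)
  if (!all(is.finite(x)))
    stop("globalScale: non-finite values present", call. = FALSE)
  s <- popSd(as.vector(x))
  if (s == 0) stop("globalScale: zero grand standard deviation", call. = FALSE)
  SummarizedExperiment::assay(cohort, "exprs") <- (x - mean(x)) / s
  cohort
}

#' Remove batch effects with parametric empirical-Bayes adjustment
#'
#' Location-scale batch adjustment (ComBat): per-gene standardization,
#' per-batch per-gene additive and multiplicative effects estimated and shrunk
#' toward batch-level priors (normal prior on the additive effect,
#' inverse-gamma on the multiplicative one; moment-matched hyperparameters;
#' iterative conditional estimation), adjusted data back-transformed.
#' Backed by \code{sva::ComBat} with parametric priors and no covariates
#' (grade is deliberately not protected).
#'
#' @param cohort a \linkS4class{MergedCohort} with >= 2 batches, each with
#'   >= 2 samples.
#' @return the batch-adjusted cohort (shape and metadata unchanged).
#' @export
combatAdjust <- function(cohort) {
  stopifnot(is(cohort, "MergedCohort"))
  batch <- sampleBatch(cohort)
  tab <- table(batch)
  if (length(tab) < 2)
    stop("combatAdjust: at least two batches are required", call. = FALSE)
  if (any(tab < 2))
    stop("combatAdjust: batch(es) with fewer than 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  adj <- suppressMessages(
    sva::ComBat(dat = exprsMat(cohort), batch = factor(batch),
                mod = NULL, par.prior = TRUE, prior.plots = FALSE))
  SummarizedExperiment::assay(cohort, "exprs") <- adj
  cohort
}

#' Run the full per-study preprocessing chain
#'
#' Convenience wrapper applying the fixed order: \code{log2Transform},
#' \code{quantileNormalize} per study, \code{intersectAndMerge},
#' \code{globalScale}, then \code{combatAdjust} (skipped with a warning if
#' only one batch is present).
#'
#' @param studies list of \linkS4class{StudyExpression}.
#' @param metadata sample metadata data.frame (see
#'   \code{\link{intersectAndMerge}}).
#' @return a preprocessed \linkS4class{MergedCohort}.
#' @export
preprocessCohort <- function(studies, metadata) {
  studies <- lapply(studies, function(s) quantileNormalize(log2Transform(s)))
  cohort <- globalScale(intersectAndMerge(studies, metadata))
  if (length(unique(sampleBatch(cohort))) >= 2) cohort <- combatAdjust(cohort)
  else warning("preprocessCohort: single batch; batch adjustment skipped")
  cohort
}
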