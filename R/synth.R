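# Synthetic multi-study cohort generator.
#
# Linear factor model: expression of a gene in planted module m for sample s is
#   loading * activity(m, s) * batchScale(b(s)) + batchShift(b(s), g) + noise,
# where activity(m, s) = class mean + N(0, activitySd). Background genes carry
# batch effects and noise only. This is the implicit generative model of
# first-principal-component meta-gene summarization.

#' Build a synthetic-cohort configuration
#'
#' Defaults mirror the meta-analysis design the pipeline targets: 212 samples
#' (129 grade 1, 46 grade 2, 37 grade 3) spread over six studies, a grade 2
#' population mixing grade-1-like / intermediate / grade-3-like latent states
#' in proportions 13/12/21 out of 46, and recurrence probabilities of 0.17
#' (grade 1), 0.05 (grade-1-like), 0.25 (intermediate), 0.75 (grade-3-like)
#' and 0.85 (grade 3), with 46% of samples lacking recurrence annotation.
#' Five modules are planted, one with no grade effect (a null module).
#'
#' @param nGenes total gene count.
#' @param moduleSizes planted module sizes.
#' @param samplesPerGrade named counts for grades 1/2/3.
#' @param grade2Mixture named fractions of grade 2 latent states (sum 1).
#' @param moduleEffects modules x 2 matrix of mean latent activity for
#'   (grade1, grade3); intermediate = midpoint.
#' @param withinModuleLoading factor loading in (0, 1].
#' @param activitySd sd of latent activity around its class mean.
#' @param noiseSd sd of i.i.d. expression noise.
#' @param nBatches number of studies.
#' @param batchShiftSd sd of additive per-batch, per-gene shifts.
#' @param batchScaleRange range of multiplicative per-batch scales.
#' @param recurrenceProbs named per-latent-class recurrence probabilities.
#' @param recurrenceMissingFrac fraction of samples with unknown recurrence.
#' @param seed integer RNG seed.
#' @return a validated \linkS4class{SynthConfig}.
#' @examples
#' cfg <- synthConfig(seed = 7)
#' cfg
#' @export
synthConfig <- function(nGenes = 600L,
                        moduleSizes = c(45L, 40L, 35L, 30L, 30L),
                        samplesPerGrade = c(grade1 = 129L, grade2 = 46L,
                                            grade3 = 37L),
                        grade2Mixture = c(grade1_like = 13 / 46,
                                          intermediate = 12 / 46,
                                          grade3_like = 21 / 46),
                        moduleEffects = rbind(c(-1.0, 1.0),
                                              c(1.0, -1.0),
                                              c(-1.2, 0.8),
                                              c(0.9, -1.1),
                                              c(0.0, 0.0)),
                        withinModuleLoading = 0.9,
                        activitySd = 1.0,
                        noiseSd = 0.5,
                        nBatches = 6L,
                        batchShiftSd = 0.5,
                        batchScaleRange = c(0.8, 1.25),
                        recurrenceProbs = c(grade1 = 0.17, grade1_like = 0.05,
                                            intermediate = 0.25,
                                            grade3_like = 0.75, grade3 = 0.85),
                        recurrenceMissingFrac = 0.46,
                        seed = 1L) {
  moduleEffects <- as.matrix(moduleEffects)
  colnames(moduleEffects) <- c("grade1", "grade3")
  cfg <- new("SynthConfig",
             nGenes = as.integer(nGenes),
             moduleSizes = as.integer(moduleSizes),
             nBackgroundGenes = as.integer(nGenes - sum(moduleSizes)),
             samplesPerGrade = setNames(as.integer(samplesPerGrade),
                                        c("grade1", "grade2", "grade3")),
             grade2Mixture = setNames(as.numeric(grade2Mixture),
                                      c("grade1_like", "intermediate",
                                        "grade3_like")),
             moduleEffects = moduleEffects,
             withinModuleLoading = withinModuleLoading,
             activitySd = activitySd,
             noiseSd = noiseSd,
             nBatches = as.integer(nBatches),
             batchShiftSd = batchShiftSd,
             batchScaleRange = as.numeric(batchScaleRange),
             recurrenceProbs = recurrenceProbs,
             recurrenceMissingFrac = recurrenceMissingFrac,
             seed = as.integer(seed))
  validObject(cfg)
  cfg
}

# Largest-remainder allocation of n items to fractions p (sums to n exactly).
largestRemainder <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

classMeanActivity <- function(effects, class) {
  mid <- (effects[, "grade1"] + effects[, "grade3"]) / 2
  switch(class,
         G1 = effects[, "grade1"],
         G2_1like = effects[, "grade1"],
         G2_int = mid,
         G2_3like = effects[, "grade3"],
         G3 = effects[, "grade3"])
}

#' Simulate a multi-study meningioma-like cohort
#'
#' Generates one \linkS4class{StudyExpression} per batch, a sample metadata
#' table and the latent ground truth, under the factor model described in
#' \code{\link{synthConfig}}. Samples of every grade are spread round-robin
#' across batches, so each grade appears in at least two batches whenever
#' \code{nBatches >= 2}. Grade 2 latent states are allocated by largest
#' remainder, so the default configuration reproduces the 13/12/21 split
#' exactly. Output is deterministic given the config (including its seed).
#'
#' @param config a \linkS4class{SynthConfig}.
#' @return a list with elements \code{studies} (list of
#'   \linkS4class{StudyExpression}, scale \code{"log2"}), \code{metadata}
#'   (data.frame: sample_id, study_id, who_grade, recurrence) and
#'   \code{truth} (\linkS4class{CohortTruth}).
#' @examples
#' sim <- simulateCohort(synthConfig(seed = 42))
#' length(sim$studies)
#' head(sim$metadata)
#' @export
simulateCohort <- function(config) {
  if (!is(config, "SynthConfig"))
    stop("config must be a SynthConfig", call. = FALSE)
  validObject(config)

  withLocalSeed(config@seed, {
    nPer <- config@samplesPerGrade
    n <- sum(nPer)
    nMod <- length(config@moduleSizes)

    # latent classes; grade 2 split by largest remainder, order shuffled
    g2counts <- largestRemainder(nPer[["grade2"]], config@grade2Mixture)
    g2classes <- sample(rep(c("G2_1like", "G2_int", "G2_3like"), g2counts))
    sampleClass <- c(rep("G1", nPer[["grade1"]]), g2classes,
                     rep("G3", nPer[["grade3"]]))
    whoGrade <- c(rep(1L, nPer[["grade1"]]), rep(2L, nPer[["grade2"]]),
                  rep(3L, nPer[["grade3"]]))
    sampleIds <- sprintf("S%04d", seq_len(n))
    names(sampleClass) <- sampleIds

    # round-robin batch assignment within each grade
    batch <- integer(n)
    for (g in 1:3) {
      idx <- which(whoGrade == g)
      batch[idx] <- rep_len(seq_len(config@nBatches), length(idx))
    }
    studyIds <- sprintf("study%d", batch)

    # latent activity: class mean + jitter
    activity <- matrix(0, nMod, n,
                       dimnames = list(sprintf("M%d", seq_len(nMod)), sampleIds))
    for (s in seq_len(n))
      activity[, s] <- classMeanActivity(config@moduleEffects, sampleClass[s])
    activity <- activity + matrix(rnorm(nMod * n, 0, config@activitySd), nMod, n)

    # gene -> module map
    geneIds <- sprintf("G%06d", seq_len(config@nGenes))
    geneModule <- c(rep(seq_len(nMod), config@moduleSizes),
                    rep(0L, config@nBackgroundGenes))
    geneModule <- setNames(as.integer(geneModule), geneIds)

    # batch effects
    shift <- matrix(rnorm(config@nGenes * config@nBatches, 0, config@batchShiftSd),
                    config@nGenes, config@nBatches)
    scale <- runif(config@nBatches, config@batchScaleRange[1],
                   config@batchScaleRange[2])

    # expression
    signal <- matrix(0, config@nGenes, n, dimnames = list(geneIds, sampleIds))
    inMod <- geneModule > 0L
    signal[inMod, ] <- config@withinModuleLoading * activity[geneModule[inMod], ]
    expr <- signal * rep(scale[batch], each = config@nGenes) +
      shift[, batch] +
      matrix(rnorm(config@nGenes * n, 0, config@noiseSd), config@nGenes, n)

    # recurrence outcomes, masked to unknown for a fixed fraction
    probs <- config@recurrenceProbs[
      c(G1 = "grade1", G2_1like = "grade1_like", G2_int = "intermediate",
        G2_3like = "grade3_like", G3 = "grade3")[sampleClass]]
    recurrence <- ifelse(rbinom(n, 1L, probs) == 1L, "yes", "no")
    nMask <- round(config@recurrenceMissingFrac * n)
    if (nMask > 0) recurrence[sample.int(n, nMask)] <- "unknown"

    metadata <- data.frame(sample_id = sampleIds, study_id = studyIds,
                           who_grade = whoGrade, recurrence = recurrence,
                           stringsAsFactors = FALSE)

    studies <- lapply(sort(unique(batch)), function(b) {
      StudyExpression(sprintf("study%d", b), expr[, batch == b, drop = FALSE],
                      scale = "log2")
    })

    truth <- new("CohortTruth", sampleClass = sampleClass,
                 geneModule = geneModule, activity = activity, config = config)

    list(studies = studies, metadata = metadata, truth = truth)
  })
}

#' Summarize the latent truth of a simulated cohort
#'
#' @param truth a \linkS4class{CohortTruth}.
#' @param metadata the matching metadata data.frame (for recurrence rates);
#'   may be omitted, in which case rates are \code{NA}.
#' @return data.frame with one row per latent class: \code{class}, \code{n},
#'   \code{n_known} (recurrence annotated) and \code{recurrence_rate} among
#'   known samples.
#' @export
truthSummary <- function(truth, metadata = NULL) {
  stopifnot(is(truth, "CohortTruth"))
  classes <- c("G1", "G2_1like", "G2_int", "G2_3like", "G3")
  cls <- factor(truth@sampleClass, levels = classes)
  out <- data.frame(class = classes, n = as.integer(table(cls)),
                    n_known = NA_integer_, recurrence_rate = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    rec <- setNames(metadata$recurrence, metadata$sample_id)
    rec <- rec[names(truth@sampleClass)]
    for (i in seq_along(classes)) {
      known <- rec[cls == classes[i] & rec != "unknown"]
      out$n_known[i] <- length(known)
      out$recurrence_rate[i] <-
        if (length(known)) mean(known == "yes") else NA_real_
    }
  }
  out
}
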