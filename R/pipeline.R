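# End-to-end orchestration: simulate (or load) -> preprocess -> differential
# expression -> co-expression network -> reclassify -> validate, with every
# artifact written as TSV/JSON and all randomness derived from one master
# seed.

#' Assemble a pipeline configuration
#'
#' Every stage parameter defaults to the published analysis value where one
#' exists (fold-change 1.5, p cutoffs 1e-4 and 0.05, membership threshold
#' 0.80, sigmoid steepness grid 1/5/10/100) and to the method's canonical
#' setting otherwise.
#'
#' @param outDir output directory for artifacts.
#' @param synth a \linkS4class{SynthConfig} to simulate inputs, or NULL to
#'   read \code{expressionPaths}/\code{metadataPath}.
#' @param expressionPaths character vector of per-study expression TSVs
#'   (used when \code{synth} is NULL).
#' @param metadataPath metadata TSV path (used when \code{synth} is NULL).
#' @param inputScale \code{"log2"} or \code{"linear"} scale of file inputs.
#' @param fcThreshold,pThreshold differential-expression cutoffs.
#' @param metagenePCut meta-gene grade-comparison cutoff.
#' @param beta soft-thresholding power (default 6, the canonical unsigned
#'   choice), or NULL to pick by scale-free fit via
#'   \code{\link{pickSoftThreshold}}.
#' @param minModuleSize,deepSplit tree-cut settings.
#' @param maxGenes single-gene candidate cap for feature selection.
#' @param alphas,reportAlpha sigmoid steepness grid and reporting value.
#' @param fuzzifier,fcmTol,fcmMaxIter,fcmRestarts FCM settings.
#' @param membershipThreshold reclassification cutoff (default 0.80).
#' @param signatureFeatures optional pre-trained signature (feature ids);
#'   when given, feature selection is skipped and the signature is applied
#'   as-is (the external-validation mode, usable without grade 3 samples).
#' @param seed master seed; all stage seeds derive from it.
#' @return a named list of settings for \code{\link{runPipeline}}.
#' @export
pipelineConfig <- function(outDir = tempfile("meningrade_run_"),
                           synth = synthConfig(),
                           expressionPaths = NULL, metadataPath = NULL,
                           inputScale = "log2",
                           fcThreshold = 1.5, pThreshold = 1e-4,
                           metagenePCut = 0.05,
                           beta = 6, minModuleSize = 30, deepSplit = 2,
                           maxGenes = 25,
                           alphas = c(1, 5, 10, 100), reportAlpha = 10,
                           fuzzifier = 2, fcmTol = 1e-6, fcmMaxIter = 300L,
                           fcmRestarts = 10L,
                           membershipThreshold = 0.80,
                           signatureFeatures = NULL,
                           seed = 1L) {
  as.list(environment())
}

#' Run the full reclassification pipeline
#'
#' Executes, in order: input simulation (or loading), per-study normalization
#' and merging with batch adjustment, grade 1 vs 3 differential expression,
#' co-expression module detection with meta-genes, fuzzy-C-means signature
#' selection (or application of a supplied signature), grade 2
#' reclassification, and recurrence/concordance validation. All artifacts are
#' written under \code{config$outDir}; a machine-readable summary is returned
#' invisibly and written as \code{summary.json}.
#'
#' @param config list from \code{\link{pipelineConfig}}.
#' @return (invisibly) a summary list: reclassification counts, chosen
#'   signature, final cost, and validation statistics.
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)

  # ---- inputs ----
  if (!is.null(config$synth)) {
    cfg <- config$synth
    cfg@seed <- deriveSeed(config$seed, "simulate")
    sim <- simulateCohort(cfg)
    studies <- sim$studies
    metadata <- sim$metadata
    for (s in studies)
      writeExpressionTsv(s, file.path(config$outDir,
                                      paste0(studyId(s), "_expression.tsv")))
    writeMetadataTsv(metadata, file.path(config$outDir, "metadata.tsv"))
    write.table(data.frame(sample_id = names(sim$truth@sampleClass),
                           latent_class = sim$truth@sampleClass),
                file.path(config$outDir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    if (is.null(config$expressionPaths) || is.null(config$metadataPath))
      stop("runPipeline: expressionPaths and metadataPath are required ",
           "when no synthetic config is given", call. = FALSE)
    for (p in c(config$expressionPaths, config$metadataPath))
      if (!file.exists(p))
        stop("runPipeline: input file not found: ", p, call. = FALSE)
    metadata <- readMetadataTsv(config$metadataPath)
    studies <- lapply(config$expressionPaths, function(p) {
      m <- readExpressionTsv(p)
      sid <- metadata$study_id[match(colnames(m), metadata$sample_id)][1]
      StudyExpression(sid %||% basename(p), m, scale = config$inputScale)
    })
  }

  # ---- preprocess ----
  cohort <- preprocessCohort(studies, metadata)
  writeExpressionTsv(cohort, file.path(config$outDir, "merged_expression.tsv"))
  grades <- sampleGrade(cohort)

  # ---- differential expression (needs both training grades) ----
  hasG13 <- any(grades == 1) && any(grades == 3)
  de <- NULL
  if (hasG13) {
    de <- deTest(cohort, fcThreshold = config$fcThreshold,
                 pThreshold = config$pThreshold)
    write.table(de, file.path(config$outDir, "de_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # ---- co-expression network ----
  beta <- config$beta %||% as.numeric(pickSoftThreshold(cohort))
  adj <- softThresholdAdjacency(cohort, beta = beta)
  tom <- topologicalOverlap(adj)
  partition <- detectModules(tom, minModuleSize = config$minModuleSize,
                             deepSplit = config$deepSplit)
  write.table(data.frame(gene_id = names(partition), module = partition),
              file.path(config$outDir, "modules.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!any(partition > 0))
    stop("runPipeline: network stage found no modules", call. = FALSE)
  metag <- moduleMetagene(cohort, partition)
  writeExpressionTsv(metageneScores(metag),
                     file.path(config$outDir, "metagenes.tsv"))
  cmp <- if (hasG13)
    compareMetagenesByGrade(metag, grades, pCut = config$metagenePCut)
  else NULL
  if (!is.null(cmp))
    write.table(cmp, file.path(config$outDir, "metagene_grade_comparison.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- reclassify ----
  fcmSeed <- deriveSeed(config$seed, "fcm")
  if (is.null(config$signatureFeatures)) {
    if (!hasG13)
      stop("runPipeline: training a signature requires grades 1 and 3; ",
           "supply signatureFeatures to apply a saved signature", call. = FALSE)
    pool <- candidateFeatures(cohort, deResult = de, metagenes = metag,
                              gradeComparison = cmp,
                              maxGenes = config$maxGenes)
    sig <- selectSignature(pool, grades, alphas = config$alphas,
                           reportAlpha = config$reportAlpha,
                           fuzzifier = config$fuzzifier, tol = config$fcmTol,
                           maxIter = config$fcmMaxIter,
                           nRestarts = config$fcmRestarts, seed = fcmSeed)
    write.table(sig$costCurve, file.path(config$outDir, "cost_curves.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    signatureFeatures <- sig$features
    sigInfo <- list(features = sig$features, direction = sig$direction,
                    alpha = sig$alpha, cost = sig$cost)
  } else {
    signatureFeatures <- config$signatureFeatures
    pool <- featureSetFrom(cohort, metag, signatureFeatures)
    sigInfo <- list(features = signatureFeatures, direction = "fixed",
                    alpha = config$reportAlpha, cost = NA_real_)
  }
  applied <- applySignature(pool, grades, signatureFeatures,
                            threshold = config$membershipThreshold,
                            alpha = config$reportAlpha,
                            fuzzifier = config$fuzzifier, tol = config$fcmTol,
                            maxIter = config$fcmMaxIter,
                            nRestarts = config$fcmRestarts, seed = fcmSeed)
  membership <- applied$membership
  report <- applied$report
  sigInfo$cost <- report@cost
  jsonlite::write_json(sigInfo, file.path(config$outDir, "signature.json"),
                       auto_unbox = TRUE, digits = NA)
  p3 <- pGrade3(membership)
  lbl <- setNames(rep(NA_character_, length(p3)), names(p3))
  lbl[names(reclassLabels(report))] <- reclassLabels(report)
  write.table(data.frame(sample_id = names(p3), p_grade3_cluster = p3,
                         who_grade = grades, label = lbl),
              file.path(config$outDir, "membership.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")

  # ---- validate ----
  rec <- setNames(sampleRecurrence(cohort), colnames(cohort))
  groupLbl <- ifelse(grades == 1, "grade1",
                     ifelse(grades == 3, "grade3", lbl))
  names(groupLbl) <- names(p3)
  validation <- list()
  haveAB <- function(a, b) {
    known <- rec != "unknown"
    any(groupLbl == a & known, na.rm = TRUE) &&
      any(groupLbl == b & known, na.rm = TRUE)
  }
  if (haveAB("grade3_like", "grade1_like")) {
    tab <- recurrenceTable(groupLbl, rec, "grade3_like", "grade1_like")
    chi <- chiSquareTest(tab)
    validation$subgroup_table <- tab
    validation$subgroup_chi <- chi
    validation$rate_grade3_like <- recurrenceRate(tab[1, ])
    validation$rate_grade1_like <- recurrenceRate(tab[2, ])
  }
  g1ids <- names(p3)[grades == 1]
  g3ids <- names(p3)[grades == 3]
  g1like <- names(lbl)[!is.na(lbl) & lbl == "grade1_like"]
  g3like <- names(lbl)[!is.na(lbl) & lbl == "grade3_like"]
  if (nrow(metageneScores(metag)) >= 3 && length(g1ids) && length(g1like))
    validation$concordance_g1 <- moduleConcordance(metag, g1ids, g1like)
  if (nrow(metageneScores(metag)) >= 3 && length(g3ids) && length(g3like))
    validation$concordance_g3 <- moduleConcordance(metag, g3ids, g3like)
  if (nrow(metageneScores(metag)) >= 3 &&
      length(g1ids) && length(g3ids) && length(g1like) && length(g3like))
    validation$differential <- differentialConcordance(
      metag, list(g1 = g1ids, g3 = g3ids, g1like = g1like, g3like = g3like))

  summary <- list(
    n_samples = ncol(cohort),
    n_genes = nrow(cohort),
    beta = as.numeric(beta),
    n_modules = length(unique(partition[partition > 0])),
    n_de_genes = if (is.null(de)) NA_integer_ else sum(de$direction != "ns"),
    signature = sigInfo,
    reclass_counts = as.list(report@counts),
    reclassified_fraction = if (length(report@labels))
      mean(report@labels != "intermediate") else NA_real_,
    cost = report@cost,
    validation = list(
      chi_p = validation$subgroup_chi$p_value %||% NA_real_,
      rate_grade3_like = validation$rate_grade3_like$percent %||% NA_real_,
      rate_grade1_like = validation$rate_grade1_like$percent %||% NA_real_,
      rho_g1 = validation$concordance_g1$rho %||% NA_real_,
      rho_g3 = validation$concordance_g3$rho %||% NA_real_,
      rho_differential = validation$differential$rho %||% NA_real_
    )
  )
  jsonlite::write_json(summary, file.path(config$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(summary, list(details = validation, report = report,
                            membership = membership, metagenes = metag,
                            partition = partition, de = de, cohort = cohort)))
}
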