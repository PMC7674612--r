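# Shared fixtures: small synthetic configurations that keep tests fast.

smallConfig <- function(seed = 1L, ...) {
  args <- list(
    nGenes = 200L, moduleSizes = c(40L, 35L, 30L),
    moduleEffects = rbind(c(-1, 1), c(1, -1), c(0, 0)),
    samplesPerGrade = c(grade1 = 40L, grade2 = 20L, grade3 = 16L),
    nBatches = 3L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthConfig, args)
}

# A minimal StudyExpression from a bare matrix.
studyFrom <- function(m, id = "s", scale = "log2") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("%s_c%02d", id, seq_len(ncol(m)))
  StudyExpression(id, m, scale = scale)
}

# A small preprocessed cohort reused by network-stage tests.
smallCohort <- function(seed = 1L, ...) {
  sim <- simulateCohort(smallConfig(seed = seed, ...))
  suppressWarnings(preprocessCohort(sim$studies, sim$metadata))
}

# Two-block planted structure: block correlation via a shared factor.
twoBlockMatrix <- function(nPerBlock = 50, nSamples = 60, withinCor = 0.9,
                           noiseSdOverride = NULL, seed = 1L) {
  set.seed(seed)
  # loading l gives within-block correlation l^2 / (l^2 + s^2); choose s for
  # the requested correlation with l = 1.
  s <- if (is.null(noiseSdOverride)) sqrt(1 / withinCor - 1) else noiseSdOverride
  f1 <- rnorm(nSamples); f2 <- rnorm(nSamples)
  x <- rbind(
    matrix(rep(f1, each = nPerBlock), nPerBlock) +
      matrix(rnorm(nPerBlock * nSamples, 0, s), nPerBlock),
    matrix(rep(f2, each = nPerBlock), nPerBlock) +
      matrix(rnorm(nPerBlock * nSamples, 0, s), nPerBlock))
  dimnames(x) <- list(sprintf("g%03d", seq_len(2 * nPerBlock)),
                      sprintf("s%03d", seq_len(nSamples)))
  x
}
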