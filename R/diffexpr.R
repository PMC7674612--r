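# Single-gene differential expression between WHO grades.

#' Per-gene log2 fold change between two grades
#'
#' In log2-transformed space the fold change is the difference of group means:
#' mean expression in \code{gradeB} samples minus mean in \code{gradeA}
#' samples (defaults: grade 3 minus grade 1).
#'
#' @param cohort a \linkS4class{MergedCohort}.
#' @param gradeA baseline grade (default 1).
#' @param gradeB comparison grade (default 3).
#' @return named numeric vector of per-gene log2 fold changes.
#' @export
log2FoldChange <- function(cohort, gradeA = 1L, gradeB = 3L) {
  stopifnot(is(cohort, "MergedCohort"))
  g <- sampleGrade(cohort)
  for (gr in c(gradeA, gradeB))
    if (!any(g == gr))
      stop("log2FoldChange: no samples of grade ", gr, call. = FALSE)
  x <- exprsMat(cohort)
  rowMeans(x[, g == gradeB, drop = FALSE]) -
    rowMeans(x[, g == gradeA, drop = FALSE])
}

#' Differential expression test between two grades
#'
#' Per-gene two-sample test (Welch t by default, Mann-Whitney optionally) with
#' fold-change/significance flags: a gene is \code{up} if its log2 fold change
#' is >= \code{fcThreshold} and p <= \code{pThreshold}, \code{down} if the
#' fold change is <= -\code{fcThreshold} at the same p cutoff, otherwise
#' \code{ns}. No multiple-testing correction is applied; the fixed p cutoff
#' (default 1e-4) is itself the stringency control. Genes with zero variance
#' in both groups are flagged degenerate with p = 1.
#'
#' @param cohort a \linkS4class{MergedCohort}.
#' @param grades length-2 grades to compare (default \code{c(1, 3)}).
#' @param test \code{"welch"} (unequal-variance t-test) or \code{"wilcoxon"}.
#' @param fcThreshold absolute log2 fold-change cutoff (default 1.5).
#' @param pThreshold p-value cutoff (default 1e-4).
#' @return data.frame: \code{gene_id}, \code{log2_fc}, \code{p_value},
#'   \code{direction}, \code{degenerate}.
#' @export
deTest <- function(cohort, grades = c(1L, 3L),
                   test = c("welch", "wilcoxon"),
                   fcThreshold = 1.5, pThreshold = 1e-4) {
  stopifnot(is(cohort, "MergedCohort"))
  test <- match.arg(test)
  g <- sampleGrade(cohort)
  a <- which(g == grades[1])
  b <- which(g == grades[2])
  if (length(a) < 2 || length(b) < 2)
    stop("deTest: need >= 2 samples in each grade", call. = FALSE)
  x <- exprsMat(cohort)
  fc <- rowMeans(x[, b, drop = FALSE]) - rowMeans(x[, a, drop = FALSE])
  p <- numeric(nrow(x))
  degenerate <- logical(nrow(x))
  for (i in seq_len(nrow(x))) {
    xa <- x[i, a]; xb <- x[i, b]
    if (var(xa) == 0 && var(xb) == 0) {
      p[i] <- 1; degenerate[i] <- TRUE
      next
    }
    p[i] <- if (test == "welch")
      tryCatch(t.test(xb, xa)$p.value, error = function(e) 1)
    else
      suppressWarnings(wilcox.test(xb, xa, exact = FALSE)$p.value)
  }
  direction <- rep("ns", nrow(x))
  direction[fc >= fcThreshold & p <= pThreshold] <- "up"
  direction[fc <= -fcThreshold & p <= pThreshold] <- "down"
  direction[degenerate] <- "ns"
  data.frame(gene_id = rownames(x), log2_fc = fc, p_value = p,
             direction = direction, degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}
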